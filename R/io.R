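#' Read / write lifecycle datasets as CSV
#'
#' The CSV dialect is one row per time slot with columns \code{slot},
#' optional \code{stage}, then the growth indices and environmental
#' parameters (header row required, UTF-8).
#'
#' @param ds A \code{lifecycle_data} tibble.
#' @param path File path.
#' @return \code{write_lifecycle_csv} returns \code{path} invisibly;
#'   \code{read_lifecycle_csv} returns a \code{lifecycle_data} tibble.
#' @export
write_lifecycle_csv <- function(ds, path) {
  readr::write_csv(ds, path)
  invisible(path)
}

#' @rdname write_lifecycle_csv
#' @param index_names,env_names Which columns are growth indices /
#'   environmental parameters; by default every non-\code{slot}/\code{stage}
#'   column not in \code{index_names} is environmental.
#' @export
read_lifecycle_csv <- function(path, index_names, env_names = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (is.null(env_names)) {
    env_names <- setdiff(names(df), c("slot", "stage", index_names))
  }
  as_lifecycle(df, index_names, env_names)
}

#' Read / write sensor fields
#'
#' CSV holds the node table (\code{id}, \code{x}, \code{y}, one
#' \code{t_<param>} column per parameter); region and radius travel as
#' function arguments. The JSON form stores nodes, region and radius
#' together.
#'
#' @param field A \code{sensor_field}.
#' @param path File path.
#' @export
write_field_csv <- function(field, path) {
  readr::write_csv(field$nodes, path)
  invisible(path)
}

#' @rdname write_field_csv
#' @param region Named vector \code{c(width =, height =)} (m).
#' @param radius Sensing radius (m).
#' @export
read_field_csv <- function(path, region, radius) {
  nodes <- readr::read_csv(path, show_col_types = FALSE)
  new_sensor_field(nodes, region = region, radius = radius)
}

#' @rdname write_field_csv
#' @export
write_field_json <- function(field, path) {
  jsonlite::write_json(list(region = as.list(field$region),
                            radius = field$radius,
                            nodes = field$nodes),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_sensor_field(tibble::as_tibble(obj$nodes),
                   region = c(width = obj$region$width,
                              height = obj$region$height),
                   radius = obj$radius)
}

#' Read / write simulation configurations as YAML
#'
#' Matrices and the coupling array are stored with their dimensions so a
#' round trip reproduces the configuration exactly.
#'
#' @param config A \code{\link{sim_config}}.
#' @param path File path.
#' @export
write_config_yaml <- function(config, path) {
  ser <- unclass(config)
  for (nm in c("index_intercept", "index_slope", "index_curvature")) {
    ser[[nm]] <- list(dim = dim(config[[nm]]), data = as.vector(config[[nm]]))
  }
  ser$coupling <- list(dim = dim(config$coupling),
                       data = as.vector(config$coupling))
  yaml::write_yaml(ser, path, precision = 18L)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("index_intercept", "index_slope", "index_curvature")) {
    if (is.list(raw[[nm]]) && !is.null(raw[[nm]]$dim)) {
      raw[[nm]] <- array(unlist(raw[[nm]]$data), dim = unlist(raw[[nm]]$dim))
    }
  }
  if (is.list(raw$coupling) && !is.null(raw$coupling$dim)) {
    raw$coupling <- array(unlist(raw$coupling$data),
                          dim = unlist(raw$coupling$dim))
  }
  raw$n_stages <- NULL
  do.call(sim_config, raw)
}

#' Persist a trained T-S FNN model as JSON
#'
#' @param model A \code{tsfnn}.
#' @param path File path.
#' @export
write_tsfnn_json <- function(model, path) {
  jsonlite::write_json(list(
    centers = model$centers, widths = model$widths,
    consequents = model$consequents, k = model$k,
    trace = model$trace, epochs_run = model$epochs_run,
    shift = model$shift, scale = model$scale),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_tsfnn_json
#' @export
read_tsfnn_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(centers = as.matrix(obj$centers),
                 widths = as.matrix(obj$widths),
                 consequents = as.matrix(obj$consequents),
                 k = obj$k, trace = obj$trace,
                 epochs_run = obj$epochs_run,
                 shift = obj$shift, scale = obj$scale),
            class = "tsfnn")
}
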