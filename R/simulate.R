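#' Generate a synthetic crop lifecycle dataset
#'
#' Draws growth-index time series following the configured per-stage trends
#' plus Gaussian noise, then builds environmental series as stage-dependent
#' weighted combinations of the index series plus noise. Deterministic given
#' the configuration seed.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A tibble of class \code{lifecycle_data} with columns \code{slot},
#'   \code{stage} (ground-truth label), the h growth indices and the f
#'   environmental parameters. Index and environment column names are carried
#'   in attributes \code{index_names} / \code{env_names}.
#' @examples
#' ds <- generate_lifecycle(sim_config(seed = 1))
#' dplyr::glimpse(ds)
#' @export
generate_lifecycle <- function(config) {
  validate_sim_config(config)
  n <- config$n_slots
  h <- length(config$index_names)
  f <- length(config$env_names)
  stage <- true_stages(config)
  starts <- c(1L, config$stage_boundaries + 1L)
  t_rel <- seq_len(n) - starts[stage]

  withr::with_seed(config$seed, {
    X <- matrix(NA_real_, n, h, dimnames = list(NULL, config$index_names))
    for (j in seq_len(h)) {
      mu <- config$index_intercept[stage, j] +
        config$index_slope[stage, j] * t_rel +
        config$index_curvature[stage, j] * t_rel^2
      X[, j] <- mu + stats::rnorm(n, sd = config$index_noise_sd)
    }
    Z <- matrix(NA_real_, n, f, dimnames = list(NULL, config$env_names))
    for (i in seq_len(f)) {
      w <- config$coupling[stage, i, , drop = FALSE]  # n x 1 x h
      mu <- rowSums(X * matrix(w, n, h))
      Z[, i] <- mu + stats::rnorm(n, sd = config$env_noise_sd)
    }
    out <- tibble::as_tibble(cbind(
      data.frame(slot = seq_len(n), stage = stage),
      as.data.frame(X), as.data.frame(Z)))
  })
  as_lifecycle(out, config$index_names, config$env_names)
}

as_lifecycle <- function(df, index_names, env_names) {
  stopifnot(all(c("slot", index_names, env_names) %in% names(df)))
  structure(tibble::as_tibble(df),
            index_names = index_names, env_names = env_names,
            class = c("lifecycle_data", class(tibble::tibble())))
}

#' Growth-index / environmental matrices of a lifecycle dataset
#' @param ds A \code{lifecycle_data} tibble.
#' @return Numeric matrix (slots x variables).
#' @export
index_matrix <- function(ds) {
  as.matrix(ds[, attr(ds, "index_names"), drop = FALSE])
}

#' @rdname index_matrix
#' @export
env_matrix <- function(ds) {
  as.matrix(ds[, attr(ds, "env_names"), drop = FALSE])
}

#' Generate a random sensor field
#'
#' Places \code{n_nodes} sensor nodes uniformly at random in the monitoring
#' region. Every node can sense every environmental parameter; per-parameter
#' sensing times default to the configured nominal per-sensor time,
#' optionally jittered.
#'
#' @param config A \code{\link{sim_config}}.
#' @param time_jitter_sd Standard deviation of multiplicative lognormal-free
#'   jitter added to per-parameter times (truncated below at 0.1 s); 0 keeps
#'   all times at the nominal value.
#' @param seed Optional seed overriding \code{config$seed}.
#' @return An object of class \code{sensor_field}: a list with \code{nodes}
#'   (tibble \code{id}, \code{x}, \code{y} plus one \code{t_<param>} column
#'   per environmental parameter), \code{region} (named width/height) and
#'   \code{radius}.
#' @export
generate_sensor_field <- function(config, time_jitter_sd = 0, seed = NULL) {
  validate_sim_config(config)
  q <- config$n_nodes
  f <- length(config$env_names)
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  withr::with_seed(seed, {
    x <- stats::runif(q, 0, config$region_width)
    y <- stats::runif(q, 0, config$region_height)
    tm <- matrix(config$per_sensor_time, q, f)
    if (time_jitter_sd > 0) {
      tm <- pmax(0.1, tm + matrix(stats::rnorm(q * f, sd = time_jitter_sd), q, f))
    }
  })
  colnames(tm) <- paste0("t_", config$env_names)
  nodes <- tibble::as_tibble(cbind(
    data.frame(id = seq_len(q), x = x, y = y), as.data.frame(tm)))
  new_sensor_field(nodes,
                   region = c(width = config$region_width,
                              height = config$region_height),
                   radius = config$sensing_radius)
}

new_sensor_field <- function(nodes, region, radius) {
  stopifnot(all(c("id", "x", "y") %in% names(nodes)),
            radius > 0, all(region > 0))
  if (any(nodes$x < 0 | nodes$x > region[["width"]] |
          nodes$y < 0 | nodes$y > region[["height"]])) {
    stop("all node positions must lie inside the region", call. = FALSE)
  }
  tcols <- grep("^t_", names(nodes), value = TRUE)
  if (length(tcols) && any(as.matrix(nodes[tcols]) <= 0)) {
    stop("per-parameter sensing times must be > 0", call. = FALSE)
  }
  structure(list(nodes = tibble::as_tibble(nodes), region = region,
                 radius = radius),
            class = "sensor_field")
}

#' @export
print.sensor_field <- function(x, ...) {
  cat(sprintf("<sensor_field> %d nodes in %g x %g m, radius %g m\n",
              nrow(x$nodes), x$region[["width"]], x$region[["height"]],
              x$radius))
  print(x$nodes, n = 5)
  invisible(x)
}

#' Split a lifecycle dataset into per-stage train/test groups
#'
#' Draws the requested number of test slots from each stage without
#' replacement (mirroring held-out test groups such as 20/30/20 across three
#' stages); the remainder is the training set.
#'
#' @param ds A \code{lifecycle_data} tibble with a \code{stage} column.
#' @param sizes Integer vector, one test-group size per stage.
#' @param seed Integer seed.
#' @return List with \code{train} and \code{test} lifecycle tibbles.
#' @export
split_stage_groups <- function(ds, sizes, seed = 1L) {
  stopifnot("stage" %in% names(ds))
  stages <- sort(unique(ds$stage))
  if (length(sizes) != length(stages)) {
    stop("`sizes` must give one test-group size per stage", call. = FALSE)
  }
  counts <- table(factor(ds$stage, levels = stages))
  if (any(sizes > as.integer(counts))) {
    stop("requested more test slots than available in some stage",
         call. = FALSE)
  }
  test_idx <- withr::with_seed(as.integer(seed), {
    unlist(lapply(seq_along(stages), function(s) {
      pool <- which(ds$stage == stages[s])
      if (sizes[s] == 0) integer(0) else sample(pool, sizes[s])
    }))
  })
  test_idx <- sort(test_idx)
  inm <- attr(ds, "index_names"); enm <- attr(ds, "env_names")
  train <- ds[setdiff(seq_len(nrow(ds)), test_idx), , drop = FALSE]
  test <- ds[test_idx, , drop = FALSE]
  list(train = as_lifecycle(train, inm, enm),
       test = as_lifecycle(test, inm, enm))
}
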