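#' Simulation and strategy configuration
#'
#' Builds the single configuration object used by the lifecycle generator,
#' the sensor-field generator and the sensing strategies. Defaults describe a
#' lettuce-like lifecycle of 150 daily time slots split into three stages
#' (seedling / rosette / heading), five growth indices, ten environmental
#' parameters, and a 20-node cluster in a 100 m x 100 m monitoring region.
#'
#' Stage trajectories are linear per stage: index \eqn{\lambda} in stage
#' \eqn{s} follows \code{intercept + slope * t_rel + curvature * t_rel^2}
#' plus Gaussian noise, where \code{t_rel} counts slots from the stage start.
#' Environmental series are stage-dependent convex combinations of the
#' growth-index series (the coupling array) plus Gaussian noise, so the
#' ground-truth relevance of each environmental parameter at each stage is
#' known and downstream selection can be validated against it.
#'
#' @param n_slots Number of time slots in the lifecycle.
#' @param stage_boundaries Last slot index of each stage except the final one;
#'   strictly increasing, inside \code{(0, n_slots)}.
#' @param index_names Names of the h growth indices.
#' @param env_names Names of the f environmental parameters.
#' @param index_intercept,index_slope,index_curvature Numeric
#'   \code{n_stages x h} matrices of per-stage trend coefficients. Defaults
#'   give stage-mean jumps of about 10 units and stage-distinct slopes;
#'   curvature defaults to zero (linear trends).
#' @param index_noise_sd,env_noise_sd Gaussian noise standard deviations for
#'   growth indices and environmental parameters.
#' @param coupling Numeric array \code{n_stages x f x h} of weights mapping
#'   index series to environmental series. Default: each stage has a primary
#'   and a secondary index; parameter i puts a strength \code{s_i} (evenly
#'   spread over (0,1), stage-rotated) on the primary index and
#'   \code{1 - s_i} on the secondary one.
#' @param region_width,region_height Monitoring region dimensions (m).
#' @param n_nodes Number of sensor nodes q.
#' @param sensing_radius Sensing disk radius r (m).
#' @param per_sensor_time Nominal sensing time of one sensor/parameter (s).
#' @param data_size_bits Data size of one parameter reading (bits).
#' @param comm_rate Uplink communication rate vc (bits/s).
#' @param t_env_budget Environmental sensing-time constraint Tse (s).
#' @param t_growth_budget Growth-index sensing-time constraint per stage (s).
#' @param area_limit Effective sensing-area constraint (m^2).
#' @param pns_node_fraction,pns_sensor_fraction Fractions of nodes and sensors
#'   used by the partial-nodes baseline.
#' @param seed Integer seed driving all stochastic generation.
#'
#' @return An object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_slots = 150L,
                       stage_boundaries = c(50L, 100L),
                       index_names = c("leaf_number", "leaf_area",
                                       "stem_height", "leaf_color",
                                       "chlorophyll"),
                       env_names = c("air_humidity", "air_temperature",
                                     "light_intensity", "soil_humidity",
                                     "soil_temperature", "soil_nitrogen",
                                     "soil_phosphorus", "soil_potassium",
                                     "co2", "wind_speed"),
                       index_intercept = NULL,
                       index_slope = NULL,
                       index_curvature = NULL,
                       index_noise_sd = 0.2,
                       env_noise_sd = 0.1,
                       coupling = NULL,
                       region_width = 100,
                       region_height = 100,
                       n_nodes = 20L,
                       sensing_radius = 20,
                       per_sensor_time = 3,
                       data_size_bits = 10,
                       comm_rate = 100,
                       t_env_budget = 12,
                       t_growth_budget = 12,
                       area_limit = 7000,
                       pns_node_fraction = 0.75,
                       pns_sensor_fraction = 0.5,
                       seed = 42L) {
  h <- length(index_names)
  f <- length(env_names)
  k <- length(stage_boundaries) + 1L

  if (is.null(index_intercept)) {
    # stage-mean jumps ~10 units per stage, distinct per-index baselines
    index_intercept <- outer(10 * (seq_len(k) - 1), 5 * seq_len(h), `+`)
  }
  if (is.null(index_slope)) {
    # stage-distinct slopes, small relative to the stage jump; each stage's
    # primary/secondary coupling indices change fastest, so the key
    # (high-variance) features of a stage are the ones its environment
    # couples to
    index_slope <- outer(0.008 * seq_len(k), 1 + 0.1 * (seq_len(h) - 1))
    for (s in seq_len(k)) {
      prim <- ((s - 1L) %% h) + 1L
      seco <- (prim %% h) + 1L
      index_slope[s, prim] <- index_slope[s, prim] * 4
      index_slope[s, seco] <- index_slope[s, seco] * 2.5
    }
  }
  if (is.null(index_curvature)) {
    index_curvature <- matrix(0, k, h)
  }
  if (is.null(coupling)) {
    coupling <- default_coupling(k, f, h)
  }

  cfg <- structure(list(
    n_slots = as.integer(n_slots),
    stage_boundaries = as.integer(stage_boundaries),
    n_stages = k,
    index_names = index_names,
    env_names = env_names,
    index_intercept = index_intercept,
    index_slope = index_slope,
    index_curvature = index_curvature,
    index_noise_sd = index_noise_sd,
    env_noise_sd = env_noise_sd,
    coupling = coupling,
    region_width = region_width,
    region_height = region_height,
    n_nodes = as.integer(n_nodes),
    sensing_radius = sensing_radius,
    per_sensor_time = per_sensor_time,
    data_size_bits = data_size_bits,
    comm_rate = comm_rate,
    t_env_budget = t_env_budget,
    t_growth_budget = t_growth_budget,
    area_limit = area_limit,
    pns_node_fraction = pns_node_fraction,
    pns_sensor_fraction = pns_sensor_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Default stage-rotated coupling array
#'
#' For stage s the primary index is \code{((s - 1) mod h) + 1} (the stage's
#' fastest-changing, hence key, growth index under the default trends).
#' Environmental parameter i carries strength \code{s_i} on the primary
#' index and \code{1 - s_i} on a slow background index that never enters
#' the stage's key-feature set, with strengths evenly spread from 0.95 down
#' to 0.05 and the assignment rotated by stage so each stage prefers
#' different parameters. Because the background index is not a reference
#' series, the composite grey correlation of parameter i is monotone in
#' \code{s_i}, making the ground-truth ranking recoverable downstream.
#'
#' @param n_stages,f,h Stage, environmental-parameter and index counts.
#' @return A \code{n_stages x f x h} array.
#' @keywords internal
default_coupling <- function(n_stages, f, h) {
  w <- array(0, dim = c(n_stages, f, h))
  strengths <- seq(0.95, 0.05, length.out = f)
  for (s in seq_len(n_stages)) {
    prim <- ((s - 1L) %% h) + 1L
    seco <- (prim %% h) + 1L
    backg <- setdiff(seq_len(h), c(prim, seco))[1]
    # rotate which parameter gets which strength so stages differ
    ord <- ((seq_len(f) + 3L * (s - 1L) - 1L) %% f) + 1L
    st <- numeric(f)
    st[ord] <- strengths
    w[s, , prim] <- st
    w[s, , backg] <- 1 - st
  }
  w
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_slots >= 2L)
  b <- cfg$stage_boundaries
  if (length(b) > 0) {
    if (any(diff(b) <= 0) || any(b <= 0) || any(b >= cfg$n_slots)) {
      stop("stage_boundaries must be strictly increasing and inside (0, n_slots)",
           call. = FALSE)
    }
  }
  h <- length(cfg$index_names); f <- length(cfg$env_names)
  k <- cfg$n_stages
  for (nm in c("index_intercept", "index_slope", "index_curvature")) {
    m <- cfg[[nm]]
    if (!is.matrix(m) || !all(dim(m) == c(k, h))) {
      stop(sprintf("%s must be a %d x %d matrix", nm, k, h), call. = FALSE)
    }
  }
  if (!all(dim(cfg$coupling) == c(k, f, h))) {
    stop(sprintf("coupling must be a %d x %d x %d array", k, f, h),
         call. = FALSE)
  }
  if (cfg$index_noise_sd < 0 || cfg$env_noise_sd < 0) {
    stop("noise standard deviations must be >= 0", call. = FALSE)
  }
  if (cfg$n_nodes <= 0L) stop("n_nodes must be positive", call. = FALSE)
  if (cfg$sensing_radius <= 0) stop("sensing_radius must be > 0", call. = FALSE)
  if (cfg$per_sensor_time <= 0) stop("per_sensor_time must be > 0", call. = FALSE)
  if (cfg$comm_rate <= 0) stop("comm_rate must be > 0", call. = FALSE)
  invisible(cfg)
}

#' Stage labels implied by configured boundaries
#' @param config A \code{sim_config}.
#' @return Integer vector of length \code{n_slots}.
#' @export
true_stages <- function(config) {
  cuts <- c(0L, config$stage_boundaries, config$n_slots)
  rep(seq_len(config$n_stages), diff(cuts))
}

#' Ground-truth coupling strength of each environmental parameter at a stage
#'
#' The strength is the weight the generator places on the stage's primary
#' growth index; it is the quantity grey-correlation ranking should recover.
#'
#' @param config A \code{sim_config}.
#' @param stage Stage number.
#' @return A tibble with columns \code{param} and \code{strength}.
#' @export
coupling_strength <- function(config, stage) {
  stopifnot(stage >= 1, stage <= config$n_stages)
  prim <- ((stage - 1L) %% length(config$index_names)) + 1L
  tibble::tibble(param = config$env_names,
                 strength = config$coupling[stage, , prim])
}

#' Per-stage data-value scores of environmental parameters
#'
#' The sensing value of an environmental parameter at a stage is scored on a
#' 0-100 scale proportional to its ground-truth coupling share, so parameters
#' strongly tied to the stage's key growth indices carry high value. A custom
#' value table (tibble with \code{param}, \code{value}) may be supplied to
#' \code{\link{run_strategy}} instead.
#'
#' @inheritParams coupling_strength
#' @return A tibble with columns \code{param} and \code{value}.
#' @export
value_scores <- function(config, stage) {
  cs <- coupling_strength(config, stage)
  tibble::tibble(param = cs$param,
                 value = 100 * cs$strength / sum(cs$strength))
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  lifecycle: %d slots, %d stages (boundaries %s)\n",
              x$n_slots, x$n_stages, paste(x$stage_boundaries, collapse = ", ")))
  cat(sprintf("  indices (h=%d): %s\n", length(x$index_names),
              paste(x$index_names, collapse = ", ")))
  cat(sprintf("  environment (f=%d): %s\n", length(x$env_names),
              paste(x$env_names, collapse = ", ")))
  cat(sprintf("  field: %d nodes, %g x %g m, radius %g m, area limit %g m^2\n",
              x$n_nodes, x$region_width, x$region_height,
              x$sensing_radius, x$area_limit))
  cat(sprintf("  budgets: Tse %g s, growth %g s; sensor time %g s; rate %g b/s\n",
              x$t_env_budget, x$t_growth_budget, x$per_sensor_time, x$comm_rate))
  invisible(x)
}
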