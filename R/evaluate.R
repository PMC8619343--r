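#' Per-node sensing time of a parameter set
#'
#' Plain sum of per-parameter sensing times, \eqn{t(Z) = \sum_j t(z_j)}.
#'
#' @param params Character vector of parameter names.
#' @param times Named per-parameter times (s).
#' @return Seconds.
#' @export
sensing_time <- function(params, times) {
  if (length(params) == 0) return(0)
  tv <- times[params]
  if (anyNA(tv)) stop("sensing time missing for: ",
                      paste(params[is.na(tv)], collapse = ", "),
                      call. = FALSE)
  sum(tv)
}

#' Total data collection time of a cluster
#'
#' Serial uplink model: every participating node transmits its readings in
#' turn, so \eqn{t_c(Z) = q \cdot \sum_j ds(z_j) / v_c + t(Z)}.
#'
#' @param n_nodes Number of participating nodes q.
#' @param params Parameters sensed by each node.
#' @param data_size Bits per parameter reading.
#' @param vc Communication rate (bits/s), \code{> 0}.
#' @param t_sense Per-node sensing time t(Z) (s).
#' @return Seconds.
#' @export
collection_time <- function(n_nodes, params, data_size, vc, t_sense) {
  if (vc <= 0) stop("communication rate must be > 0", call. = FALSE)
  n_nodes * length(params) * data_size / vc + t_sense
}

#' Total and effective data value of a sensed parameter set
#'
#' \eqn{V(Z) = \sum_j v(z_j)} and the coverage-discounted effective value
#' \eqn{V(c, Z) = (Ar_v / Ar_\Lambda) V(Z)}.
#'
#' @param params Selected parameter names.
#' @param values Tibble with \code{param} and \code{value} columns (e.g.
#'   \code{\link{value_scores}}) or a named numeric vector.
#' @param area_eff Effective sensing area (m^2), \code{<= area_total}.
#' @param area_total Monitoring-region area (m^2).
#' @return Named numeric vector with \code{total} and \code{effective}.
#' @export
data_value <- function(params, values, area_eff, area_total) {
  if (is.data.frame(values)) {
    values <- stats::setNames(values$value, values$param)
  }
  stopifnot(area_eff <= area_total + 1e-9)
  v <- if (length(params) == 0) 0 else sum(values[params])
  if (anyNA(v)) stop("value missing for some parameter", call. = FALSE)
  c(total = v, effective = area_eff / area_total * v)
}

per_unit_metrics <- function(tdv, t_sense, n_nodes, area_eff) {
  c(pdv_st = tdv / t_sense, pdv_ns = tdv / n_nodes, pdv_ea = tdv / area_eff)
}

#' Run one sensing strategy and compute its data-value metrics
#'
#' The three strategies are:
#' \describe{
#'   \item{ANS}{all nodes sense all parameters (baseline);}
#'   \item{PNS}{a seeded random subset of nodes senses a seeded random
#'     subset of parameters (partial baseline);}
#'   \item{ASM}{the full adaptive pipeline — predict the current stage with
#'     the T-S FNN, pick key growth indices under the growth time budget,
#'     rank and select environmental parameters by GIW-DGC under Tse, then
#'     select nodes greedily under the effective-area constraint.}
#' }
#'
#' The total data value (TDV) scores each collected parameter by its
#' stage-specific relevance (\code{\link{value_scores}} by default) and
#' discounts the sum by the ratio of effective to total sensing area of the
#' participating nodes, so redundant overlapping coverage lowers the value
#' of the data it duplicates. Per-unit metrics divide TDV by sensing time,
#' node count and effective area exactly.
#'
#' @param method \code{"ANS"}, \code{"PNS"} or \code{"ASM"}.
#' @param ds Historical \code{lifecycle_data} (used by ASM's grey ranking).
#' @param field A \code{sensor_field}.
#' @param config The \code{\link{sim_config}}.
#' @param division A \code{stage_division} (required for ASM).
#' @param model A trained \code{tsfnn} (required for ASM).
#' @param x_now Fresh growth-index vector for stage prediction (required
#'   for ASM).
#' @param stage Stage used for the value table; default ASM's prediction,
#'   or stage 1 for the baselines if not given.
#' @param sst Override every per-parameter sensing time with this value (s)
#'   when computing time metrics (the single-sensor sensing-time sweep);
#'   ASM's parameter subset is still chosen under the nominal times and
#'   budget.
#' @param values Optional custom value table (tibble \code{param},
#'   \code{value}).
#' @param seed Seed for PNS's random subsets.
#' @param mode,resolution Coverage estimator options.
#' @return A \code{strategy_result} tibble (one row): method, stage,
#'   n_params, n_nodes, t_sense, t_collect, area_eff, area_total_disks,
#'   tdv, v_effective, pdv_st, pdv_ns, pdv_ea, plus the selected parameters
#'   and node ids as list-columns.
#' @export
run_strategy <- function(method = c("ANS", "PNS", "ASM"),
                         ds, field, config,
                         division = NULL, model = NULL, x_now = NULL,
                         stage = NULL, sst = NULL, values = NULL,
                         seed = 1L, mode = "grid", resolution = 0.5) {
  method <- match.arg(method)
  env_names <- config$env_names
  f <- length(env_names)
  nominal <- stats::setNames(rep(config$per_sensor_time, f), env_names)
  metric_times <- if (is.null(sst)) nominal else
    stats::setNames(rep(sst, f), env_names)

  if (method == "ANS") {
    params <- env_names
    node_ids <- field$nodes$id
    if (is.null(stage)) stage <- 1L
  } else if (method == "PNS") {
    sel <- withr::with_seed(as.integer(seed), {
      list(nodes = sort(sample(field$nodes$id,
                               max(1, round(config$pns_node_fraction *
                                              nrow(field$nodes))))),
           params = sort(sample(seq_len(f),
                                max(1, round(config$pns_sensor_fraction * f)))))
    })
    params <- env_names[sel$params]
    node_ids <- sel$nodes
    if (is.null(stage)) stage <- 1L
  } else {
    if (is.null(division) || is.null(model) || is.null(x_now)) {
      stop("ASM needs `division`, `model` and `x_now`", call. = FALSE)
    }
    stage_pred <- predict_stage(model, x_now)
    if (is.null(stage)) stage <- stage_pred
    kf <- division$key_features
    kf_stage <- kf[kf$stage == stage & kf$key, , drop = FALSE]
    kf_stage <- kf_stage[order(kf_stage$rank), , drop = FALSE]
    idx_times <- stats::setNames(rep(config$per_sensor_time,
                                     length(config$index_names)),
                                 config$index_names)
    growth_sel <- select_growth_params(kf_stage$index, idx_times,
                                       config$t_growth_budget)
    rng <- division$ranges
    srows <- rng[rng$stage == stage, , drop = FALSE]
    stage_slots <- unlist(lapply(seq_len(nrow(srows)), function(r) {
      seq(srows$start[r], srows$end[r])
    }))
    vars <- kf_stage$variance[match(growth_sel, kf_stage$index)]
    env_sel <- select_env_params(ds, stage_slots, growth_sel, vars,
                                 tse = config$t_env_budget, times = nominal)
    params <- env_sel$selected
    node_sel <- adaptive_select(field, config$area_limit,
                                params = params, mode = mode,
                                resolution = resolution)
    node_ids <- node_sel$selected$id
  }

  nodes <- field$nodes[field$nodes$id %in% node_ids, , drop = FALSE]
  area_eff <- effective_area(nodes, field$radius, field$region,
                             mode = mode, resolution = resolution)
  area_region <- field$region[["width"]] * field$region[["height"]]
  # total (non-unioned) sensing area, each disk clipped to the region
  disk_areas <- vapply(seq_len(nrow(nodes)), function(i) {
    effective_area(nodes[i, ], field$radius, field$region,
                   mode = mode, resolution = resolution)
  }, numeric(1))
  area_disks <- sum(disk_areas)

  vt <- if (is.null(values)) value_scores(config, stage) else values
  dv <- data_value(params, vt, area_eff, area_region)
  redundancy_eff <- if (area_disks > 0) area_eff / area_disks else 1
  tdv <- redundancy_eff * dv[["total"]]
  t_sense <- sensing_time(params, metric_times)
  t_coll <- collection_time(length(node_ids), params, config$data_size_bits,
                            config$comm_rate, t_sense)
  pm <- per_unit_metrics(tdv, t_sense, length(node_ids), area_eff)
  structure(tibble::tibble(
    method = method, stage = as.integer(stage),
    n_params = length(params), n_nodes = length(node_ids),
    t_sense = t_sense, t_collect = t_coll,
    area_eff = area_eff, area_disks = area_disks,
    tdv = tdv, v_effective = dv[["effective"]],
    pdv_st = pm[["pdv_st"]], pdv_ns = pm[["pdv_ns"]],
    pdv_ea = pm[["pdv_ea"]],
    params = list(params), node_ids = list(node_ids)),
    class = c("strategy_result", class(tibble::tibble())))
}

#' Sweep strategies over sensing times, communication rates and seeds
#'
#' Runs every combination of method, single-sensor sensing time (SST) and
#' communication rate over the replicate seeds and collects the metric rows.
#'
#' @inheritParams run_strategy
#' @param methods Methods to run.
#' @param sst_values SST sweep values (s); \code{NA} keeps nominal times.
#' @param vc_values Communication-rate sweep (bits/s).
#' @param seeds Replicate seeds (drive PNS subsets).
#' @return Tibble of metric rows with \code{sst}, \code{vc} and \code{seed}
#'   columns added.
#' @export
run_experiment <- function(ds, field, config, division = NULL, model = NULL,
                           x_now = NULL, methods = c("ANS", "PNS", "ASM"),
                           sst_values = config$per_sensor_time,
                           vc_values = config$comm_rate, seeds = 1L,
                           mode = "grid", resolution = 0.5) {
  grid <- expand.grid(method = methods, sst = sst_values, vc = vc_values,
                      seed = seeds, stringsAsFactors = FALSE)
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    cfg <- config
    cfg$comm_rate <- g$vc
    res <- run_strategy(g$method, ds, field, cfg, division = division,
                        model = model, x_now = x_now,
                        sst = if (is.na(g$sst)) NULL else g$sst,
                        seed = g$seed, mode = mode, resolution = resolution)
    dplyr::mutate(res, sst = g$sst, vc = g$vc, seed = g$seed,
                  .before = 1)
  })
}
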