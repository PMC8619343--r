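#' Grey relational coefficients between a reference and comparison series
#'
#' Deng's grey relational coefficient at each time slot,
#' \deqn{\xi(\tau) = \frac{\Delta_{min} + \rho\,\Delta_{max}}
#'                       {\Delta(\tau) + \rho\,\Delta_{max}},}
#' where \eqn{\Delta(\tau) = |x_0(\tau) - z_i(\tau)|} and the extrema are
#' taken over the comparison set. By default the extrema are the per-pair
#' min/max over \eqn{\tau}; supply \code{delta_min}/\code{delta_max} to use
#' extrema shared across many comparison series (the global-extrema
#' reading).
#'
#' Series should be normalized to a common scale first (see
#' \code{\link{normalize_series}}); identical sequences give \eqn{\xi \equiv
#' 1}.
#'
#' @param x0 Reference series.
#' @param zi Comparison series, same length.
#' @param rho Resolution coefficient in \code{[0, 1]}.
#' @param delta_min,delta_max Optional externally supplied extrema.
#' @return Numeric vector of coefficients in \code{(0, 1]}.
#' @export
grey_coefficient <- function(x0, zi, rho = 0.5,
                             delta_min = NULL, delta_max = NULL) {
  stopifnot(length(x0) == length(zi))
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]", call. = FALSE)
  d <- abs(x0 - zi)
  dmin <- if (is.null(delta_min)) min(d) else delta_min
  dmax <- if (is.null(delta_max)) max(d) else delta_max
  if (dmax == 0) return(rep(1, length(d)))  # identical sequences
  denom <- d + rho * dmax
  xi <- (dmin + rho * dmax) / denom
  xi[denom == 0] <- 1
  xi
}

#' Degree of grey correlation (DGC)
#'
#' The mean grey relational coefficient over all time slots; 1 means the
#' comparison series tracks the reference exactly.
#'
#' @inheritParams grey_coefficient
#' @return Scalar in \code{(0, 1]}.
#' @export
dgc <- function(x0, zi, rho = 0.5, delta_min = NULL, delta_max = NULL) {
  mean(grey_coefficient(x0, zi, rho, delta_min, delta_max))
}

#' Growth-index-weighted degree of grey correlation (GIW-DGC)
#'
#' Composite relevance of one environmental series to a set of key growth
#' indices: the per-index DGCs weighted by each index's share of the total
#' key-feature variance,
#' \deqn{\mathrm{GIW\mbox{-}DGC}(z_i) = \sum_j
#'   \frac{\sigma^2_j}{\sum_{j'} \sigma^2_{j'}}\; \zeta(x_j, z_i).}
#' With weights summing to one the score stays in \code{(0, 1]}.
#'
#' @param x Matrix of key-index series (slots x indices), already
#'   normalized.
#' @param variances Per-index variances (the priority weights).
#' @param zi Normalized comparison series.
#' @inheritParams grey_coefficient
#' @return Scalar composite score.
#' @export
giw_dgc <- function(x, variances, zi, rho = 0.5,
                    delta_min = NULL, delta_max = NULL) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == length(variances))
  if (all(variances == 0)) {
    warning("all key-feature variances are zero; using equal weights")
    variances <- rep(1, length(variances))
  }
  w <- variances / sum(variances)
  zeta <- vapply(seq_len(ncol(x)), function(j) {
    dgc(x[, j], zi, rho, delta_min, delta_max)
  }, numeric(1))
  sum(w * zeta)
}

#' Normalize series for grey relational analysis
#'
#' @param x Numeric vector.
#' @param method \code{"minmax"} maps to \code{[0, 1]} (constant series map
#'   to 0); \code{"zscore"} standardizes; \code{"none"} returns unchanged.
#' @return Numeric vector.
#' @export
normalize_series <- function(x, method = c("minmax", "zscore", "none")) {
  method <- match.arg(method)
  switch(method,
         minmax = {
           r <- range(x)
           if (diff(r) == 0) rep(0, length(x)) else (x - r[1]) / diff(r)
         },
         zscore = {
           s <- stats::sd(x)
           if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
         },
         none = x)
}

#' Rank and select environmental parameters for a growth stage
#'
#' Implements the grey-correlation selection loop: slice the historical
#' lifecycle to the stage's slots, normalize the stage's key growth indices
#' and every environmental series, score each environmental parameter by
#' GIW-DGC against the key indices (variance-share weighted), rank
#' descending (ties keep input order), and greedily accept parameters while
#' the cumulative sensing time stays within the budget Tse.
#'
#' @param ds A \code{lifecycle_data} tibble (the historical data).
#' @param stage_range Integer slots of the current stage (e.g. from
#'   \code{stage_division$ranges}).
#' @param key_features Character vector of the stage's key growth indices in
#'   priority order.
#' @param variances Variances of those indices (priority weights).
#' @param tse Sensing-time budget Tse (s).
#' @param times Named per-parameter sensing times (s); default the ones in
#'   \code{config} are built from.
#' @param rho Resolution coefficient.
#' @param norm Normalization method (see \code{\link{normalize_series}}).
#' @param global_extrema Share \eqn{\Delta_{min}/\Delta_{max}} across all
#'   (index, parameter) pairs of the comparison set — the classical two-level
#'   min/max of the printed coefficient and the default. Set \code{FALSE}
#'   for per-pair extrema over time only; note the per-pair form is
#'   invariant to rescaling a pair's difference series, which flattens the
#'   ranking when series differ mainly in how closely they track the
#'   reference.
#' @return An \code{env_selection}: list with \code{ranking} (tibble
#'   \code{param}, \code{giw_dgc}, \code{rank}, \code{time},
#'   \code{cum_time}, \code{selected}), \code{dgc_table} (per index-param
#'   DGCs), \code{selected} (character), \code{tse}, \code{total_time}.
#' @export
select_env_params <- function(ds, stage_range, key_features, variances,
                              tse, times, rho = 0.5,
                              norm = "minmax", global_extrema = TRUE) {
  if (length(key_features) == 0) {
    stop("no key growth indices supplied (empty reference set)",
         call. = FALSE)
  }
  rows <- ds[stage_range, , drop = FALSE]
  if (nrow(rows) == 0) stop("stage slice of history is empty", call. = FALSE)
  env_names <- attr(ds, "env_names")
  Xk <- apply(as.matrix(rows[, key_features, drop = FALSE]), 2,
              normalize_series, method = norm)
  Z <- apply(as.matrix(rows[, env_names, drop = FALSE]), 2,
             normalize_series, method = norm)
  dmin <- dmax <- NULL
  if (global_extrema) {
    D <- abs(array(Xk[, rep(seq_along(key_features), ncol(Z))],
                   c(nrow(Z), length(key_features) * ncol(Z))) -
             Z[, rep(seq_len(ncol(Z)), each = length(key_features))])
    dmin <- min(D); dmax <- max(D)
  }
  dgc_table <- purrr::map_dfr(seq_along(env_names), function(i) {
    tibble::tibble(param = env_names[i], index = key_features,
                   dgc = vapply(seq_along(key_features), function(j) {
                     dgc(Xk[, j], Z[, i], rho, dmin, dmax)
                   }, numeric(1)))
  })
  scores <- vapply(seq_along(env_names), function(i) {
    giw_dgc(Xk, variances, Z[, i], rho, dmin, dmax)
  }, numeric(1))
  tv <- times[env_names]
  if (anyNA(tv)) stop("sensing time missing for some parameter", call. = FALSE)
  ord <- order(-scores)  # stable: ties keep input order
  ranking <- tibble::tibble(param = env_names[ord],
                            giw_dgc = scores[ord],
                            rank = seq_along(ord),
                            time = unname(tv[ord]))
  keep <- cumsum(ranking$time) <= tse
  if (any(!keep)) keep[which(!keep)[1]:length(keep)] <- FALSE
  ranking$cum_time <- cumsum(ranking$time)
  ranking$selected <- keep
  structure(list(ranking = ranking, dgc_table = dgc_table,
                 selected = ranking$param[keep], tse = tse,
                 total_time = sum(ranking$time[keep])),
            class = "env_selection")
}

#' @export
print.env_selection <- function(x, ...) {
  cat(sprintf("<env_selection> %d of %d parameters within Tse = %g s (used %g s)\n",
              length(x$selected), nrow(x$ranking), x$tse, x$total_time))
  print(x$ranking)
  invisible(x)
}
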