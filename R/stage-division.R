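#' Gath-Geva fuzzy clustering of growth-index series
#'
#' Clusters the time-slot growth-index vectors with the fuzzy
#' maximum-likelihood (Gath-Geva) algorithm: cluster centers are
#' membership^m-weighted means, covariances and priors are
#' membership-weighted, and the distance of a point to a cluster is
#' \deqn{D_{ij} = \det(B_j)\, \exp((x_i-c_j)^T B_j^{-1} (x_i-c_j)/2) / P_j,}
#' with membership update \eqn{u_{ij} \propto D_{ij}^{-2/(m-1)}} normalized
#' over clusters. Distances are handled in the log domain, so widely
#' separated clusters do not overflow the exponential.
#'
#' The covariance weighting uses plain memberships (no fuzzifier exponent),
#' and the distance uses \eqn{\det(B_j)} rather than its square root; the
#' classical square-root form is available via \code{sqrt_det = TRUE}.
#'
#' @param x Numeric matrix or data frame (n slots x h indices).
#' @param k Number of clusters, \code{2 <= k <= n}.
#' @param m Fuzzifier, \code{> 1}.
#' @param eps Convergence tolerance on the max-abs entrywise change of the
#'   membership matrix.
#' @param max_iter Iteration cap.
#' @param seed Seed for the initialization.
#' @param init \code{"fcm"} (fuzzy c-means warm start, default) or
#'   \code{"random"} membership initialization.
#' @param sqrt_det Use \eqn{\sqrt{\det B_j}} in the distance.
#' @param unsquared_cc Compute the classification coefficient without the
#'   square (the literal plain-mean form) instead of the standard partition
#'   coefficient.
#' @return A \code{gg_partition}: list with \code{k}, \code{U} (k x n),
#'   \code{centers}, \code{covariances}, \code{priors}, \code{cc},
#'   \code{afe}, \code{iterations}, \code{converged}.
#' @export
gg_cluster <- function(x, k, m = 2, eps = 1e-6, max_iter = 200L,
                       seed = 1L, init = c("fcm", "random"),
                       sqrt_det = FALSE, unsquared_cc = FALSE) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  n <- nrow(X); h <- ncol(X)
  if (k < 2 || k > n) stop("k must satisfy 2 <= k <= n", call. = FALSE)
  if (m <= 1) stop("fuzzifier m must be > 1", call. = FALSE)
  if (eps <= 0) stop("eps must be > 0", call. = FALSE)
  init <- match.arg(init)

  U <- withr::with_seed(as.integer(seed), init_membership(X, k, m, init))
  converged <- FALSE
  iter <- 0L
  expo <- 2 / (m - 1)
  repeat {
    iter <- iter + 1L
    Um <- U^m
    centers <- (Um %*% X) / rowSums(Um)
    logD <- matrix(NA_real_, k, n)
    covs <- vector("list", k)
    priors <- rowSums(U) / n
    for (j in seq_len(k)) {
      Xc <- sweep(X, 2, centers[j, ])
      wj <- U[j, ]
      B <- crossprod(Xc * wj, Xc) / sum(wj)
      B <- regularize_cov(B)
      covs[[j]] <- B
      ch <- tryCatch(chol(B), error = function(e) NULL)
      if (is.null(ch)) {
        B <- B + diag(1e-6 + 1e-6 * mean(diag(B)), h)
        covs[[j]] <- B
        ch <- chol(B)
      }
      logdet <- 2 * sum(log(diag(ch)))
      mah <- rowSums((Xc %*% chol2inv(ch)) * Xc)
      dfac <- if (sqrt_det) 0.5 else 1
      logD[j, ] <- dfac * logdet + mah / 2 - log(priors[j])
    }
    # u_ij = D^{-2/(m-1)} normalized over clusters (log-domain softmax)
    L <- -expo * logD
    L <- sweep(L, 2, apply(L, 2, max))
    E <- exp(L)
    U_new <- sweep(E, 2, colSums(E), "/")
    delta <- max(abs(U_new - U))
    U <- U_new
    if (delta < eps) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  v <- partition_validity(U, unsquared = unsquared_cc)
  structure(list(k = k, U = U, centers = centers, covariances = covs,
                 priors = rowSums(U) / n, cc = v[["cc"]], afe = v[["afe"]],
                 iterations = iter, converged = converged, m = m,
                 data = X),
            class = "gg_partition")
}

init_membership <- function(X, k, m, init) {
  n <- nrow(X)
  if (init == "fcm") {
    fit <- tryCatch(
      e1071::cmeans(jitter_dups(X), centers = k, m = max(m, 1.5),
                    iter.max = 200),
      error = function(e) NULL)
    if (!is.null(fit)) return(t(fit$membership))
  }
  U <- matrix(stats::runif(k * n), k, n)
  sweep(U, 2, colSums(U), "/")
}

# cmeans fails on duplicate initial centers; break exact ties imperceptibly
jitter_dups <- function(X) {
  if (anyDuplicated(X)) X + matrix(stats::rnorm(length(X), sd = 1e-8),
                                   nrow(X), ncol(X))
  else X
}

regularize_cov <- function(B, cond_limit = 1e12) {
  B <- (B + t(B)) / 2
  ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
  tr_h <- mean(diag(B))
  if (min(ev) <= 0 || max(ev) / max(min(ev), .Machine$double.xmin) > cond_limit) {
    ridge <- 1e-6 * max(tr_h, 1e-6)
    B <- B + diag(ridge, ncol(B))
  }
  B
}

#' Partition validity indices
#'
#' Classification coefficient (CC), the mean squared membership
#' \eqn{\alpha = \frac1n \sum_i \sum_j u_{ij}^2}, and average fuzzy entropy
#' (AFE), \eqn{\beta = -\frac1n \sum_i \sum_j u_{ij} \ln u_{ij}} with
#' \eqn{0 \ln 0 := 0}. CC is 1 for a crisp partition and \eqn{1/k} for a
#' maximally fuzzy one; AFE is 0 and \eqn{\ln k} respectively.
#'
#' @param U Column-stochastic membership matrix (k clusters x n points).
#' @param unsquared Use plain memberships in CC instead of their squares.
#' @return Named numeric vector with elements \code{cc} and \code{afe}.
#' @export
partition_validity <- function(U, unsquared = FALSE) {
  U <- as.matrix(U)
  if (any(U < -1e-12) || any(U > 1 + 1e-12)) {
    stop("membership values must lie in [0, 1]", call. = FALSE)
  }
  n <- ncol(U)
  cc <- if (unsquared) sum(U) / n else sum(U^2) / n
  Up <- U[U > 0]
  afe <- -sum(Up * log(Up)) / n
  c(cc = cc, afe = afe)
}

#' Divide a crop lifecycle into growth stages
#'
#' Runs Gath-Geva clustering over a range of candidate stage counts, selects
#' the count with the best partition validity (maximum CC, ties broken by
#' minimum AFE), labels each time slot by its maximum membership, relabels
#' clusters into temporal order by median slot, majority-smooths label runs
#' shorter than 3 slots, and extracts per-stage key growth features.
#'
#' @param ds A \code{lifecycle_data} tibble or a numeric slot-by-index
#'   matrix.
#' @param k_range Candidate stage counts (each \code{>= 2}).
#' @param m,eps,max_iter,seed,init,sqrt_det,unsquared_cc Passed to
#'   \code{\link{gg_cluster}}.
#' @param theta Variance bound for key-feature selection; \code{NULL} uses
#'   the per-stage mean variance (scale-free default).
#' @return A \code{stage_division}: list with \code{best_k}, \code{validity}
#'   (tibble of k, cc, afe, converged), \code{labels}, \code{ranges} (tibble
#'   stage/start/end), \code{key_features} (see
#'   \code{\link{select_key_features}}), \code{partition} (the winning
#'   \code{gg_partition}) and \code{theta}.
#' @export
divide_growth_stages <- function(ds, k_range = 2:6, m = 2, eps = 1e-6,
                                 max_iter = 200L, seed = 1L,
                                 init = "fcm", sqrt_det = FALSE,
                                 unsquared_cc = FALSE, theta = NULL) {
  X <- if (inherits(ds, "lifecycle_data")) index_matrix(ds) else as.matrix(ds)
  if (any(k_range < 2)) stop("all candidate k must be >= 2", call. = FALSE)
  fits <- lapply(seq_along(k_range), function(i) {
    gg_cluster(X, k_range[i], m = m, eps = eps, max_iter = max_iter,
               seed = seed + i - 1L, init = init, sqrt_det = sqrt_det,
               unsquared_cc = unsquared_cc)
  })
  validity <- tibble::tibble(
    k = k_range,
    cc = vapply(fits, `[[`, numeric(1), "cc"),
    afe = vapply(fits, `[[`, numeric(1), "afe"),
    converged = vapply(fits, `[[`, logical(1), "converged"))
  if (!any(validity$converged)) {
    stop("no candidate stage count converged; validity table:\n",
         paste(utils::capture.output(print(validity)), collapse = "\n"),
         call. = FALSE)
  }
  best <- order(-validity$cc, validity$afe)[1]
  fit <- fits[[best]]
  labels <- relabel_temporal(apply(fit$U, 2, which.max))
  labels <- smooth_short_runs(labels, min_run = 3L)
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  ranges <- tibble::tibble(stage = r$values,
                           start = c(1L, utils::head(ends, -1) + 1L),
                           end = ends)
  kf <- if (inherits(ds, "lifecycle_data")) {
    select_key_features(ds, ranges, theta = theta)
  } else NULL
  structure(list(best_k = fit$k, validity = validity, labels = labels,
                 ranges = ranges, key_features = kf, partition = fit,
                 theta = theta),
            class = "stage_division")
}

# order cluster ids by the median slot at which they occur
relabel_temporal <- function(labels) {
  med <- vapply(sort(unique(labels)), function(l) {
    stats::median(which(labels == l))
  }, numeric(1))
  map <- integer(max(labels))
  map[sort(unique(labels))[order(med)]] <- seq_along(med)
  map[labels]
}

smooth_short_runs <- function(labels, min_run = 3L) {
  for (pass in 1:5) {
    r <- rle(labels)
    if (length(r$lengths) == 1 || all(r$lengths >= min_run)) break
    i <- which(r$lengths < min_run)[1]
    r$values[i] <- if (i == 1) r$values[i + 1] else r$values[i - 1]
    labels <- inverse.rle(r)
  }
  labels
}

#' Per-stage key growth features ordered by variance
#'
#' Growth indices are z-scored over the whole lifecycle, then the population
#' variance of each standardized index is computed within each stage's slot
#' range. Indices whose variance exceeds the bound \code{theta} are the
#' stage's key features, ordered from largest variance to smallest (highest
#' priority first).
#'
#' @param ds A \code{lifecycle_data} tibble.
#' @param ranges Tibble with columns \code{stage}, \code{start}, \code{end}
#'   partitioning the slots.
#' @param theta Variance bound; \code{NULL} uses the mean of the stage's
#'   variance vector.
#' @return Tibble with columns \code{stage}, \code{index}, \code{variance},
#'   \code{rank} (priority among the stage's key features, NA if filtered
#'   out) and \code{key} (logical).
#' @export
select_key_features <- function(ds, ranges, theta = NULL) {
  X <- index_matrix(ds)
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0] <- 1  # constant indices stay constant (variance 0)
  Xs <- sweep(sweep(X, 2, colMeans(X)), 2, sds, "/")
  purrr::map_dfr(seq_len(nrow(ranges)), function(r) {
    if (ranges$end[r] < ranges$start[r]) {
      stop("empty stage range", call. = FALSE)
    }
    rows <- seq(ranges$start[r], ranges$end[r])
    v <- apply(Xs[rows, , drop = FALSE], 2, pop_var)
    th <- if (is.null(theta)) mean(v) else theta
    key <- v > th
    ord <- order(-v)
    rank <- rep(NA_integer_, length(v))
    rank[ord[key[ord]]] <- seq_len(sum(key))
    tibble::tibble(stage = ranges$stage[r], index = colnames(X),
                   variance = unname(v), rank = rank, key = key) |>
      dplyr::arrange(dplyr::desc(.data$variance))
  })
}

# population variance (divide by the series length, not length - 1)
pop_var <- function(x) mean((x - mean(x))^2)

#' @export
print.gg_partition <- function(x, ...) {
  cat(sprintf("<gg_partition> k = %d, CC = %.4f, AFE = %.4f, %d iterations%s\n",
              x$k, x$cc, x$afe, x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
print.stage_division <- function(x, ...) {
  cat(sprintf("<stage_division> best k = %d (CC = %.4f, AFE = %.4f)\n",
              x$best_k, x$partition$cc, x$partition$afe))
  print(x$ranges)
  invisible(x)
}
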