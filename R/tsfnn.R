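#' Takagi-Sugeno fuzzy neural network for growth-stage prediction
#'
#' Each of the N rules has Gaussian memberships
#' \eqn{\mu_j^i = \exp(-(x_j - o_j^i)^2 / b_j^i)} per input dimension, a
#' firing strength \eqn{\omega_i = \prod_j \mu_j^i}, and a linear consequent
#' \eqn{y_i = p_0^i + \sum_j p_j^i x_j}; the network output is the
#' firing-normalized combination \eqn{y = \sum_i \bar\omega_i y_i} with
#' \eqn{\bar\omega = \omega / \sum \omega}. Firing strengths are normalized
#' in the log domain, so inputs far from every rule center do not underflow
#' to an undefined output.
#'
#' Training is per-sample gradient descent on the squared error
#' \eqn{e = \frac12 (y_d - y)^2}: consequents move at the learning rate
#' \code{lr}, membership centers and widths at the membership rate
#' \code{gamma}. Targets are the scalar stage indices; predictions are
#' rounded and clamped to \code{[1, k]}.
#'
#' @param x Training inputs (n x h matrix or data frame).
#' @param y Numeric targets (stage indices).
#' @param n_rules Number of rules N; default one per distinct target.
#' @param lr Learning rate for consequent parameters.
#' @param gamma Learning rate for membership centers and widths.
#' @param epochs Maximum training epochs.
#' @param tol Stop early when the mean epoch error falls below this.
#' @param seed Seed controlling rule initialization and per-epoch shuffling.
#' @param width_floor Lower bound kept on membership widths.
#' @param scale_inputs Z-score the inputs before training (default TRUE);
#'   the centering/scaling is stored in the model and applied automatically
#'   by \code{\link{tsfnn_forward}} and \code{\link{predict_stage}}, keeping
#'   gradient steps well-conditioned whatever the raw units.
#' @return A \code{tsfnn} model: list with \code{centers} (N x h),
#'   \code{widths} (N x h), \code{consequents} (N x (h+1), intercept first),
#'   \code{k} (number of stages seen), \code{trace} (mean error per epoch),
#'   \code{epochs_run}.
#' @export
tsfnn_train <- function(x, y, n_rules = NULL, lr = 1e-3, gamma = 1e-3,
                        epochs = 500L, tol = 1e-6, seed = 1L,
                        width_floor = 1e-3, scale_inputs = TRUE) {
  X <- as.matrix(x); storage.mode(X) <- "double"
  shift <- scl <- NULL
  if (scale_inputs) {
    shift <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[!is.finite(scl) | scl == 0] <- 1
    X <- sweep(sweep(X, 2, shift), 2, scl, "/")
  }
  y <- as.numeric(y)
  n <- nrow(X); h <- ncol(X)
  stopifnot(length(y) == n, n >= 1)
  if (lr < 0 || gamma < 0) stop("learning rates must be >= 0", call. = FALSE)
  k <- length(unique(round(y)))
  if (is.null(n_rules)) n_rules <- max(k, 1L)
  N <- as.integer(n_rules)

  model <- withr::with_seed(as.integer(seed), {
    init <- tsfnn_init(X, N, width_floor)
    o <- init$centers; b <- init$widths
    p <- matrix(0, N, h + 1)
    trace <- numeric(0)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      errs <- numeric(n)
      for (s in ord) {
        xs <- X[s, ]
        fw <- tsfnn_eval(o, b, p, xs)
        d <- y[s] - fw$y
        errs[s] <- 0.5 * d^2
        if (lr > 0) {
          # de/dp_j^i = -(yd - y) * wbar_i * x_j  (x_0 := 1)
          p <- p + lr * d * (fw$wbar %o% c(1, xs))
        }
        if (gamma > 0) {
          co <- d * fw$wbar * (fw$yi - fw$y)       # N vector
          dx <- sweep(-o, 2, xs, `+`)              # x_j - o_j^i, N x h
          o <- o + gamma * co * (2 * dx / b)
          b <- pmax(b + gamma * co * (dx^2 / b^2), width_floor)
        }
      }
      trace <- c(trace, mean(errs))
      if (mean(errs) > 1e6) {
        stop("T-S FNN training diverged (mean error > 1e6); ",
             "try a smaller learning rate", call. = FALSE)
      }
      if (mean(errs) < tol) break
    }
    list(centers = o, widths = b, consequents = p, k = k,
         trace = trace, epochs_run = length(trace))
  })
  model$lr <- lr; model$gamma <- gamma
  model$shift <- shift; model$scale <- scl
  structure(model, class = "tsfnn")
}

# FCM rule placement: centers from fuzzy c-means, widths from
# membership-weighted within-cluster variance per dimension
tsfnn_init <- function(X, N, width_floor) {
  n <- nrow(X); h <- ncol(X)
  if (N == 1 || n <= N) {
    ctr <- matrix(colMeans(X), N, h, byrow = TRUE)
    wid <- matrix(pmax(apply(X, 2, stats::var), width_floor), N, h,
                  byrow = TRUE)
    if (anyNA(wid)) wid[] <- 1
    return(list(centers = ctr, widths = wid))
  }
  fit <- tryCatch(e1071::cmeans(jitter_dups(X), centers = N, m = 2,
                                iter.max = 200),
                  error = function(e) NULL)
  if (is.null(fit)) {
    idx <- sample.int(n, N)
    ctr <- X[idx, , drop = FALSE]
    wid <- matrix(pmax(apply(X, 2, stats::var), width_floor), N, h,
                  byrow = TRUE)
    return(list(centers = ctr, widths = wid))
  }
  ctr <- as.matrix(fit$centers)
  U <- fit$membership  # n x N
  wid <- matrix(width_floor, N, h)
  for (i in seq_len(N)) {
    w <- U[, i]
    mu <- colSums(X * w) / sum(w)
    v <- colSums(sweep(X, 2, mu)^2 * w) / sum(w)
    wid[i, ] <- pmax(v, 0) + width_floor
  }
  list(centers = ctr, widths = wid)
}

# core forward evaluation shared by forward pass and training
tsfnn_eval <- function(o, b, p, xs) {
  dx <- sweep(-o, 2, xs, `+`)                 # x_j - o_j^i
  logmu <- -(dx^2) / b                        # N x h
  logw <- rowSums(logmu)
  lw <- logw - max(logw)
  w <- exp(lw)
  wbar <- w / sum(w)
  yi <- p[, 1] + as.vector(p[, -1, drop = FALSE] %*% xs)
  list(mu = exp(logmu), omega = exp(logw), wbar = wbar, yi = yi,
       y = sum(wbar * yi))
}

#' Forward pass of a T-S fuzzy neural network
#'
#' @param model A \code{tsfnn} model.
#' @param x Numeric input vector of length h.
#' @return List with \code{mu} (N x h Gaussian memberships), \code{omega}
#'   (rule firing strengths), \code{wbar} (normalized firings), \code{yi}
#'   (rule consequents) and \code{y} (network output).
#' @export
tsfnn_forward <- function(model, x) {
  stopifnot(inherits(model, "tsfnn"), length(x) == ncol(model$centers))
  x <- as.numeric(x)
  if (!is.null(model$shift)) x <- (x - model$shift) / model$scale
  tsfnn_eval(model$centers, model$widths, model$consequents, x)
}

# analytic gradients of e = .5 (yd - y)^2 at one sample; used by tests
tsfnn_gradients <- function(model, x, yd) {
  fw <- tsfnn_forward(model, x)
  d <- yd - fw$y
  dp <- -d * (fw$wbar %o% c(1, as.numeric(x)))
  co <- -d * fw$wbar * (fw$yi - fw$y)
  dx <- sweep(-model$centers, 2, as.numeric(x), `+`)
  do <- co * (2 * dx / model$widths)
  db <- co * (dx^2 / model$widths^2)
  list(dp = dp, do = do, db = db, e = 0.5 * d^2)
}

#' Predict the growth stage for one or more index vectors
#'
#' The scalar network output is rounded to the nearest integer and clamped
#' to \code{[1, k]}.
#'
#' @param model A \code{tsfnn} model.
#' @param x Numeric vector (one observation) or matrix (rows =
#'   observations).
#' @param k Number of stages; defaults to the count seen in training.
#' @return Integer stage label(s).
#' @export
predict_stage <- function(model, x, k = model$k) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  ys <- apply(x, 1, function(r) tsfnn_forward(model, r)$y)
  as.integer(pmin(pmax(round(ys), 1L), k))
}

#' @export
predict.tsfnn <- function(object, newdata, ...) {
  predict_stage(object, newdata)
}

#' Select growth parameters to sense under a time budget
#'
#' Walks the priority-ordered key features and keeps the longest prefix whose
#' cumulative sensing time stays within the budget.
#'
#' @param features Character vector of key features in priority order.
#' @param times Named numeric vector of per-feature sensing times (s).
#' @param budget Time budget (s).
#' @return Character vector (possibly empty) of selected features.
#' @export
select_growth_params <- function(features, times, budget) {
  if (length(features) == 0) return(character(0))
  tv <- times[features]
  if (anyNA(tv)) stop("sensing time missing for some features", call. = FALSE)
  if (any(tv < 0)) stop("sensing times must be >= 0", call. = FALSE)
  keep <- cumsum(tv) <= budget
  if (any(!keep)) keep[which(!keep)[1]:length(keep)] <- FALSE
  features[keep]
}

#' @export
print.tsfnn <- function(x, ...) {
  cat(sprintf("<tsfnn> %d rules, %d inputs, %d epochs, final error %.3g\n",
              nrow(x$centers), ncol(x$centers), x$epochs_run,
              utils::tail(x$trace, 1)))
  invisible(x)
}
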