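test_that("forward pass matches the rule formulas", {
  # input at a rule's centers: every membership and the firing equal 1
  ctr <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)
  wid <- matrix(1, 2, 2)
  p <- matrix(0, 2, 3)
  m <- manual_tsfnn(ctr, wid, p)
  fw <- tsfnn_forward(m, c(1, 2))
  expect_equal(fw$mu[1, ], c(1, 1))
  expect_equal(fw$omega[1], 1)
  # single rule: normalization cancels, y is exactly linear
  m1 <- manual_tsfnn(matrix(0, 1, 2), matrix(1, 1, 2),
                     matrix(c(1, 2, -3), 1, 3))
  x <- c(0.7, -0.4)
  expect_equal(tsfnn_forward(m1, x)$y, 1 + 2 * 0.7 - 3 * -0.4)
  # random small model vs independent direct formula evaluation
  withr::with_seed(8, {
    ctr <- matrix(rnorm(4), 2, 2); wid <- matrix(runif(4, 0.5, 2), 2, 2)
    p <- matrix(rnorm(6), 2, 3); x <- rnorm(2)
  })
  m2 <- manual_tsfnn(ctr, wid, p)
  mu <- exp(-(sweep(-ctr, 2, x, `+`))^2 / wid)
  om <- apply(mu, 1, prod)
  yi <- p[, 1] + p[, 2:3] %*% x
  y_ref <- sum(om / sum(om) * yi)
  expect_equal(tsfnn_forward(m2, x)$y, y_ref, tolerance = 1e-12)
})

test_that("forward pass is invariant to rule reordering and robust to underflow", {
  withr::with_seed(9, {
    ctr <- matrix(rnorm(6), 3, 2); wid <- matrix(runif(6, 0.5, 2), 3, 2)
    p <- matrix(rnorm(9), 3, 3); x <- rnorm(2)
  })
  m <- manual_tsfnn(ctr, wid, p)
  perm <- c(3, 1, 2)
  mp <- manual_tsfnn(ctr[perm, ], wid[perm, ], p[perm, ])
  expect_equal(tsfnn_forward(m, x)$y, tsfnn_forward(mp, x)$y)
  # far-away input underflows all firings; normalized output stays finite
  far <- manual_tsfnn(matrix(c(0, 1000), 2, 1), matrix(1e-3, 2, 1),
                      matrix(c(1, 0, 2, 0), 2, 2))
  fw <- tsfnn_forward(far, 500)
  expect_true(is.finite(fw$y))
  expect_equal(sum(fw$wbar), 1)
})

test_that("analytic gradients agree with central finite differences", {
  withr::with_seed(21, {
    ctr <- matrix(rnorm(6), 3, 2); wid <- matrix(runif(6, 0.5, 2), 3, 2)
    p <- matrix(rnorm(9), 3, 3)
    x <- rnorm(2); yd <- rnorm(1)
  })
  m <- manual_tsfnn(ctr, wid, p)
  g <- cropsense:::tsfnn_gradients(m, x, yd)
  eps <- 1e-6
  err_at <- function(mm) {
    d <- yd - tsfnn_forward(mm, x)$y
    0.5 * d^2
  }
  check <- function(field, grad) {
    for (i in seq_along(m[[field]])) {
      mp <- m; mp[[field]][i] <- mp[[field]][i] + eps
      mn <- m; mn[[field]][i] <- mn[[field]][i] - eps
      fd <- (err_at(mp) - err_at(mn)) / (2 * eps)
      denom <- max(abs(fd), abs(grad[i]), 1e-8)
      expect_lt(abs(fd - grad[i]) / denom, 1e-5)
    }
  }
  check("consequents", g$dp)
  check("centers", g$do)
  check("widths", g$db)
})

test_that("zero learning rates freeze the parameters", {
  withr::with_seed(2, {
    X <- matrix(rnorm(30), 15, 2)
    y <- sample(1:3, 15, replace = TRUE)
  })
  m <- tsfnn_train(X, y, n_rules = 3, lr = 0, gamma = 0, epochs = 5, seed = 4)
  init <- withr::with_seed(4L, cropsense:::tsfnn_init(
    scale(X), 3L, 1e-3))
  expect_equal(m$consequents, matrix(0, 3, 3))
  expect_equal(m$centers, init$centers)
  expect_equal(m$widths, init$widths)
})

test_that("a single rule on a linear target recovers the regression line", {
  x <- matrix(seq(0, 1, length.out = 25), ncol = 1)
  yd <- 2 * x[, 1] + 1
  m <- tsfnn_train(x, yd, n_rules = 1, lr = 0.05, gamma = 0, epochs = 3000,
                   tol = 1e-9, seed = 1, scale_inputs = FALSE)
  expect_equal(unname(m$consequents[1, ]), c(1, 2), tolerance = 1e-3)
  expect_lt(tail(m$trace, 1), 1e-8)
})

test_that("mean epoch error is non-increasing at a small learning rate", {
  ds <- generate_lifecycle(sim_config(seed = 3))
  sp <- split_stage_groups(ds, c(20, 30, 20), seed = 3)
  m <- tsfnn_train(index_matrix(sp$train), sp$train$stage, n_rules = 3,
                   lr = 1e-3, gamma = 1e-3, epochs = 40, seed = 3)
  expect_true(all(diff(m$trace) <= 1e-6))
})

test_that("training diverges loudly at an absurd learning rate", {
  withr::with_seed(1, {
    X <- matrix(rnorm(40), 20, 2)
    y <- rep(1:2, 10)
  })
  expect_error(tsfnn_train(X, y, n_rules = 2, lr = 50, gamma = 0,
                           epochs = 50, seed = 1),
               "diverged")
})

test_that("stage decoding rounds and clamps the scalar output", {
  m24 <- manual_tsfnn(matrix(0, 1, 1), matrix(1, 1, 1),
                      matrix(c(2.4, 0), 1, 2), k = 3L)
  expect_equal(predict_stage(m24, 0), 2L)
  m7 <- manual_tsfnn(matrix(0, 1, 1), matrix(1, 1, 1),
                     matrix(c(7, 0), 1, 2), k = 3L)
  expect_equal(predict_stage(m7, 0), 3L)
  mneg <- manual_tsfnn(matrix(0, 1, 1), matrix(1, 1, 1),
                       matrix(c(-2, 0), 1, 2), k = 3L)
  expect_equal(predict_stage(mneg, 0), 1L)
})

test_that("held-out stage prediction beats K-NN across seeds", {
  accs <- t(vapply(1:10, function(s) {
    ds <- generate_lifecycle(sim_config(seed = s))
    sp <- split_stage_groups(ds, c(20, 30, 20), seed = s)
    m <- tsfnn_train(index_matrix(sp$train), sp$train$stage, n_rules = 3,
                     epochs = 150, seed = s)
    pred <- predict_stage(m, index_matrix(sp$test))
    knn <- as.integer(as.character(class::knn(
      index_matrix(sp$train), index_matrix(sp$test),
      factor(sp$train$stage), k = 5)))
    c(fnn = mean(pred == sp$test$stage),
      knn = mean(knn == sp$test$stage))
  }, c(fnn = 0, knn = 0)))
  expect_true(all(accs[, "fnn"] >= accs[, "knn"]))
  expect_gte(median(accs[, "fnn"]), 0.96)
})

test_that("growth-parameter selection is a greedy budget prefix", {
  feats <- c("a", "b", "c", "d")
  tm <- c(a = 3, b = 3, c = 3, d = 3)
  expect_equal(select_growth_params(feats, tm, 12), feats)     # budget fits all
  expect_equal(select_growth_params(feats, tm, 7), c("a", "b")) # 2 of 4
  expect_equal(select_growth_params(feats, tm, 0), character(0))
  expect_equal(select_growth_params(character(0), tm, 10), character(0))
  expect_error(select_growth_params(feats, c(a = -1, b = 3, c = 3, d = 3), 5),
               ">= 0")
  expect_error(select_growth_params(c("a", "zz"), tm, 5), "missing")
})

test_that("models survive a JSON round trip", {
  ds <- generate_lifecycle(small_config(seed = 2))
  sp <- split_stage_groups(ds, c(5, 5, 5), seed = 2)
  m <- tsfnn_train(index_matrix(sp$train), sp$train$stage, n_rules = 3,
                   epochs = 30, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_tsfnn_json(m, path)
  m2 <- read_tsfnn_json(path)
  X <- index_matrix(sp$test)
  expect_equal(predict_stage(m2, X), predict_stage(m, X))
  expect_equal(tsfnn_forward(m2, X[1, ])$y, tsfnn_forward(m, X[1, ])$y,
               tolerance = 1e-12)
})
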