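test_that("validity indices match crisp, uniform and hand-computed cases", {
  # crisp partition: CC = 1, AFE = 0
  Uc <- diag(3)[, c(1, 1, 2, 3, 3)]
  v <- partition_validity(Uc)
  expect_equal(v[["cc"]], 1)
  expect_equal(v[["afe"]], 0)
  # maximally fuzzy: CC = 1/k, AFE = ln k
  for (k in 2:5) {
    Uu <- matrix(1 / k, k, 7)
    v <- partition_validity(Uu)
    expect_equal(v[["cc"]], 1 / k)
    expect_equal(v[["afe"]], log(k))
  }
  # 2x2 hand arithmetic
  U <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2)
  v <- partition_validity(U)
  expect_equal(v[["cc"]], (0.64 + 0.04 + 0.09 + 0.49) / 2)
  expect_equal(v[["afe"]],
               -(0.8 * log(0.8) + 0.2 * log(0.2) +
                   0.3 * log(0.3) + 0.7 * log(0.7)) / 2)
  # literal (unsquared) form: column-stochastic U always gives k-independent 1... per column sums
  expect_equal(partition_validity(U, unsquared = TRUE)[["cc"]], 1)
  expect_error(partition_validity(matrix(c(1.2, -0.2, 0.5, 0.5), 2, 2)),
               "\\[0, 1\\]")
})

test_that("validity bounds hold for random memberships", {
  withr::with_seed(11, {
    for (i in 1:20) {
      k <- sample(2:6, 1)
      U <- random_membership(k, 30)
      v <- partition_validity(U)
      expect_gte(v[["cc"]], 1 / k - 1e-12)
      expect_lte(v[["cc"]], 1 + 1e-12)
      expect_gte(v[["afe"]], -1e-12)
      expect_lte(v[["afe"]], log(k) + 1e-12)
    }
  })
})

test_that("validity indices are invariant to cluster relabeling", {
  withr::with_seed(3, {
    U <- random_membership(4, 25)
    v <- partition_validity(U)
    vp <- partition_validity(U[sample(4), ])
    expect_equal(v, vp)
  })
})

test_that("well-separated 1-D groups are recovered from every restart", {
  x <- matrix(c(0, 0.1, 0.2, 10, 10.1, 10.2), ncol = 1)
  grp <- c(1, 1, 1, 2, 2, 2)
  for (s in 1:20) {
    fit <- gg_cluster(x, k = 2, m = 2, seed = s, init = "random")
    lab <- apply(fit$U, 2, which.max)
    # same side for each group, crisp memberships
    expect_true(all(lab[1:3] == lab[1]) && all(lab[4:6] == lab[4]))
    expect_true(lab[1] != lab[4])
    expect_true(all(apply(fit$U, 2, max) > 0.99))
  }
})

test_that("membership columns stay stochastic and bad k is rejected", {
  withr::with_seed(5, {
    X <- matrix(rnorm(60), 20, 3)
    fit <- gg_cluster(X, k = 3, seed = 1)
    expect_equal(colSums(fit$U), rep(1, 20))
    expect_true(all(fit$U >= 0 & fit$U <= 1))
    expect_equal(sum(fit$priors), 1, tolerance = 1e-9)
  })
  expect_error(gg_cluster(matrix(rnorm(10), 5, 2), k = 1), "2 <= k")
  expect_error(gg_cluster(matrix(rnorm(10), 5, 2), k = 6), "2 <= k")
  expect_error(gg_cluster(matrix(rnorm(10), 5, 2), k = 2, m = 1), "m must be")
})

test_that("duplicate data triggers regularization, not a crash", {
  X <- matrix(1, 12, 2)  # all rows identical -> zero covariance path
  fit <- gg_cluster(X, k = 2, seed = 1)
  expect_equal(colSums(fit$U), rep(1, 12))
  expect_true(all(is.finite(fit$U)))
})

test_that("three well-separated synthetic stages are recovered at k = 3", {
  cfg <- sim_config(index_noise_sd = 0, env_noise_sd = 0)
  ds <- generate_lifecycle(cfg)
  div <- divide_growth_stages(ds, k_range = 2:5, seed = 1)
  expect_equal(div$best_k, 3L)
  expect_equal(nrow(div$ranges), 3L)
  expect_true(all(abs(div$ranges$end[1:2] - c(50, 100)) <= 2))
  # stage ranges partition the slots
  expect_equal(div$ranges$start[1], 1L)
  expect_equal(div$ranges$end[3], 150L)
  expect_true(all(div$ranges$start[-1] == head(div$ranges$end, -1) + 1L))
})

test_that("a singleton k range is honoured", {
  ds <- generate_lifecycle(small_config(seed = 2))
  div <- divide_growth_stages(ds, k_range = 2, seed = 1)
  expect_equal(div$best_k, 2L)
})

test_that("key features use population variance, ordering and the theta filter", {
  expect_equal(cropsense:::pop_var(1:5), 2)
  cfg <- small_config(seed = 4)
  ds <- generate_lifecycle(cfg)
  ranges <- tibble::tibble(stage = 1:3, start = c(1L, 21L, 41L),
                           end = c(20L, 40L, 60L))
  # theta = -1 keeps every index, ordered by decreasing variance
  kf <- select_key_features(ds, ranges, theta = -1)
  expect_equal(nrow(kf), 15L)
  expect_true(all(kf$key))
  for (s in 1:3) {
    v <- kf$variance[kf$stage == s]
    expect_true(all(diff(v) <= 0))
    expect_equal(kf$rank[kf$stage == s], 1:5)
  }
  # a constant index has zero variance and is excluded for theta > 0
  ds2 <- ds
  ds2$leaf_color <- 1
  ds2 <- cropsense:::as_lifecycle(ds2, attr(ds, "index_names"),
                                  attr(ds, "env_names"))
  kf2 <- select_key_features(ds2, ranges, theta = 1e-6)
  expect_false(any(kf2$key[kf2$index == "leaf_color"]))
  expect_error(select_key_features(ds, tibble::tibble(stage = 1, start = 5L,
                                                      end = 4L)),
               "empty stage")
})

test_that("default-noise lifecycle yields a near-crisp partition at the true k", {
  # between-stage separation >= 10x within-stage spread by construction
  ds <- generate_lifecycle(sim_config(seed = 6))
  div <- divide_growth_stages(ds, k_range = 2:5, seed = 6)
  expect_equal(div$best_k, 3L)
  expect_gte(div$partition$cc, 0.99)
  expect_lte(div$partition$afe, 0.1)
})
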