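test_that("sensing time is a plain sum over selected parameters", {
  tm <- stats::setNames(rep(3, 10), paste0("p", 1:10))
  expect_equal(sensing_time(paste0("p", 1:10), tm), 30)  # all-sensors baseline
  expect_equal(sensing_time(character(0), tm), 0)
  expect_equal(sensing_time(c("a", "b"), c(a = 0.1, b = 3)), 3.1)
  expect_error(sensing_time("zz", tm), "missing")
})

test_that("collection time follows the serial-uplink model", {
  # nominal cluster: 20 nodes x 10 parameters x 10 bits at 100 b/s + 30 s
  expect_equal(collection_time(20, paste0("p", 1:10), 10, 100, 30), 50)
  # infinite-rate limit leaves only the sensing time
  expect_equal(collection_time(20, paste0("p", 1:10), 10, 1e12, 30), 30,
               tolerance = 1e-6)
  # doubling the rate halves the transmission term exactly
  t1 <- collection_time(20, paste0("p", 1:10), 10, 100, 0)
  t2 <- collection_time(20, paste0("p", 1:10), 10, 200, 0)
  expect_equal(t1, 2 * t2)
  expect_error(collection_time(20, "a", 10, 0, 1), "> 0")
})

test_that("data value sums scores and scales by coverage", {
  vals <- tibble::tibble(param = c("a", "b"), value = c(40, 30))
  dv <- data_value(c("a", "b"), vals, area_eff = 7000, area_total = 10000)
  expect_equal(dv[["total"]], 70)
  expect_equal(dv[["effective"]], 49)
  full <- data_value(c("a", "b"), vals, 10000, 10000)
  expect_equal(full[["effective"]], full[["total"]])
  expect_equal(data_value(character(0), vals, 5000, 10000),
               c(total = 0, effective = 0))
})

test_that("per-unit metric identities reproduce the printed baseline figures", {
  # printed total data value 227.20 over 20 nodes and full-region coverage
  pm <- cropsense:::per_unit_metrics(227.20, t_sense = 30, n_nodes = 20,
                                     area_eff = 10000)
  expect_equal(pm[["pdv_ns"]], 11.36)
  expect_equal(round(pm[["pdv_ea"]], 4), 0.0227)
  # the identities invert exactly
  expect_equal(pm[["pdv_st"]] * 30, 227.20)
  expect_equal(pm[["pdv_ns"]] * 20, 227.20)
  expect_equal(pm[["pdv_ea"]] * 10000, 227.20)
})

test_that("strategies produce consistent metric rows", {
  cfg <- sim_config(seed = 1)
  ds <- generate_lifecycle(cfg)
  div <- divide_growth_stages(ds, k_range = 3, seed = 1)
  sp <- split_stage_groups(ds, c(20, 30, 20), seed = 1)
  model <- tsfnn_train(index_matrix(sp$train), sp$train$stage, n_rules = 3,
                       epochs = 100, seed = 1)
  field <- generate_sensor_field(cfg)
  x_now <- index_matrix(sp$test)[1, ]

  ans <- run_strategy("ANS", ds, field, cfg, stage = 1)
  expect_equal(ans$n_params, 10L)
  expect_equal(ans$n_nodes, 20L)
  expect_equal(ans$t_sense, 30)
  pns <- run_strategy("PNS", ds, field, cfg, stage = 1, seed = 3)
  expect_equal(pns$n_nodes, 15L)
  expect_equal(pns$n_params, 5L)
  asm <- run_strategy("ASM", ds, field, cfg, division = div, model = model,
                      x_now = x_now)
  expect_equal(asm$stage, 1L)           # prediction feeds the pipeline
  expect_equal(asm$n_params, 4L)        # Tse = 12 s at 3 s per parameter
  expect_lt(asm$n_nodes, ans$n_nodes)
  expect_gte(asm$area_eff, cfg$area_limit)
  # metric identities hold exactly on every row
  for (row in list(ans, pns, asm)) {
    expect_equal(row$pdv_st * row$t_sense, row$tdv)
    expect_equal(row$pdv_ns * row$n_nodes, row$tdv)
    expect_equal(row$pdv_ea * row$area_eff, row$tdv)
  }
  # determinism end to end
  asm2 <- run_strategy("ASM", ds, field, cfg, division = div, model = model,
                       x_now = x_now)
  expect_identical(asm, asm2)
  expect_error(run_strategy("ASM", ds, field, cfg), "needs")
})

test_that("experiment sweeps reproduce the time orderings and trends", {
  cfg <- sim_config(seed = 4)
  ds <- generate_lifecycle(cfg)
  div <- divide_growth_stages(ds, k_range = 3, seed = 4)
  sp <- split_stage_groups(ds, c(20, 30, 20), seed = 4)
  model <- tsfnn_train(index_matrix(sp$train), sp$train$stage, n_rules = 3,
                       epochs = 100, seed = 4)
  field <- generate_sensor_field(cfg)
  x_now <- index_matrix(sp$test)[1, ]
  grid <- run_experiment(ds, field, cfg, division = div, model = model,
                         x_now = x_now, sst_values = c(1, 2, 3),
                         vc_values = c(50, 100, 200), seeds = 1)
  # sensing time is linear in SST for the all-sensors baseline
  ans <- grid[grid$method == "ANS" & grid$vc == 100, ]
  expect_equal(ans$t_sense[order(ans$sst)], c(10, 20, 30))
  # adaptive < partial < all-sensors at every SST
  for (s in c(1, 2, 3)) {
    sub <- grid[grid$sst == s & grid$vc == 100, ]
    expect_lt(sub$t_sense[sub$method == "ASM"],
              sub$t_sense[sub$method == "PNS"])
    expect_lt(sub$t_sense[sub$method == "PNS"],
              sub$t_sense[sub$method == "ANS"])
  }
  # collection time is non-increasing in the communication rate
  for (m in c("ANS", "PNS", "ASM")) {
    sub <- grid[grid$method == m & grid$sst == 2, ]
    expect_true(all(diff(sub$t_collect[order(sub$vc)]) <= 1e-9))
  }
})

test_that("the adaptive strategy dominates the per-unit value metrics on average", {
  cfg <- sim_config(seed = 1)
  ds <- generate_lifecycle(cfg)
  div <- divide_growth_stages(ds, k_range = 3, seed = 1)
  sp <- split_stage_groups(ds, c(20, 30, 20), seed = 1)
  model <- tsfnn_train(index_matrix(sp$train), sp$train$stage, n_rules = 3,
                       epochs = 100, seed = 1)
  x_now <- index_matrix(sp$test)[1, ]
  rows <- dplyr::bind_rows(lapply(1:10, function(s) {
    field <- generate_sensor_field(cfg, seed = 100 + s)
    dplyr::bind_rows(
      run_strategy("ANS", ds, field, cfg, stage = 1),
      run_strategy("PNS", ds, field, cfg, stage = 1, seed = s),
      run_strategy("ASM", ds, field, cfg, division = div, model = model,
                   x_now = x_now))
  }))
  agg <- dplyr::summarise(
    dplyr::group_by(rows, method),
    dplyr::across(c(pdv_st, pdv_ns, pdv_ea, area_eff, n_nodes), mean))
  asm <- agg[agg$method == "ASM", ]
  for (m in c("ANS", "PNS")) {
    other <- agg[agg$method == m, ]
    expect_gt(asm$pdv_st, other$pdv_st)
    expect_gt(asm$pdv_ns, other$pdv_ns)
    expect_gt(asm$pdv_ea, other$pdv_ea)
  }
  # the all-nodes baseline still dominates raw coverage
  expect_gte(agg$area_eff[agg$method == "ANS"], max(agg$area_eff))
  expect_lt(asm$n_nodes, 20)
})
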