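test_that("count allocation is proportional with a floor of five", {
  g4 <- aft_graph(data.frame(from = c("A", "B", "C"), to = c("B", "C", "D")))
  K <- allocate_counts(g4, J = 1, weights = rep(1, 4), total = 40)
  expect_equal(unname(K[, 1]), rep(10L, 4))
  g2 <- path_graph(2)
  K2 <- allocate_counts(g2, J = 1, weights = c(1, 3), total = 40)
  expect_equal(unname(K2[, 1]), c(10L, 30L))
  # floor rule
  K3 <- allocate_counts(g4, J = 2, weights = c(100, 1, 1, 1), total = 100)
  expect_true(all(K3 >= 5))
  expect_error(allocate_counts(g4, J = 2, total = 30), "5 subjects")
  # identical across cohorts
  K4 <- allocate_counts(g4, J = 3, total = 90)
  expect_true(all(K4[, 1] == K4[, 2] & K4[, 2] == K4[, 3]))
})

test_that("intrinsic CAR draws live on the zero-sum subspace", {
  g <- lattice_graph(3, 3)
  set.seed(10)
  draws <- t(replicate(2000, rcar(g, tau2 = 1.5)))
  expect_lt(max(abs(rowSums(draws))), 1e-8)
  # contrast variance matches the pseudo-inverse covariance
  Sig <- 1.5 * MASS::ginv(car_structure_matrix(g))
  v_emp <- stats::var(draws[, 1] - draws[, 2])
  v_thy <- Sig[1, 1] + Sig[2, 2] - 2 * Sig[1, 2]
  expect_lt(abs(v_emp / v_thy - 1), 0.15)
})

test_that("scenario generation honours its stated structure", {
  spec <- small_scenario("S4", J = 5)
  d <- generate_scenario(spec, seed = 1)
  tr <- attr(d, "truth")
  # S4 truth stored exactly
  expect_identical(tr$xi_true, c(0, 0.5, -0.5, 0.6, -0.8))
  expect_identical(tr$beta, c(1, 0.5))
  # schema: consumable by the fitting interface without transformation
  expect_true(all(c("time", "event", "unit", "year", "x1", "x2") %in%
                  names(d)))
  expect_true(all(d$event %in% 0:1))
  expect_true(all(d$time > 0))
  expect_equal(nrow(d), sum(tr$K))
  expect_true(all(tr$K >= 5))

  # censoring disabled: every record is an event
  spec0 <- small_scenario("S1", censoring = NA)
  d0 <- generate_scenario(spec0, seed = 2)
  expect_true(all(d0$event == 1L))

  # different seeds give different data with the same schema
  d1 <- generate_scenario(spec, seed = 11)
  d2 <- generate_scenario(spec, seed = 12)
  expect_identical(names(d1), names(d2))
  expect_false(identical(d1$time, d2$time))

  # county-level variant: x1 constant within county
  specc <- small_scenario("S2")
  specc$covariate_level <- "county"
  dc <- generate_scenario(specc, seed = 3)
  spread <- tapply(dc$x1, dc$unit, function(v) diff(range(v)))
  expect_true(all(spread == 0))
})

test_that("censoring calibration hits the target rate on average", {
  spec <- small_scenario("S1", censoring = 0.2)
  rates <- vapply(1:20, function(s) {
    attr(generate_scenario(spec, seed = 100 + s), "truth")$achieved_censoring
  }, 1.0)
  expect_lt(abs(mean(rates) - 0.20), 0.03)
  spec8 <- small_scenario("S1", censoring = 0.8)
  rates8 <- vapply(1:10, function(s) {
    attr(generate_scenario(spec8, seed = 100 + s), "truth")$achieved_censoring
  }, 1.0)
  expect_lt(abs(mean(rates8) - 0.80), 0.03)
})

test_that("Monte Carlo aggregation reproduces hand-computed summaries", {
  # stubbed estimates: (1.1, 0.9) over 2 reps for beta1
  stub <- tibble::tibble(
    rep = c(1L, 2L), model = "M2",
    beta1 = c(1.1, 0.9), beta2 = c(0.5, 0.5),
    sigma = 1, dic = c(10, 11), p_d = 1, censoring = 0.2)
  attr(stub, "truth_beta") <- c(1, 0.5)
  s <- summarize_mc(stub)
  b1 <- s$estimates[s$estimates$parameter == "beta1", ]
  expect_equal(b1$bias, 0)
  expect_equal(b1$sd, stats::sd(c(1.1, 0.9)))
  expect_equal(b1$mse, 0.01)
  b2 <- s$estimates[s$estimates$parameter == "beta2", ]
  expect_equal(b2$bias, 0)
  expect_equal(b2$sd, 0)
  expect_equal(b2$mse, 0)

  # exact-truth stub: all summaries collapse to zero
  stub2 <- stub
  stub2$beta1 <- c(1, 1); stub2$beta2 <- c(0.5, 0.5)
  attr(stub2, "truth_beta") <- c(1, 0.5)
  s2 <- summarize_mc(stub2)
  expect_true(all(s2$estimates$bias == 0 & s2$estimates$sd == 0 &
                  s2$estimates$mse == 0))

  # selection frequencies sum to one and a formatted table round-trips
  stub3 <- dplyr::bind_rows(
    dplyr::mutate(stub, model = "M1", dic = c(20, 20)),
    dplyr::mutate(stub, model = "M2", dic = c(10, 30)),
    dplyr::mutate(stub, model = "M3", dic = c(15, 12)))
  attr(stub3, "truth_beta") <- c(1, 0.5)
  s3 <- summarize_mc(stub3)
  expect_equal(sum(s3$selection$freq), 1)
  expect_equal(s3$selection$freq[s3$selection$model == "M2"], 0.5)
  tab <- summarize_tables(list(S1 = s3))
  expect_equal(nrow(tab), 6) # 3 models x 2 parameters
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, f, row.names = FALSE)
  back <- utils::read.csv(f)
  expect_equal(back$S1_bias, tab$S1_bias)
})

test_that("a short study runs end to end with caching", {
  spec <- small_scenario("S1", J = 3, total = 5 * 6 * 3 + 30)
  cache <- withr::local_tempdir()
  mc <- run_mc_study(spec, models = "M2", n_reps = 2,
                     chain = fast_chain(1, 150, 150), seed = 5,
                     cache_dir = cache)
  expect_equal(nrow(mc), 2)
  expect_true(all(file.exists(file.path(cache,
                                        sprintf("rep_%04d.csv", 1:2)))))
  # resumption reuses cached replicates byte-for-byte
  mc2 <- run_mc_study(spec, models = "M2", n_reps = 2,
                      chain = fast_chain(1, 150, 150), seed = 5,
                      cache_dir = cache)
  expect_equal(as.data.frame(mc), as.data.frame(mc2))
  expect_s3_class(plot_mc_estimates(mc), "ggplot")
})

test_that("ignoring temporal drift biases the spatial-only model most", {
  # random-walk frailty scenario: the spatial-only model attenuates the
  # covariate effect far more than the random-slope model
  g <- pa_county_graph()
  spec <- scenario_spec("S3", graph = g, target_censoring = 0.20)
  mc <- run_mc_study(spec, models = c("M1", "M2"), n_reps = 30,
                     chain = chain_control(n_burnin = 1000, n_keep = 1000,
                                           seed = 1),
                     seed = 404)
  b_m1 <- mean(mc$beta1[mc$model == "M1"]) - 1
  b_m2 <- mean(mc$beta1[mc$model == "M2"]) - 1
  expect_gt(abs(b_m1), abs(b_m2))
})

test_that("a county-level covariate inflates the spread of its estimate", {
  g <- pa_county_graph()
  ch <- chain_control(n_burnin = 1000, n_keep = 1000, seed = 1)
  spec_subj <- scenario_spec("S1", graph = g, target_censoring = 0.20)
  spec_cty <- scenario_spec("S1", graph = g, target_censoring = 0.20,
                            covariate_level = "county")
  mc_subj <- run_mc_study(spec_subj, models = "M2", n_reps = 15,
                          chain = ch, seed = 505)
  mc_cty <- run_mc_study(spec_cty, models = "M2", n_reps = 15,
                         chain = ch, seed = 505)
  expect_gt(stats::sd(mc_cty$beta1), stats::sd(mc_subj$beta1))
})
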