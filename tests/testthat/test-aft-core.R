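test_that("standardised residual laws match their closed forms", {
  # extreme value at the location point: S = exp(-1)
  expect_equal(log_survival(exp(1.5), 1.5, 2, "weibull"), -1)
  # logistic median
  expect_equal(exp(log_survival(1, 0, 1, "loglogistic")), 0.5)
  # direct evaluation: mu' = 0, sigma = 1, t = 2 -> log S = -exp(log 2) = -2
  expect_equal(log_survival(2, 0, 1, "weibull"), -2)
  # log f at t = 1, mu' = 0, sigma = 1: f_eps(0) = e^-1, 1/(sigma t) = 1
  expect_equal(log_density(1, 0, 1, "weibull"), -1)
  expect_error(log_survival(-1, 0, 1), "positive")
  expect_error(log_density(1, 0, -1), "positive")
})

test_that("each family's density is normalised and consistent with survival", {
  for (fam in c("weibull", "loglogistic", "lognormal")) {
    total <- stats::integrate(function(t) exp(log_density(t, 0, 1, fam)),
                              lower = 1e-12, upper = Inf,
                              rel.tol = 1e-8)$value
    expect_equal(total, 1, tolerance = 1e-4)
    # f = -dS/dt by central differences
    t0 <- c(0.3, 1, 2.7)
    h <- 1e-5
    dS <- (exp(log_survival(t0 + h, 0.2, 0.7, fam)) -
           exp(log_survival(t0 - h, 0.2, 0.7, fam))) / (2 * h)
    expect_equal(-dS, exp(log_density(t0, 0.2, 0.7, fam)), tolerance = 1e-5)
  }
})

test_that("weibull family reproduces stats/flexsurv parametric forms", {
  t <- c(0.2, 1, 3, 10)
  mu <- 0.4; sig <- 0.8
  expect_equal(log_survival(t, mu, sig, "weibull"),
               stats::pweibull(t, shape = 1 / sig, scale = exp(mu),
                               lower.tail = FALSE, log.p = TRUE))
  expect_equal(log_density(t, mu, sig, "weibull"),
               stats::dweibull(t, shape = 1 / sig, scale = exp(mu),
                               log = TRUE))
  expect_equal(log_density(t, mu, sig, "lognormal"),
               stats::dlnorm(t, meanlog = mu, sdlog = sig, log = TRUE))
  skip_if_not_installed("flexsurv")
  expect_equal(log_density(t, mu, sig, "loglogistic"),
               flexsurv::dllogis(t, shape = 1 / sig, scale = exp(mu),
                                 log = TRUE))
})

test_that("log survival is monotone in t and increasing in mu'", {
  t <- seq(0.1, 20, length.out = 50)
  for (fam in c("weibull", "loglogistic", "lognormal")) {
    ls <- log_survival(t, 0.5, 1.2, fam)
    expect_true(all(diff(ls) < 0))
    expect_true(all(log_survival(5, 1, 1, fam) > log_survival(5, 0, 1, fam)))
  }
})

test_that("linear predictors follow the candidate model formulas", {
  g <- path_graph(3)
  d <- tibble::tibble(unit_index = c(1L, 2L), cohort_index = c(3L, 1L),
                      x1 = c(1, 0), x2 = c(1, 2))
  # all parameters zero -> 0 under every model
  for (m in c("M1", "M2", "M3")) {
    spec <- staft_model(m, J = 5, p = 2)
    st <- staft_state(0, c(0, 0), rep(0, spec$n_xi),
                      matrix(0, 3, spec$q), 1, spec)
    expect_equal(linear_predictor(d, st, spec), c(0, 0))
  }
  # M2 arithmetic: mu=1, beta=(1,0.5), x=(1,1), xi=0.5, z=2, frailties 0
  spec2 <- staft_model("M2", J = 5, p = 2)
  st2 <- staft_state(1, c(1, 0.5), 0.5, matrix(0, 3, 2), 1, spec2)
  expect_equal(linear_predictor(d, st2, spec2)[1], 3.5)
  # M3 with degenerate gamma agrees with direct evaluation on one cohort
  spec3 <- staft_model("M3", J = 5, p = 2)
  st3 <- staft_state(1, c(1, 0.5), c(0.7, 0, 0, 0), matrix(0, 3, 6), 1, spec3)
  d2 <- tibble::tibble(unit_index = 1L, cohort_index = 2L, x1 = 2, x2 = 0)
  expect_equal(linear_predictor(d2, st3, spec3), 1 + 2 + 0.7)
  # reference cohort gets no xi contribution
  d3 <- tibble::tibble(unit_index = 1L, cohort_index = 1L, x1 = 2, x2 = 0)
  expect_equal(linear_predictor(d3, st3, spec3), 3)
  # cohort out of range rejected
  d4 <- tibble::tibble(unit_index = 1L, cohort_index = 7L, x1 = 0, x2 = 0)
  expect_error(linear_predictor(d4, st3, spec3), "cohort")
})

test_that("conditional log-likelihood sums per-record terms correctly", {
  g <- path_graph(3)
  dat <- prepare_survival_data(toy_data(g, J = 2, K = 3), g, c("x1", "x2"))
  spec <- staft_model("M2", J = 2, p = 2)
  st <- random_state(spec, g, seed = 11)

  lp <- linear_predictor(dat, st, spec)
  # term-by-term oracle through the closed-form Weibull density/survival
  oracle <- sum(ifelse(
    dat$event == 1,
    stats::dweibull(dat$time, 1 / st$sigma, exp(lp), log = TRUE),
    stats::pweibull(dat$time, 1 / st$sigma, exp(lp), lower.tail = FALSE,
                    log.p = TRUE)))
  expect_equal(conditional_loglik(dat, st, spec), oracle, tolerance = 1e-10)

  # all-event and all-censored reductions
  d1 <- dat; d1$event <- 1L
  expect_equal(conditional_loglik(d1, st, spec),
               sum(log_density(d1$time, lp, st$sigma, "weibull")))
  d0 <- dat; d0$event <- 0L
  expect_equal(conditional_loglik(d0, st, spec),
               sum(log_survival(d0$time, lp, st$sigma, "weibull")))

  # invariant to record order
  perm <- sample(nrow(dat))
  expect_equal(conditional_loglik(dat[perm, ], st, spec),
               conditional_loglik(dat, st, spec))

  expect_error(conditional_loglik(dat[0, ], st, spec), "empty")
})

test_that("data preparation validates events, times, and unit labels", {
  g <- path_graph(3)
  d <- toy_data(g, J = 2, K = 2)
  d$event[5] <- 2
  expect_error(prepare_survival_data(d, g, c("x1", "x2")), "row 5")
  d2 <- toy_data(g, J = 2, K = 2)
  d2$unit[1] <- "Z"
  expect_error(prepare_survival_data(d2, g, c("x1", "x2")), "Z")
  d3 <- toy_data(g, J = 2, K = 2)
  ok <- prepare_survival_data(d3, g, c("x1", "x2"))
  expect_equal(attr(ok, "I"), 3)
  expect_equal(attr(ok, "J"), 2)
  expect_equal(sum(cell_counts(ok)$K), nrow(d3))
})
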