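test_that("CAR log-density matches its quadratic form and is intrinsic", {
  g <- path_graph(3)
  expect_equal(car_log_density(rep(0, 3), g, tau2 = 2),
               -(3 - 1) / 2 * log(2))
  # 3-node path, omega = (1, 0, -1): quadratic form 2, contribution -1
  expect_equal(car_log_density(c(1, 0, -1), g, tau2 = 1), -1)
  # adding a constant on a connected graph changes nothing
  set.seed(3)
  w <- rnorm(3)
  expect_equal(car_log_density(w + 5, g, 0.7), car_log_density(w, g, 0.7))
})

test_that("CAR full conditional is the neighbour mean with variance tau2/n_i", {
  g <- path_graph(3)
  fc <- car_full_conditional(2, c(2, 99, 4), g, tau2 = 1.4)
  expect_equal(fc$mean, 3)
  expect_equal(fc$variance, 1.4 / 2)
  expect_false(fc$island)
  expect_equal(car_full_conditional(1, c(9, 0, 0), g, 1)$mean, 0)

  # island: flagged, marginal N(0, tau2)
  gi <- aft_graph(data.frame(from = "A", to = "B"),
                  labels = c("A", "B", "C"))
  fci <- car_full_conditional(3, c(1, 2, 3), gi, 2.5)
  expect_true(fci$island)
  expect_equal(fci$variance, 2.5)
})

test_that("full conditional agrees with Gaussian conditioning on a 4-node graph", {
  # Gaussian-conditioning (Schur complement) oracle applied to the joint
  # precision Q/tau2: x_i | x_-i is N(-P_ii^-1 sum_j P_ij x_j, 1/P_ii),
  # proper even though the joint is intrinsic.
  g <- aft_graph(data.frame(from = c("A", "A", "B", "C"),
                            to   = c("B", "C", "C", "D")))
  tau2 <- 1.7
  Q <- car_structure_matrix(g) / tau2
  set.seed(42)
  w <- rnorm(4)
  for (i in 1:4) {
    prec_ii <- Q[i, i]
    cond_var <- 1 / prec_ii
    cond_mean <- -cond_var * sum(Q[i, -i] * w[-i])
    fc <- car_full_conditional(i, w, g, tau2)
    expect_equal(fc$mean, cond_mean, tolerance = 1e-12)
    expect_equal(fc$variance, cond_var, tolerance = 1e-12)
  }
})

test_that("MCAR log-density reduces to CAR and matches the Kronecker form", {
  g <- path_graph(3)
  # q = 1, Lambda = 1/tau2 reduction on random inputs
  set.seed(5)
  for (r in 1:5) {
    w <- rnorm(3)
    tau2 <- runif(1, 0.3, 3)
    expect_equal(mcar_log_density(matrix(w, 3, 1), g, matrix(1 / tau2)),
                 car_log_density(w, g, tau2), tolerance = 1e-12)
  }
  # q = 2 dense Kronecker-product oracle, vec stacking unit blocks
  Delta <- matrix(c(0.5, -1, 0.5, 1, 0, -1), nrow = 3)
  Lambda <- rbind(c(2, 0.3), c(0.3, 1))
  Q <- car_structure_matrix(g)
  vecD <- as.vector(t(Delta)) # (Delta_1', Delta_2', Delta_3')
  oracle <- (3 - 1) / 2 * determinant(Lambda)$modulus[1] -
    0.5 * drop(t(vecD) %*% (Q %x% Lambda) %*% vecD)
  expect_equal(mcar_log_density(Delta, g, Lambda), oracle, tolerance = 1e-10)
  # zero block: quadratic term vanishes
  expect_equal(mcar_log_density(matrix(0, 3, 2), g, Lambda),
               (3 - 1) / 2 * determinant(Lambda)$modulus[1])
  # invariance to a constant row shift on a connected graph
  shifted <- sweep(Delta, 2, c(2, -1), "+")
  expect_equal(mcar_log_density(shifted, g, Lambda),
               mcar_log_density(Delta, g, Lambda), tolerance = 1e-10)
  expect_error(mcar_log_density(Delta, g, rbind(c(1, 2), c(2, 1))),
               "positive definite")
})

test_that("V matches the pairwise-difference oracle and the trace identity", {
  g <- lattice_graph(3, 3)
  set.seed(9)
  Delta <- matrix(rnorm(g$I * 2), g$I, 2)
  V <- compute_V(Delta, g)
  # brute force over adjacent pairs
  Vb <- matrix(0, 2, 2)
  for (i in seq_len(g$I - 1)) {
    for (k in (i + 1):g$I) {
      if (g$C[i, k] == 1) {
        d <- Delta[i, ] - Delta[k, ]
        Vb <- Vb + outer(d, d)
      }
    }
  }
  expect_equal(unname(V), Vb, tolerance = 1e-10)
  expect_equal(compute_V(matrix(0, g$I, 2), g), matrix(0, 2, 2),
               ignore_attr = TRUE)
  # q = 1: V is the CAR quadratic form
  w <- rnorm(g$I)
  expect_equal(drop(compute_V(matrix(w), g)),
               drop(t(w) %*% car_structure_matrix(g) %*% w))
  # trace(Lambda V) equals the Kronecker quadratic form
  Lambda <- rbind(c(1.5, -0.2), c(-0.2, 0.8))
  vecD <- as.vector(t(Delta))
  expect_equal(sum(Lambda * V),
               drop(t(vecD) %*% (car_structure_matrix(g) %x% Lambda) %*% vecD),
               tolerance = 1e-8)
})

test_that("Wishart full conditional has the conjugate parameters", {
  g <- path_graph(4)
  # Delta = 0: posterior is the prior scale with df p + I
  fc0 <- lambda_full_conditional(matrix(0, 4, 2), g)
  expect_equal(fc0$df, 2 + 4)
  expect_equal(fc0$scale, diag(100, 2), tolerance = 1e-8)

  set.seed(21)
  Delta <- matrix(rnorm(8, sd = 0.7), 4, 2)
  fc <- lambda_full_conditional(Delta, g)
  # Monte Carlo oracle: mean of Wishart(df, S) draws is df * S
  draws <- stats::rWishart(10000, fc$df, fc$scale)
  expect_equal(apply(draws, c(1, 2), mean), fc$df * fc$scale,
               tolerance = 0.05)

  # q = 1 scalar conjugacy oracle: precision lambda = 1/tau2 with prior
  # Gamma(shape p/2, rate 1/(2 R)) has full conditional
  # Gamma(shape (p + I)/2, rate (1/R + quadform)/2); the Wishart(p + I,
  # (R^-1 + V)^-1) matches that exactly
  w <- rnorm(4)
  R <- 100
  fc1 <- lambda_full_conditional(matrix(w), g, wishart_df = 1,
                                 wishart_scale = matrix(R))
  quadform <- drop(t(w) %*% car_structure_matrix(g) %*% w)
  expect_equal(drop(fc1$scale), 1 / (1 / R + quadform), tolerance = 1e-12)
  # Gamma(a, b) mean a/b equals Wishart mean df * scale
  a <- (1 + 4) / 2
  b <- (1 / R + quadform) / 2
  expect_equal(fc1$df * drop(fc1$scale), a / b, tolerance = 1e-12)
})
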