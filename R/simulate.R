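#' Allocate per-(unit, cohort) subject counts
#'
#' Distributes a total subject budget across units proportionally to
#' `weights` with largest-remainder rounding, identically across the `J`
#' cohorts, and floors every cell at 5 subjects (mimicking a registry in
#' which every county contributes at least five patients each year).
#'
#' @param graph An `aft_graph`.
#' @param J Number of cohorts.
#' @param weights Per-unit non-negative weights (default: degree-smoothed
#'   uniform, `degree + 1`).
#' @param total Total subject budget across all cells; must be at least
#'   `5 * I * J`.
#' @return An `I x J` integer matrix `K` with `K[i, j] >= 5`.
#' @export
allocate_counts <- function(graph, J, weights = NULL, total = 2000) {
  stopifnot(inherits(graph, "aft_graph"), J >= 1)
  I <- graph$I
  if (is.null(weights)) weights <- rowSums(graph$C) + 1
  stopifnot(length(weights) == I, all(weights >= 0), sum(weights) > 0)
  if (total < 5 * I * J) {
    stop("total ", total, " cannot give every cell 5 subjects (need >= ",
         5 * I * J, ")", call. = FALSE)
  }
  per_cohort <- largest_remainder(total / J, weights)
  per_cohort <- pmax(per_cohort, 5L)
  matrix(rep(per_cohort, J), nrow = I, ncol = J,
         dimnames = list(graph$unit_labels, NULL))
}

# integer allocation of `total` proportional to `weights`
largest_remainder <- function(total, weights) {
  share <- total * weights / sum(weights)
  base <- floor(share)
  rem <- round(total) - sum(base)
  if (rem > 0) {
    extra <- order(share - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Draw spatial frailties from the intrinsic CAR prior
#'
#' Samples from the singular Gaussian with precision kernel
#' `(D_omega - C) / tau2` restricted to the zero-sum subspace of each
#' connected component, via the spectral pseudo-inverse of the structure
#' matrix.  Islands are drawn independently as `N(0, tau2)`.
#'
#' @param graph An `aft_graph`.
#' @param tau2 Conditional variance parameter.
#' @return Numeric vector of length `graph$I`, summing to zero within each
#'   non-trivial connected component.
#' @export
rcar <- function(graph, tau2 = 1) {
  Q <- car_structure_matrix(graph)
  eg <- eigen(Q, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  U <- eg$vectors[, pos, drop = FALSE]
  lam <- eg$values[pos]
  omega <- drop(U %*% (stats::rnorm(length(lam)) * sqrt(tau2 / lam)))
  islands <- rowSums(graph$C) == 0
  if (any(islands)) omega[islands] <- stats::rnorm(sum(islands), 0, sqrt(tau2))
  omega
}

#' Simulation scenario specification
#'
#' Four generating mechanisms for the log survival time
#' `log T = mu0 + x1 + 0.5 x2 + (spatial-temporal part) + eps`, with
#' `x1 ~ N(0, 1)` (subject-level, or constant within unit for the
#' county-level variant), `x2 ~ Bernoulli(0.5)`, `eps` standard
#' extreme-value, and `omega` an intrinsic CAR draw on the graph:
#'
#' * `S1`: linear cohort trend `+ omega_i + 0.5 (j - 1)`
#' * `S2`: square-root cohort trend `+ omega_i + 0.5 sqrt(j - 1)`
#' * `S3`: explosive random-walk frailty `+ omega_ij`, with
#'   `omega_i1 = omega_i` and `omega_ij = 2 omega_{i,j-1} + zeta`,
#'   `zeta ~ N(0, 1)`
#' * `S4`: categorical cohort effects `+ omega_i + xi_j`,
#'   `xi = (0, 0.5, -0.5, 0.6, -0.8)`
#'
#' Censoring times are uniform `(0, c)` with `c` calibrated per dataset so
#' the expected censoring fraction matches `target_censoring`.
#'
#' @param scenario `"S1"`, `"S2"`, `"S3"` or `"S4"`.
#' @param graph An `aft_graph` (default the 67-county Pennsylvania graph).
#' @param J Number of cohorts (default 5; S4 requires `J = 5`).
#' @param covariate_level `"subject"` or `"county"` (the county-level `x1`
#'   variant).
#' @param target_censoring Target censoring fraction in (0, 1), or `NA` to
#'   disable censoring.
#' @param mu0 Generating intercept.
#' @param tau2 Conditional variance of the generating CAR frailty.
#' @param total Subject budget passed to [allocate_counts()].
#' @param weights Optional per-unit allocation weights.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario = c("S1", "S2", "S3", "S4"),
                          graph = NULL, J = 5,
                          covariate_level = c("subject", "county"),
                          target_censoring = 0.20,
                          mu0 = 0.5, tau2 = 1, total = 2000,
                          weights = NULL) {
  scenario <- match.arg(scenario)
  covariate_level <- match.arg(covariate_level)
  if (is.null(graph)) graph <- pa_county_graph()
  stopifnot(J >= 2)
  if (scenario == "S4" && J != 5) stop("S4 is defined for J = 5", call. = FALSE)
  if (!is.na(target_censoring)) {
    stopifnot(target_censoring > 0, target_censoring < 1)
  }
  xi_true <- if (scenario == "S4") c(0, 0.5, -0.5, 0.6, -0.8) else NULL
  structure(list(scenario = scenario, graph = graph, J = as.integer(J),
                 covariate_level = covariate_level,
                 target_censoring = target_censoring,
                 mu0 = mu0, tau2 = tau2, total = total, weights = weights,
                 beta = c(1, 0.5), xi_true = xi_true),
            class = "scenario_spec")
}

# smallest c with E[min(T, c)] / c = target (expected censoring fraction of
# C ~ Unif(0, c) against the realised times T); monotone in c => bisection
calibrate_censoring_bound <- function(T, target, tol = 1e-4, max_iter = 200) {
  f <- function(cc) mean(pmin(T, cc)) / cc - target
  lo <- min(T) * 1e-3
  hi <- max(T) * 2
  # f decreasing in c; widen until bracketed
  k <- 0
  while (f(hi) > 0 && k < 60) { hi <- hi * 4; k <- k + 1 }
  while (f(lo) < 0 && k < 120) { lo <- lo / 4; k <- k + 1 }
  if (f(hi) > 0 || f(lo) < 0) {
    stop("censoring calibration failed; achievable range [",
         signif(f(hi) + target, 3), ", ", signif(f(lo) + target, 3),
         "] does not cover target ", target, call. = FALSE)
  }
  for (i in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi / lo < 1 + tol) break
  }
  sqrt(lo * hi)
}

#' Generate one dataset under a simulation scenario
#'
#' @param spec A [scenario_spec()].
#' @param seed Optional integer seed (`set.seed` is called when supplied).
#' @return A tibble in the standard survival-table format (`time`, `event`,
#'   `unit`, `year`, `x1`, `x2`) with a `truth` attribute recording all
#'   generating parameters (`beta`, `mu0`, `omega`, cohort structure,
#'   calibrated censoring bound `c`, achieved censoring rate).
#' @export
generate_scenario <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!is.null(seed)) set.seed(seed)
  g <- spec$graph
  I <- g$I
  J <- spec$J
  K <- allocate_counts(g, J, weights = spec$weights, total = spec$total)
  n <- sum(K)
  unit_idx <- rep(rep(seq_len(I), J), times = as.vector(K))
  cohort <- rep(rep(seq_len(J), each = I), times = as.vector(K))

  omega <- rcar(g, spec$tau2)
  if (spec$scenario == "S3") {
    W <- matrix(0, I, J)
    W[, 1] <- omega
    for (j in 2:J) W[, j] <- 2 * W[, j - 1] + stats::rnorm(I)
    st_part <- W[cbind(unit_idx, cohort)]
  } else {
    trend <- switch(spec$scenario,
      S1 = 0.5 * (cohort - 1),
      S2 = 0.5 * sqrt(cohort - 1),
      S4 = spec$xi_true[cohort]
    )
    st_part <- omega[unit_idx] + trend
  }

  if (spec$covariate_level == "county") {
    x1_unit <- stats::rnorm(I)
    x1 <- x1_unit[unit_idx]
  } else {
    x1 <- stats::rnorm(n)
  }
  x2 <- stats::rbinom(n, 1, 0.5)
  eps <- log(stats::rexp(n)) # standard extreme-value residual
  logT <- spec$mu0 + spec$beta[1] * x1 + spec$beta[2] * x2 + st_part + eps
  T <- exp(logT)

  if (is.na(spec$target_censoring)) {
    time <- T
    event <- rep(1L, n)
    cbound <- Inf
  } else {
    cbound <- calibrate_censoring_bound(T, spec$target_censoring)
    C <- stats::runif(n, 0, cbound)
    time <- pmin(T, C)
    event <- as.integer(T <= C)
  }

  out <- tibble::tibble(
    time = time, event = event,
    unit = g$unit_labels[unit_idx], year = cohort,
    x1 = x1, x2 = x2
  )
  attr(out, "truth") <- list(
    scenario = spec$scenario, beta = spec$beta, mu0 = spec$mu0,
    xi_true = spec$xi_true, omega = omega, tau2 = spec$tau2,
    covariate_level = spec$covariate_level,
    target_censoring = spec$target_censoring,
    censoring_bound = cbound,
    achieved_censoring = mean(event == 0L),
    K = K
  )
  out
}

#' Run a Monte Carlo study over replicated scenario datasets
#'
#' For each replicate: generate a dataset, fit each requested candidate
#' model, record the posterior-mean estimates of `beta1` and `beta2` and
#' the DIC.  Per-replicate seeds are derived deterministically from `seed`.
#' Failed fits are excluded and counted; more than 5% failures aborts.
#'
#' @param spec A [scenario_spec()].
#' @param models Character subset of `c("M1", "M2", "M3")`.
#' @param n_reps Number of Monte Carlo replicates (>= 2).
#' @param chain A [chain_control()]; its seed is ignored (per-replicate
#'   seeds are used).
#' @param seed Master seed.
#' @param family Error family used for fitting.
#' @param cache_dir Optional directory: per-replicate estimate CSVs are
#'   written there and reused, so an interrupted study resumes without
#'   recomputing finished replicates.
#' @return A tibble of class `staft_mc` with one row per (replicate,
#'   model): `rep`, `model`, `beta1`, `beta2`, `sigma`, `dic`, `p_d`,
#'   `censoring`, plus attributes `truth_beta`, `scenario`, `n_failed`.
#' @export
run_mc_study <- function(spec, models = c("M1", "M2", "M3"), n_reps = 100,
                         chain = chain_control(seed = 1), seed = 1,
                         family = "weibull", cache_dir = NULL) {
  stopifnot(n_reps >= 2, all(models %in% c("M1", "M2", "M3")))
  if (!is.null(cache_dir) && !dir.exists(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE)
  }
  n_failed <- 0
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cache_file <- if (!is.null(cache_dir)) {
      file.path(cache_dir, sprintf("rep_%04d.csv", r))
    } else NULL
    if (!is.null(cache_file) && file.exists(cache_file)) {
      rows[[r]] <- tibble::as_tibble(utils::read.csv(cache_file))
      next
    }
    rep_seed <- (seed * 10007L + r * 131L) %% .Machine$integer.max
    dat <- generate_scenario(spec, seed = rep_seed)
    truth <- attr(dat, "truth")
    fits <- purrr::map(models, function(m) {
      tryCatch(
        fit_staft(dat, spec$graph, covariates = c("x1", "x2"), model = m,
                  family = family,
                  chain = chain_control(
                    n_burnin = chain$n_burnin, n_keep = chain$n_keep,
                    thin = chain$thin, seed = rep_seed + 7L,
                    step_size = chain$step_size,
                    target_acceptance = chain$target_acceptance,
                    adapt_window = chain$adapt_window, clamp = chain$clamp)),
        error = function(e) NULL)
    })
    ok <- !vapply(fits, is.null, TRUE)
    if (!all(ok)) {
      n_failed <- n_failed + 1
      if (n_failed > 0.05 * n_reps) {
        stop("more than 5% of replicates failed", call. = FALSE)
      }
      next
    }
    rows[[r]] <- purrr::map2_dfr(fits, models, function(f, m) {
      est <- stats::setNames(f$summary$estimate, f$summary$term)
      tibble::tibble(
        rep = r, model = m,
        beta1 = unname(est["beta.1"]), beta2 = unname(est["beta.2"]),
        sigma = unname(est["sigma"]),
        dic = f$dic$dic, p_d = f$dic$p_D,
        censoring = truth$achieved_censoring
      )
    })
    if (!is.null(cache_file)) utils::write.csv(rows[[r]], cache_file,
                                               row.names = FALSE)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "truth_beta") <- spec$beta
  attr(out, "scenario") <- spec$scenario
  attr(out, "n_failed") <- n_failed
  class(out) <- c("staft_mc", class(out))
  out
}

#' Summarise a Monte Carlo study: bias / SD / MSE and selection frequencies
#'
#' @param mc A `staft_mc` tibble from [run_mc_study()] (or stubbed
#'   estimates with the same columns and attributes).
#' @return A list with `estimates` (tibble: `model`, `parameter`, `truth`,
#'   `bias`, `sd`, `mse`, `n_reps`) and `selection` (tibble: `model`,
#'   `freq`, summing to 1), plus `mean_censoring`.  SD uses the `n - 1`
#'   denominator, so `mse >= bias^2` holds only up to that convention.
#' @export
summarize_mc <- function(mc) {
  truth <- attr(mc, "truth_beta")
  if (is.null(truth)) truth <- c(1, 0.5)
  long <- tidyr::pivot_longer(
    dplyr::select(mc, "rep", "model", "beta1", "beta2"),
    c("beta1", "beta2"), names_to = "parameter", values_to = "estimate")
  long$truth <- ifelse(long$parameter == "beta1", truth[1], truth[2])
  est <- dplyr::summarise(
    dplyr::group_by(long, .data$model, .data$parameter),
    truth = .data$truth[1],
    bias = mean(.data$estimate) - .data$truth[1],
    sd = stats::sd(.data$estimate),
    mse = mean((.data$estimate - .data$truth[1])^2),
    n_reps = dplyr::n(), .groups = "drop")
  sel <- NULL
  if (length(unique(mc$model)) >= 2) {
    picks <- dplyr::summarise(
      dplyr::group_by(mc, .data$rep),
      pick = select_model(stats::setNames(as.list(.data$dic), .data$model)),
      .groups = "drop")
    mods <- sort(unique(mc$model))
    sel <- tibble::tibble(
      model = mods,
      freq = unname(vapply(mods, function(m) mean(picks$pick == m), 1.0)))
  }
  list(estimates = est, selection = sel,
       mean_censoring = mean(mc$censoring))
}

#' Format Monte Carlo summaries as a publication-style wide table
#'
#' @param summaries Named list of [summarize_mc()] results, one per
#'   scenario (names used as column groups).
#' @return A tibble: rows are (model, parameter), columns are
#'   `<scenario>_bias`, `<scenario>_sd`, `<scenario>_mse`.
#' @export
summarize_tables <- function(summaries) {
  stopifnot(length(summaries) >= 1)
  pieces <- purrr::imap(summaries, function(s, nm) {
    e <- s$estimates
    tibble::tibble(
      model = e$model, parameter = e$parameter, scenario = nm,
      bias = round(e$bias, 3), sd = round(e$sd, 3), mse = round(e$mse, 3))
  })
  long <- dplyr::bind_rows(pieces)
  tidyr::pivot_wider(long, names_from = "scenario",
                     values_from = c("bias", "sd", "mse"),
                     names_glue = "{scenario}_{.value}")
}

#' Bias plot for a Monte Carlo study
#'
#' @param mc A `staft_mc` tibble.
#' @return A ggplot object: per-model boxplots of the estimates of `beta1`
#'   and `beta2` with the generating truth as a dashed line.
#' @export
plot_mc_estimates <- function(mc) {
  truth <- attr(mc, "truth_beta")
  long <- tidyr::pivot_longer(
    dplyr::select(mc, "model", "beta1", "beta2"),
    c("beta1", "beta2"), names_to = "parameter", values_to = "estimate")
  ref <- tibble::tibble(parameter = c("beta1", "beta2"), truth = truth)
  ggplot2::ggplot(long, ggplot2::aes(.data$model, .data$estimate)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(data = ref,
                        ggplot2::aes(yintercept = .data$truth),
                        linetype = 2) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "posterior-mean estimate")
}
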