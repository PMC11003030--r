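#' MCMC chain settings
#'
#' @param n_burnin Burn-in iterations discarded (default 1000).
#' @param n_keep Kept iterations after burn-in (default 1000).
#' @param thin Thinning interval (default 1).
#' @param seed Integer seed; required, all chain randomness flows from it.
#' @param step_size Initial random-walk step size for every MH block;
#'   adapted during burn-in only.
#' @param target_acceptance Adaptation midpoint of the 10-60% acceptance
#'   band (default 0.45).
#' @param adapt_window Iterations per step-size adaptation window.
#' @param clamp Standardised-residual bound (numerical guard).
#' @return A list of class `chain_control`.
#' @export
chain_control <- function(n_burnin = 1000, n_keep = 1000, thin = 1,
                          seed = NULL, step_size = 0.1,
                          target_acceptance = 0.45, adapt_window = 50,
                          clamp = 30) {
  stopifnot(n_burnin >= 1, n_keep >= 1, thin >= 1,
            target_acceptance > 0, target_acceptance < 1)
  structure(list(n_burnin = as.integer(n_burnin),
                 n_keep = as.integer(n_keep), thin = as.integer(thin),
                 seed = seed, step_size = step_size,
                 target_acceptance = target_acceptance,
                 adapt_window = as.integer(adapt_window), clamp = clamp),
            class = "chain_control")
}

#' Prior settings
#'
#' @param wishart_scale_diag Diagonal of the Wishart prior scale `R`
#'   (default 100; 10 is the hyper-prior sensitivity option).
#' @param wishart_df Prior degrees of freedom; default the frailty block
#'   dimension `q` (the vague choice).
#' @param sigma2_shape,sigma2_rate Inverse-gamma prior on `sigma^2`
#'   (default 0.001, 0.001).
#' @return A list of class `prior_control`.
#' @export
prior_control <- function(wishart_scale_diag = 100, wishart_df = NULL,
                          sigma2_shape = 0.001, sigma2_rate = 0.001) {
  structure(list(wishart_scale_diag = wishart_scale_diag,
                 wishart_df = wishart_df,
                 sigma2_shape = sigma2_shape, sigma2_rate = sigma2_rate),
            class = "prior_control")
}

#' Fit a Bayesian spatial-temporal AFT model
#'
#' Posterior sampling for candidate models M1/M2/M3 (see [staft_model()])
#' by Gibbs-within-Metropolis-Hastings: componentwise random-walk MH for
#' `beta`, `xi`, `mu`, each frailty component and `log sigma`, and an exact
#' Wishart draw for the MCAR precision `Lambda`, followed by sum-to-zero
#' centering of each frailty component (absorbed into `mu`/`xi` so linear
#' predictors are unchanged).  Step sizes adapt multiplicatively during
#' burn-in toward the target acceptance rate and are frozen afterwards.
#'
#' @param data Survival table: columns `time`, `event` (0/1), `unit`,
#'   `year`, plus covariates.  Alternatively a dataset already prepared by
#'   [prepare_survival_data()].
#' @param graph An `aft_graph`; data units must be a subset of its labels.
#' @param covariates Character vector of covariate column names.
#' @param model `"M1"`, `"M2"` or `"M3"`.
#' @param family Error family (see [aft_family()]).
#' @param chain A [chain_control()]; `seed` must be set.
#' @param prior A [prior_control()].
#' @param frailty Set `FALSE` to drop all frailty terms (an ordinary AFT
#'   regression; used for oracle checks).
#' @param fix_sigma Optional fixed value for `sigma` (skips its update).
#' @param fix_lambda Optional fixed `q x q` precision matrix for `Lambda`
#'   (skips its Wishart update).
#' @param prior_only If `TRUE`, suppress all likelihood contributions and
#'   sample the frailties from their (centered) prior; fixed effects and
#'   `sigma` are not updated.  For prior-recovery diagnostics.
#' @return An object of class `staft_fit`: list with `draws` (tibble, one
#'   row per kept iteration), `summary` (tibble of posterior means and 95%
#'   credible limits), `deviance` (vector), `dic` (a `staft_dic`),
#'   `acceptance` (tibble per MH block), `state_mean` (posterior-mean
#'   `staft_state`), `spec`, `graph`, `data`, `control`.
#' @export
fit_staft <- function(data, graph, covariates = c("x1", "x2"),
                      model = c("M2", "M1", "M3"), family = "weibull",
                      chain = chain_control(seed = 1),
                      prior = prior_control(),
                      frailty = TRUE, fix_sigma = NULL, fix_lambda = NULL,
                      prior_only = FALSE) {
  model <- match.arg(model)
  if (is.null(attr(data, "covariates"))) {
    data <- prepare_survival_data(data, graph, covariates)
  }
  covariates <- attr(data, "covariates")
  J <- attr(data, "J")
  spec <- staft_model(model, family = family, J = J,
                      p = length(covariates), covariate_names = covariates)
  if (is.null(chain$seed)) stop("chain_control seed must be set", call. = FALSE)

  q <- spec$q
  wdf <- if (is.null(prior$wishart_df)) q else prior$wishart_df
  R <- diag(prior$wishart_scale_diag, q)
  Lambda_init <- if (is.null(fix_lambda)) diag(1, q) else as.matrix(fix_lambda)
  sigma_init <- if (is.null(fix_sigma)) 1 else fix_sigma

  X <- as.matrix(as.data.frame(data)[, covariates, drop = FALSE])
  set.seed(chain$seed)
  res <- chain_run_cpp(
    logY = log(data$time), delta = as.integer(data$event), X = X,
    unit = as.integer(data$unit_index - 1L),
    cohort = as.integer(data$cohort_index - 1L),
    I = graph$I, J = J, model = as.integer(substring(model, 2)),
    family = family_code(spec$family), C = graph$C,
    n_burnin = chain$n_burnin, n_keep = chain$n_keep, thin = chain$thin,
    clamp = chain$clamp, wishart_df = wdf, wishart_R = R,
    sig_a = prior$sigma2_shape, sig_b = prior$sigma2_rate,
    s_init = chain$step_size, adapt_target = chain$target_acceptance,
    adapt_window = chain$adapt_window,
    fix_sigma = !is.null(fix_sigma), sigma_init = sigma_init,
    prior_only = prior_only, fix_lambda = !is.null(fix_lambda),
    Lambda_init = Lambda_init, include_frailty = frailty)

  nm <- draw_names(spec, graph, frailty, fix_lambda = !is.null(fix_lambda))
  draws <- tibble::as_tibble(as.data.frame(res$draws))
  names(draws) <- nm

  qs <- t(apply(res$draws, 2, stats::quantile, probs = c(0.025, 0.975)))
  summary_tbl <- tibble::tibble(
    term = nm,
    estimate = colMeans(res$draws),
    conf.low = qs[, 1], conf.high = qs[, 2]
  )

  state_mean <- mean_state(summary_tbl, spec, graph, frailty)
  dev_at_mean <- -2 * conditional_loglik(data, state_mean, spec,
                                         clamp = chain$clamp)
  dic_res <- if (prior_only) NULL else dic(res$deviance, dev_at_mean)

  structure(list(
    draws = draws,
    summary = summary_tbl,
    deviance = as.numeric(res$deviance),
    dic = dic_res,
    acceptance = tibble::tibble(block = unlist(res$block),
                                rate = as.numeric(res$acceptance),
                                step_size = as.numeric(res$step_size)),
    state_mean = state_mean,
    spec = spec, graph = graph, data = data,
    control = chain, prior = prior, frailty = frailty
  ), class = "staft_fit")
}

draw_names <- function(spec, graph, frailty, fix_lambda = FALSE) {
  nm <- c("mu", paste0("beta.", seq_len(spec$p)))
  if (spec$n_xi > 0) nm <- c(nm, paste0("xi.", seq_len(spec$n_xi)))
  if (frailty) {
    nm <- c(nm, paste0("omega.", seq_len(graph$I)))
    if (spec$q > 1) {
      for (c in seq_len(spec$q - 1)) {
        lbl <- if (spec$model == "M2") paste0("gamma.", seq_len(graph$I))
               else paste0("gamma.", seq_len(graph$I), ".", c)
        nm <- c(nm, lbl)
      }
    }
  }
  nm <- c(nm, "sigma")
  if (frailty && !fix_lambda) {
    for (c in seq_len(spec$q))
      for (d in seq_len(c)) nm <- c(nm, paste0("Lambda.", d, ".", c))
  }
  nm
}

mean_state <- function(summary_tbl, spec, graph, frailty) {
  est <- stats::setNames(summary_tbl$estimate, summary_tbl$term)
  beta <- est[paste0("beta.", seq_len(spec$p))]
  xi <- if (spec$n_xi > 0) est[paste0("xi.", seq_len(spec$n_xi))]
        else numeric(0)
  Delta <- matrix(0, graph$I, spec$q)
  if (frailty) {
    Delta[, 1] <- est[paste0("omega.", seq_len(graph$I))]
    if (spec$q > 1) {
      for (c in seq_len(spec$q - 1)) {
        lbl <- if (spec$model == "M2") paste0("gamma.", seq_len(graph$I))
               else paste0("gamma.", seq_len(graph$I), ".", c)
        Delta[, 1 + c] <- est[lbl]
      }
    }
  }
  staft_state(mu = unname(est["mu"]), beta = unname(beta),
              xi = unname(xi), Delta = Delta,
              sigma = unname(est["sigma"]), spec = spec)
}

#' @export
print.staft_fit <- function(x, ...) {
  cat("<staft_fit> ", x$spec$model, " (", x$spec$family, "), ",
      nrow(x$data), " records, ", x$graph$I, " units, J = ", x$spec$J,
      "\n", sep = "")
  core <- dplyr::filter(x$summary,
                        !grepl("^(omega|gamma|Lambda)", .data$term))
  print(core, n = nrow(core))
  if (!is.null(x$dic)) {
    cat(sprintf("DIC %.1f (p_D %.1f)\n", x$dic$dic, x$dic$p_D))
  }
  invisible(x)
}

#' Tidy posterior summaries of a fitted model
#'
#' @param x A `staft_fit`.
#' @param pars `"fixed"` (default) keeps `mu`, `beta`, `xi`, `sigma`;
#'   `"all"` includes frailties and `Lambda` entries.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `conf.low`,
#'   `conf.high` (posterior mean and 95% credible limits).
#' @method tidy staft_fit
#' @export
tidy.staft_fit <- function(x, pars = c("fixed", "all"), ...) {
  pars <- match.arg(pars)
  out <- x$summary
  if (pars == "fixed") {
    out <- dplyr::filter(out, !grepl("^(omega|gamma|Lambda)", .data$term))
  }
  out
}

#' One-row model summary
#'
#' @param x A `staft_fit`.
#' @param ... Unused.
#' @return A tibble with `model`, `family`, `n`, `I`, `J`, `dic`, `p_d`,
#'   `dbar`, `sigma`, and the min/max MH acceptance rate.
#' @method glance staft_fit
#' @export
glance.staft_fit <- function(x, ...) {
  tibble::tibble(
    model = x$spec$model, family = x$spec$family,
    n = nrow(x$data), I = x$graph$I, J = x$spec$J,
    dic = if (is.null(x$dic)) NA_real_ else x$dic$dic,
    p_d = if (is.null(x$dic)) NA_real_ else x$dic$p_D,
    dbar = if (is.null(x$dic)) NA_real_ else x$dic$dbar,
    sigma = x$state_mean$sigma,
    min_acceptance = min(x$acceptance$rate, na.rm = TRUE),
    max_acceptance = max(x$acceptance$rate, na.rm = TRUE)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Trace and autocorrelation plots of a fitted chain
#'
#' @param object A `staft_fit`.
#' @param type `"trace"` or `"acf"`.
#' @param pars Parameter names to show (default: fixed effects and sigma).
#' @param lag_max Maximum lag for `type = "acf"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot staft_fit
#' @export
autoplot.staft_fit <- function(object, type = c("trace", "acf"),
                               pars = NULL, lag_max = 30, ...) {
  type <- match.arg(type)
  if (is.null(pars)) {
    pars <- setdiff(names(object$draws),
                    grep("^(omega|gamma|Lambda)", names(object$draws),
                         value = TRUE))
  }
  d <- dplyr::mutate(object$draws[, pars, drop = FALSE],
                     .iter = dplyr::row_number())
  long <- tidyr::pivot_longer(d, -".iter", names_to = "term")
  if (type == "trace") {
    ggplot2::ggplot(long, ggplot2::aes(.data$.iter, .data$value)) +
      ggplot2::geom_line(linewidth = 0.3) +
      ggplot2::facet_wrap(~term, scales = "free_y") +
      ggplot2::labs(x = "kept iteration", y = NULL)
  } else {
    acfs <- chain_summaries(object$draws[, pars, drop = FALSE],
                            lag_max = lag_max)
    ggplot2::ggplot(acfs, ggplot2::aes(.data$lag, .data$acf)) +
      ggplot2::geom_col(width = 0.2) +
      ggplot2::facet_wrap(~term) +
      ggplot2::labs(x = "lag", y = "autocorrelation")
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
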