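#' Deviance information criterion
#'
#' `DIC = 2 p_D + dev(theta_bar)` with `p_D = dbar - dev(theta_bar)`, where
#' `dbar` is the posterior mean of the per-iteration conditional deviance
#' (-2 x conditional log-likelihood given the frailties) and
#' `dev(theta_bar)` is the deviance at the posterior means of all sampled
#' quantities including the frailties.  Equivalently
#' `DIC = 2 dbar - dev(theta_bar)`.  Smaller is better.
#'
#' @param deviance_samples Per-iteration deviance values (length >= 2).
#' @param dev_at_mean Deviance at the posterior mean parameters.
#' @return A list of class `staft_dic` with `dic`, `p_D`, `dbar`,
#'   `dev_at_mean`.
#' @examples
#' dic(c(10, 12), 9) # dbar 11, p_D 2, dic 13
#' @export
dic <- function(deviance_samples, dev_at_mean) {
  if (length(deviance_samples) < 2) {
    stop("need at least 2 deviance samples", call. = FALSE)
  }
  if (!all(is.finite(deviance_samples)) || !is.finite(dev_at_mean)) {
    stop("non-finite deviance", call. = FALSE)
  }
  dbar <- mean(deviance_samples)
  p_D <- dbar - dev_at_mean
  structure(list(dic = 2 * p_D + dev_at_mean, p_D = p_D, dbar = dbar,
                 dev_at_mean = dev_at_mean),
            class = "staft_dic")
}

#' @export
print.staft_dic <- function(x, ...) {
  cat(sprintf("DIC %.2f  (dbar %.2f, dev at mean %.2f, p_D %.2f)\n",
              x$dic, x$dbar, x$dev_at_mean, x$p_D))
  invisible(x)
}

#' Select the model with the smallest DIC
#'
#' Ties are broken deterministically by the fixed model order
#' M1 < M2 < M3 (a warning notes the tie).
#'
#' @param dic_results Named list (names in `"M1"`, `"M2"`, `"M3"`) of
#'   `staft_dic` objects, `staft_fit` objects, or bare DIC numbers.
#' @return The selected model label.
#' @examples
#' select_model(list(M1 = 100, M2 = 90, M3 = 95)) # "M2"
#' @export
select_model <- function(dic_results) {
  if (length(dic_results) < 2) stop("need >= 2 models", call. = FALSE)
  vals <- vapply(dic_results, function(x) {
    if (inherits(x, "staft_fit")) x$dic$dic
    else if (inherits(x, "staft_dic")) x$dic
    else as.numeric(x)
  }, 1.0)
  order_fixed <- c("M1", "M2", "M3")
  labs <- names(vals)
  stopifnot(all(labs %in% order_fixed))
  vals <- vals[order(match(labs, order_fixed))]
  best <- which(vals == min(vals))
  if (length(best) > 1) {
    warning("DIC tie between ", paste(names(vals)[best], collapse = ", "),
            "; keeping ", names(vals)[best[1]])
  }
  names(vals)[best[1]]
}

#' Cox-Snell residuals
#'
#' `r = -log S(Y | theta)` at the posterior-mean parameters.  Under a
#' correctly specified model the pairs `(r, event)` behave like a
#' right-censored sample from a unit exponential distribution, so the
#' cumulative hazard of the residuals should lie near the identity line.
#'
#' @param fit A `staft_fit`, or a prepared dataset if `state`/`spec` are
#'   given explicitly.
#' @param data,state,spec Optional explicit pieces overriding those stored
#'   in `fit`.
#' @return A tibble with columns `unit_index`, `cohort_index`, `residual`,
#'   `event`.
#' @export
cox_snell_residuals <- function(fit, data = NULL, state = NULL, spec = NULL) {
  if (inherits(fit, "staft_fit")) {
    if (is.null(data)) data <- fit$data
    if (is.null(state)) state <- fit$state_mean
    if (is.null(spec)) spec <- fit$spec
  }
  lp <- linear_predictor(data, state, spec)
  r <- -log_survival(data$time, lp, state$sigma, spec$family)
  tibble::tibble(unit_index = data$unit_index,
                 cohort_index = data$cohort_index,
                 residual = r, event = data$event)
}

#' Plot method for Cox-Snell residuals
#'
#' Nelson-Aalen cumulative hazard of the residuals against the residuals;
#' points near the identity indicate an adequate fit.
#'
#' @param residuals A tibble from [cox_snell_residuals()].
#' @return A ggplot object.
#' @export
plot_cox_snell <- function(residuals) {
  ord <- order(residuals$residual)
  r <- residuals$residual[ord]
  d <- residuals$event[ord]
  n <- length(r)
  at_risk <- n - seq_len(n) + 1
  H <- cumsum(d / at_risk) # Nelson-Aalen estimate on the residual scale
  df <- tibble::tibble(residual = r, cumhaz = H)
  ggplot2::ggplot(df, ggplot2::aes(.data$residual, .data$cumhaz)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "Cox-Snell residual", y = "cumulative hazard")
}

#' Per-parameter autocorrelation summaries of posterior draws
#'
#' @param draws A data frame / tibble of posterior draws (>= 10 rows), one
#'   column per scalar parameter.
#' @param lag_max Largest lag reported.
#' @return A tibble with columns `term`, `lag` (0..`lag_max`), `acf`, and
#'   `constant` (TRUE when a chain was constant, in which case `acf` is NA
#'   rather than NaN).
#' @export
chain_summaries <- function(draws, lag_max = 30) {
  draws <- as.data.frame(draws)
  if (nrow(draws) < 10) stop("need >= 10 samples", call. = FALSE)
  lag_max <- min(lag_max, nrow(draws) - 1)
  purrr::map_dfr(names(draws), function(term) {
    x <- draws[[term]]
    if (stats::sd(x) == 0) {
      tibble::tibble(term = term, lag = 0:lag_max,
                     acf = c(1, rep(NA_real_, lag_max)), constant = TRUE)
    } else {
      a <- stats::acf(x, lag.max = lag_max, plot = FALSE)$acf[, 1, 1]
      tibble::tibble(term = term, lag = 0:lag_max, acf = a, constant = FALSE)
    }
  })
}
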