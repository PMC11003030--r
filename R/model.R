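#' Candidate spatial-temporal AFT model specifications
#'
#' Three nested candidate models for survival times indexed by areal unit
#' (county) `i` and diagnosis-year cohort `j`:
#'
#' * **M1** (spatial): `log T = mu + x'beta + omega_i + sigma eps` — a
#'   CAR-distributed spatial frailty only; no temporal term.
#' * **M2** (spatial + random temporal slope):
#'   `log T = mu + x'beta + xi z + gamma_i z + omega_i + sigma eps`, where
#'   `z = j - 1` codes cohort as a continuous covariate starting at 0 and
#'   `(omega_i, gamma_i)` carries a bivariate MCAR prior.
#' * **M3** (spatial + categorical cohort):
#'   `log T = mu + x'beta + xi_j + gamma_ij + omega_i + sigma eps`, with the
#'   first cohort as fixed-effect reference (`xi_1 = 0`) and a frailty
#'   intercept per (unit, cohort) so `(omega_i, gamma_i1, ..., gamma_iJ)`
#'   carries a `(1+J)`-variate MCAR prior.
#'
#' @param model `"M1"`, `"M2"` or `"M3"`.
#' @param family Error family name, see [aft_family()].
#' @param J Number of temporal cohorts.
#' @param p Number of covariates.
#' @param covariate_names Optional covariate names (length `p`).
#' @return A list of class `staft_model` with elements `model`, `family`,
#'   `J`, `p`, `q` (frailty block dimension: 1, 2 or `1+J`), `n_xi` (free
#'   temporal fixed effects: 0, 1 or `J-1`) and `covariate_names`.
#' @export
staft_model <- function(model = c("M2", "M1", "M3"),
                        family = "weibull", J = 5, p = 2,
                        covariate_names = NULL) {
  model <- match.arg(model)
  family <- aft_family(family)$name
  J <- as.integer(J)
  p <- as.integer(p)
  if (J < 2) stop("need J >= 2 cohorts", call. = FALSE)
  if (is.null(covariate_names)) covariate_names <- paste0("x", seq_len(p))
  stopifnot(length(covariate_names) == p)
  q <- switch(model, M1 = 1L, M2 = 2L, M3 = 1L + J)
  n_xi <- switch(model, M1 = 0L, M2 = 1L, M3 = J - 1L)
  structure(
    list(model = model, family = family, J = J, p = p, q = q, n_xi = n_xi,
         covariate_names = covariate_names),
    class = "staft_model"
  )
}

#' @export
print.staft_model <- function(x, ...) {
  cat("<staft_model> ", x$model, " (", x$family, "), J = ", x$J,
      ", p = ", x$p, ", frailty dim q = ", x$q, "\n", sep = "")
  invisible(x)
}

#' Parameter state of a spatial-temporal AFT model
#'
#' Bundles one full set of model parameters: intercept `mu`, fixed effects
#' `beta` (length `p`), free temporal fixed effects `xi` (length 0 for M1,
#' 1 for M2, `J-1` for M3), the `I x q` frailty block `Delta` (column 1 is
#' the spatial frailty `omega`; remaining columns are temporal frailties
#' `gamma`), and the positive scale `sigma`.
#'
#' @param mu Intercept.
#' @param beta Numeric vector of covariate effects.
#' @param xi Numeric vector of temporal fixed effects (may be length 0).
#' @param Delta `I x q` matrix of frailties (or `NULL` for a frailty-free
#'   state, in which case `I` gives the number of units and `Delta` is zero).
#' @param sigma Positive scale.
#' @param spec A `staft_model` used to validate dimensions.
#' @param I Number of units (needed only when `Delta` is `NULL`).
#' @return A list of class `staft_state`.
#' @export
staft_state <- function(mu = 0, beta = numeric(0), xi = numeric(0),
                        Delta = NULL, sigma = 1, spec = NULL, I = NULL) {
  if (is.null(Delta)) {
    if (is.null(I)) stop("supply Delta or I", call. = FALSE)
    q <- if (is.null(spec)) 1L else spec$q
    Delta <- matrix(0, I, q)
  }
  Delta <- as.matrix(Delta)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (!is.null(spec)) {
    if (length(beta) != spec$p) stop("beta has wrong length", call. = FALSE)
    if (length(xi) != spec$n_xi) {
      stop("xi must have length ", spec$n_xi, " for ", spec$model,
           call. = FALSE)
    }
    if (ncol(Delta) != spec$q) stop("Delta has wrong q", call. = FALSE)
  }
  structure(list(mu = mu, beta = as.numeric(beta), xi = as.numeric(xi),
                 Delta = Delta, sigma = sigma),
            class = "staft_state")
}

#' Prepare a survival table for fitting
#'
#' Validates a subject-level survival table and attaches 1-based unit and
#' cohort indices.  Units must be a subset of the graph's labels; cohorts
#' are the sorted unique values of `year`.
#'
#' @param data Data frame with columns `time` (positive), `event` (0/1),
#'   `unit`, `year`, plus the covariates named in `covariates`.
#' @param graph An `aft_graph`; unit indexing follows its label order.
#' @param covariates Character vector of covariate column names.
#' @param time,event,unit,year Column names, if different from the defaults.
#' @return A tibble with columns `time`, `event`, `unit_index`,
#'   `cohort_index`, the covariate columns, and attributes `I`, `J`, `p`,
#'   `cohort_levels`, `covariates`, `unit_labels`.
#' @export
prepare_survival_data <- function(data, graph, covariates,
                                  time = "time", event = "event",
                                  unit = "unit", year = "year") {
  stopifnot(inherits(graph, "aft_graph"))
  data <- as.data.frame(data)
  needed <- c(time, event, unit, year, covariates)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  tt <- as.numeric(data[[time]])
  ev <- data[[event]]
  if (nrow(data) == 0) stop("empty dataset", call. = FALSE)
  bad <- which(!(ev %in% c(0, 1)))
  if (length(bad) > 0) {
    stop("event must be 0 or 1; offending row ", bad[1],
         " has value '", ev[bad[1]], "'", call. = FALSE)
  }
  if (any(tt <= 0)) {
    stop("time must be positive; offending row ", which(tt <= 0)[1],
         call. = FALSE)
  }
  ui <- match(as.character(data[[unit]]), graph$unit_labels)
  if (anyNA(ui)) {
    miss <- unique(as.character(data[[unit]])[is.na(ui)])
    stop("unit label(s) not in graph: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cohort_levels <- sort(unique(data[[year]]))
  ci <- match(data[[year]], cohort_levels)
  out <- tibble::tibble(
    time = tt, event = as.integer(ev),
    unit_index = ui, cohort_index = ci
  )
  for (v in covariates) out[[v]] <- as.numeric(data[[v]])
  attr(out, "I") <- graph$I
  attr(out, "J") <- length(cohort_levels)
  attr(out, "p") <- length(covariates)
  attr(out, "cohort_levels") <- cohort_levels
  attr(out, "covariates") <- covariates
  attr(out, "unit_labels") <- graph$unit_labels
  out
}

#' Per-(unit, cohort) subject counts of a prepared dataset
#'
#' @param data A prepared dataset (see [prepare_survival_data()]).
#' @return A tibble with columns `unit_index`, `cohort_index`, `K`.
#' @export
cell_counts <- function(data) {
  dplyr::count(data, .data$unit_index, .data$cohort_index, name = "K")
}

#' Linear predictor of a spatial-temporal AFT model
#'
#' Evaluates `mu'(x) = mu + x'beta + (temporal fixed part) + (frailty part)`
#' for each record under the selected candidate model (see [staft_model()]).
#'
#' @param data A prepared dataset (see [prepare_survival_data()]) or any
#'   data frame with `unit_index`, `cohort_index` and the covariates of
#'   `spec`.
#' @param state A `staft_state`.
#' @param spec A `staft_model`.
#' @return Numeric vector, one linear predictor per record.
#' @export
linear_predictor <- function(data, state, spec) {
  j <- data$cohort_index
  i <- data$unit_index
  if (any(j < 1 | j > spec$J)) stop("cohort index out of range", call. = FALSE)
  if (any(i < 1 | i > nrow(state$Delta))) {
    stop("unit index out of range", call. = FALSE)
  }
  X <- as.matrix(as.data.frame(data)[, spec$covariate_names, drop = FALSE])
  lp <- state$mu + drop(X %*% state$beta)
  z <- j - 1
  if (spec$model == "M1") {
    lp <- lp + state$Delta[i, 1]
  } else if (spec$model == "M2") {
    lp <- lp + state$xi * z + state$Delta[i, 2] * z + state$Delta[i, 1]
  } else {
    xi_full <- c(0, state$xi)            # reference cohort first
    lp <- lp + xi_full[j] + state$Delta[cbind(i, 1 + j)] + state$Delta[i, 1]
  }
  lp
}

#' Censored conditional log-likelihood
#'
#' Sum over records of `event * log f + (1 - event) * log S` at each
#' record's linear predictor, conditional on the frailties in `state`.
#'
#' @inheritParams linear_predictor
#' @param clamp Standardised-residual bound passed to [log_density()].
#' @return A single number.
#' @export
conditional_loglik <- function(data, state, spec, clamp = 30) {
  if (nrow(data) == 0) stop("empty dataset", call. = FALSE)
  lp <- linear_predictor(data, state, spec)
  lf <- log_density(data$time, lp, state$sigma, spec$family, clamp)
  ls <- log_survival(data$time, lp, state$sigma, spec$family, clamp)
  sum(ifelse(data$event == 1, lf, ls))
}
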