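#' One random-walk Metropolis-Hastings update
#'
#' Proposes `new = current + s * W` with `W ~ N(0, 1)` and accepts iff the
#' likelihood ratio `exp(log_target(new) - log_target(current))` exceeds an
#' independent `U ~ Unif(0, 1)`.  A proposal where `log_target` is `NaN` is
#' rejected with a warning.  This scalar kernel is the building block the
#' sampler applies componentwise; it is exposed for diagnostics and testing
#' (the production chain runs the compiled equivalent).
#'
#' @param current Current value (finite).
#' @param log_target Function returning the (unnormalised) log target.
#' @param s Step size, `s >= 0`.
#' @return A list with `value` and `accepted`.
#' @export
mh_update <- function(current, log_target, s) {
  stopifnot(s >= 0, is.finite(current))
  lt_cur <- log_target(current)
  w <- stats::rnorm(1)
  u <- stats::runif(1)
  proposal <- current + s * w
  lt_new <- log_target(proposal)
  if (is.nan(lt_new)) {
    warning("log target NaN at proposal; rejecting")
    return(list(value = current, accepted = FALSE))
  }
  # accept iff LR > U on the log scale
  accepted <- (lt_new - lt_cur) > log(u)
  list(value = if (accepted) proposal else current, accepted = accepted)
}

#' Center frailties for identifiability
#'
#' Translates each frailty component column of `Delta` to sum to zero
#' across units, absorbing the subtracted means into `mu` (and, for
#' cohort-indexed components, into `xi`) so that the linear predictor of
#' every record is unchanged.
#'
#' @param state A `staft_state`.
#' @param spec A `staft_model`.
#' @return The centered `staft_state`.
#' @export
center_frailties <- function(state, spec) {
  cm <- colMeans(state$Delta)
  state$Delta <- sweep(state$Delta, 2, cm)
  if (spec$model == "M1") {
    state$mu <- state$mu + cm[1]
  } else if (spec$model == "M2") {
    state$mu <- state$mu + cm[1]
    state$xi <- state$xi + cm[2]
  } else {
    # columns: omega, gamma_.1 (reference cohort), gamma_.2, ...
    state$mu <- state$mu + cm[1] + cm[2]
    if (spec$n_xi > 0) {
      state$xi <- state$xi + cm[2 + seq_len(spec$n_xi)] - cm[2]
    }
  }
  state
}
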