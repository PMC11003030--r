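#' Intrinsic CAR prior log-density
#'
#' Unnormalised log-density of the intrinsic conditional autoregressive
#' prior for a spatial frailty vector `omega`:
#' `-(I - G)/2 * log(tau2) - omega' (D_omega - C) omega / (2 * tau2)`,
#' where `G` is the number of connected components of the graph.  `tau2` is
#' the *conditional* variance parameter: given its neighbours, `omega_i` is
#' normal with mean the arithmetic neighbour mean and variance
#' `tau2 / n_i` (`n_i` = neighbour count).  The prior is improper: adding a
#' constant to `omega` within a connected component leaves it unchanged, and
#' the rank-based normalising exponent `(I - G)/2` keeps hyper-parameter
#' updates proper despite the singular structure matrix.
#'
#' @param omega Numeric vector of length `graph$I`.
#' @param graph An `aft_graph`.
#' @param tau2 Positive conditional-variance parameter.
#' @return Unnormalised log-density (a single number).
#' @export
car_log_density <- function(omega, graph, tau2) {
  stopifnot(inherits(graph, "aft_graph"), tau2 > 0,
            length(omega) == graph$I)
  Q <- car_structure_matrix(graph)
  quad <- drop(crossprod(omega, Q %*% omega))
  -(graph$I - graph$n_components) / 2 * log(tau2) - quad / (2 * tau2)
}

#' CAR full conditional of one unit's frailty
#'
#' Mean and variance of `omega_i | omega_{-i}` under the intrinsic CAR
#' prior: the mean is the arithmetic mean of the neighbours' values and the
#' variance is `tau2 / n_i`.  An island (no neighbours) has no CAR
#' conditional; its frailty is treated as marginally `N(0, tau2)` and the
#' result is flagged.
#'
#' @param i Unit index (1-based, in graph label order).
#' @param omega Frailty vector.
#' @param graph An `aft_graph`.
#' @param tau2 Conditional variance parameter.
#' @return A list with `mean`, `variance`, `island` (logical).
#' @export
car_full_conditional <- function(i, omega, graph, tau2) {
  stopifnot(inherits(graph, "aft_graph"), length(omega) == graph$I)
  nb <- which(graph$C[i, ] == 1)
  if (length(nb) == 0) {
    return(list(mean = 0, variance = tau2, island = TRUE))
  }
  list(mean = mean(omega[nb]), variance = tau2 / length(nb), island = FALSE)
}

#' MCAR prior log-density for a frailty block
#'
#' Unnormalised log-density of the intrinsic multivariate CAR prior for an
#' `I x q` frailty block `Delta` (row `i` is `Delta_i = (omega_i, gamma_i)`),
#' with cross-component precision matrix `Lambda`:
#' `(I - G)/2 * log det(Lambda) - vec(Delta)' [(D_omega - C) %x% Lambda] vec(Delta) / 2`,
#' where `vec` stacks the unit blocks `Delta_1, ..., Delta_I`.  With `q = 1`
#' and `Lambda = 1/tau2` this reduces to [car_log_density()].
#'
#' @param Delta `I x q` numeric matrix.
#' @param graph An `aft_graph`.
#' @param Lambda `q x q` symmetric positive-definite precision matrix.
#' @return Unnormalised log-density (a single number).
#' @export
mcar_log_density <- function(Delta, graph, Lambda) {
  Delta <- as.matrix(Delta)
  Lambda <- as.matrix(Lambda)
  stopifnot(inherits(graph, "aft_graph"), nrow(Delta) == graph$I,
            ncol(Delta) == ncol(Lambda))
  ev <- eigen(Lambda, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("Lambda must be positive definite", call. = FALSE)
  V <- compute_V(Delta, graph)
  ldet <- sum(log(ev))
  (graph$I - graph$n_components) / 2 * ldet - sum(Lambda * V) / 2
}

#' Frailty cross-product matrix V of the Wishart full conditional
#'
#' `V[c, d] = Delta*_c' (D_omega - C) Delta*_d`, where `Delta*_c` is
#' component `c` of the frailty across all units (column `c` of `Delta`).
#' Equivalently `V = sum over adjacent pairs (i, i') of
#' (Delta_i - Delta_i')(Delta_i - Delta_i')'`, and
#' `vec(Delta)' [(D_omega - C) %x% Lambda] vec(Delta) = trace(Lambda V)`.
#'
#' @param Delta `I x q` numeric matrix.
#' @param graph An `aft_graph`.
#' @return Symmetric positive semi-definite `q x q` matrix.
#' @export
compute_V <- function(Delta, graph) {
  Delta <- as.matrix(Delta)
  stopifnot(inherits(graph, "aft_graph"), nrow(Delta) == graph$I)
  Q <- car_structure_matrix(graph)
  crossprod(Delta, Q %*% Delta)
}

#' Wishart full conditional of the MCAR precision matrix
#'
#' With prior `Lambda ~ Wishart(p, R)` the full conditional given the
#' frailty block is `Wishart(p + I, (R^{-1} + V)^{-1})` where `V` is
#' [compute_V()].  With `q = 1` this is the Gamma full conditional of a
#' scalar CAR precision.
#'
#' @param Delta `I x q` frailty block.
#' @param graph An `aft_graph`.
#' @param wishart_df Prior degrees of freedom `p` (default `q`, the vague
#'   choice).
#' @param wishart_scale Prior scale matrix `R` (default `diag(100, q)`;
#'   `diag(10, q)` is the hyper-prior sensitivity option).
#' @return A list with `df` and `scale` (the `q x q` posterior scale).
#' @export
lambda_full_conditional <- function(Delta, graph, wishart_df = NULL,
                                    wishart_scale = NULL) {
  Delta <- as.matrix(Delta)
  q <- ncol(Delta)
  if (is.null(wishart_df)) wishart_df <- q
  if (is.null(wishart_scale)) wishart_scale <- diag(100, q)
  wishart_scale <- as.matrix(wishart_scale)
  stopifnot(nrow(wishart_scale) == q, wishart_df >= q)
  ev <- eigen(wishart_scale, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("wishart scale R must be positive definite",
                         call. = FALSE)
  V <- compute_V(Delta, graph)
  S <- solve(solve(wishart_scale) + V)
  S <- (S + t(S)) / 2
  ev2 <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev2) <= 0) {
    stop("posterior Wishart scale is not positive definite; V = ",
         paste(signif(V, 4), collapse = " "), call. = FALSE)
  }
  list(df = wishart_df + graph$I, scale = S)
}
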