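# Shared fixtures: small graphs and toy survival tables, built in code.

path_graph <- function(n = 3) {
  labels <- LETTERS[seq_len(n)]
  aft_graph(data.frame(from = labels[-n], to = labels[-1]), labels = labels)
}

# two disjoint edges on 4 nodes (2 connected components)
two_component_graph <- function() {
  aft_graph(data.frame(from = c("A", "C"), to = c("B", "D")),
            labels = c("A", "B", "C", "D"))
}

# deterministic toy survival table on a given graph
toy_data <- function(graph, J = 2, K = 4, seed = 1) {
  set.seed(seed)
  units <- rep(graph$unit_labels, each = J * K)
  years <- rep(rep(seq_len(J), each = K), times = graph$I)
  n <- length(units)
  tibble::tibble(
    time = exp(stats::rnorm(n, 0.5, 1)),
    event = stats::rbinom(n, 1, 0.8),
    unit = units, year = years,
    x1 = stats::rnorm(n), x2 = stats::rbinom(n, 1, 0.5)
  )
}

# a quick-fitting scenario on a small lattice
small_scenario <- function(scenario = "S1", J = 5, censoring = 0.2,
                           total = NULL) {
  g <- lattice_graph(2, 3)
  if (is.null(total)) total <- 5 * g$I * J + 60
  scenario_spec(scenario, graph = g, J = J, target_censoring = censoring,
                total = total)
}

fast_chain <- function(seed, n_burnin = 300, n_keep = 300) {
  chain_control(n_burnin = n_burnin, n_keep = n_keep, seed = seed)
}

# random state with dimensions matching a spec/graph
random_state <- function(spec, graph, seed = 1) {
  set.seed(seed)
  staft_state(
    mu = stats::rnorm(1),
    beta = stats::rnorm(spec$p),
    xi = stats::rnorm(spec$n_xi),
    Delta = matrix(stats::rnorm(graph$I * spec$q), graph$I, spec$q),
    sigma = stats::runif(1, 0.5, 2), spec = spec
  )
}
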