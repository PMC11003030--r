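#' Areal adjacency graphs for CAR/MCAR priors
#'
#' An `aft_graph` holds the binary neighbour matrix `C` of a set of areal
#' units (counties), the diagonal neighbour-count matrix `D_omega`, and the
#' ordered unit labels.  All frailty vectors and structure matrices in the
#' package inherit the label order of the graph.
#'
#' @param edges A data frame (or tibble) whose first two columns name the two
#'   endpoints of each undirected edge.  Duplicate edges (in either
#'   orientation) are removed silently; self-loops are an error.
#' @param labels Optional character vector fixing the unit order.  Units that
#'   appear in `labels` but in no edge become isolated units ("islands").
#'   When `NULL`, units are ordered lexicographically.
#' @return An object of class `aft_graph`: a list with elements
#'   `unit_labels`, `C` (I x I binary symmetric matrix, zero diagonal),
#'   `D_omega` (diagonal neighbour counts), `I`, `n_components` (number of
#'   connected components) and `islands` (labels with no neighbour).
#' @examples
#' g <- aft_graph(data.frame(from = c("A", "B"), to = c("B", "C")))
#' diag(g$D_omega)
#' @export
aft_graph <- function(edges, labels = NULL) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2) stop("`edges` needs at least two columns", call. = FALSE)
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  loops <- which(a == b)
  if (length(loops) > 0) {
    stop("self-loop in edge list at line ", loops[1], ": '",
         a[loops[1]], " ", b[loops[1]], "'", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- sort(unique(c(a, b)))
  } else {
    labels <- as.character(labels)
    if (anyDuplicated(labels)) stop("duplicate unit labels", call. = FALSE)
    unknown <- setdiff(unique(c(a, b)), labels)
    if (length(unknown) > 0) {
      stop("edge endpoint(s) not in `labels`: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  I <- length(labels)
  if (I < 2) stop("a graph needs at least 2 units", call. = FALSE)
  C <- matrix(0L, I, I, dimnames = list(labels, labels))
  ia <- match(a, labels)
  ib <- match(b, labels)
  C[cbind(ia, ib)] <- 1L
  C[cbind(ib, ia)] <- 1L
  new_aft_graph(C, labels)
}

new_aft_graph <- function(C, labels) {
  deg <- rowSums(C)
  structure(
    list(
      unit_labels = labels,
      C = C,
      D_omega = diag(deg, nrow = length(labels)),
      I = length(labels),
      n_components = n_components(C),
      islands = labels[deg == 0]
    ),
    class = "aft_graph"
  )
}

# connected components of a binary adjacency matrix by breadth-first search
n_components <- function(C) {
  I <- nrow(C)
  comp <- integer(I)
  k <- 0L
  for (s in seq_len(I)) {
    if (comp[s] > 0L) next
    k <- k + 1L
    frontier <- s
    comp[s] <- k
    while (length(frontier) > 0) {
      nb <- which(colSums(C[frontier, , drop = FALSE]) > 0 & comp == 0L)
      comp[nb] <- k
      frontier <- nb
    }
  }
  k
}

#' @export
print.aft_graph <- function(x, ...) {
  cat("<aft_graph> ", x$I, " units, ", sum(x$C) / 2, " edges, ",
      x$n_components, " component(s)", sep = "")
  if (length(x$islands) > 0) {
    cat(", islands: ", paste(x$islands, collapse = ", "), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Read / write an edge-list file
#'
#' Plain-text undirected edge lists: one edge per line, two whitespace- or
#' comma-separated unit labels, `#` comment lines ignored.
#'
#' @param path File path.
#' @param labels Optional ordered unit labels (see [aft_graph()]).
#' @return `read_edge_list()` returns an `aft_graph`; `write_edge_list()`
#'   returns `path` invisibly.
#' @export
read_edge_list <- function(path, labels = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]
  if (length(lines) == 0 && is.null(labels)) {
    stop("no edges in ", path, call. = FALSE)
  }
  parts <- strsplit(lines, "[,[:space:]]+")
  bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad) > 0) {
    stop("malformed edge line ", bad[1], " in ", path, call. = FALSE)
  }
  edges <- data.frame(
    from = vapply(parts, `[[`, "", 1L),
    to = vapply(parts, `[[`, "", 2L)
  )
  aft_graph(edges, labels = labels)
}

#' @param graph An `aft_graph`.
#' @rdname read_edge_list
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "aft_graph"))
  idx <- which(upper.tri(graph$C) & graph$C == 1, arr.ind = TRUE)
  lines <- paste(graph$unit_labels[idx[, 1]], graph$unit_labels[idx[, 2]])
  writeLines(c("# undirected edge list: one edge per line", lines), path)
  invisible(path)
}

#' Edge list of a graph as a tibble
#'
#' @param graph An `aft_graph`.
#' @return A tibble with columns `from`, `to`, one row per undirected edge.
#' @export
graph_edges <- function(graph) {
  stopifnot(inherits(graph, "aft_graph"))
  idx <- which(upper.tri(graph$C) & graph$C == 1, arr.ind = TRUE)
  tibble::tibble(
    from = graph$unit_labels[idx[, 1]],
    to = graph$unit_labels[idx[, 2]]
  )
}

#' Rook-adjacency rectangular lattice graph
#'
#' Convenience generator for small test graphs: units are grid cells labelled
#' `r<i>c<j>`, adjacent iff they share a grid edge.
#'
#' @param rows,cols Grid dimensions; `rows * cols >= 2`.
#' @return An `aft_graph`.
#' @examples
#' lattice_graph(2, 2)
#' @export
lattice_graph <- function(rows, cols) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1 || cols < 1 || rows * cols < 2) {
    stop("need rows * cols >= 2", call. = FALSE)
  }
  lab <- function(r, c) sprintf("r%dc%d", r, c)
  from <- character(0); to <- character(0)
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      if (c < cols) { from <- c(from, lab(r, c)); to <- c(to, lab(r, c + 1)) }
      if (r < rows) { from <- c(from, lab(r, c)); to <- c(to, lab(r + 1, c)) }
    }
  }
  labels <- as.vector(t(outer(seq_len(rows), seq_len(cols), lab)))
  aft_graph(data.frame(from = from, to = to), labels = labels)
}

#' Pennsylvania 67-county adjacency graph
#'
#' Loads the package's reconstructed adjacency structure of the 67
#' Pennsylvania counties (shared land borders).  The county border graph is
#' public geographic information; the shipped edge list was reconstructed
#' from county maps rather than copied from any single published matrix, so
#' individual borderline adjacencies (counties meeting near a corner) may
#' differ from other renderings.  Simulation results in this package are
#' insensitive to such single-edge perturbations.
#'
#' @return An `aft_graph` with 67 units ordered lexicographically by county
#'   name.
#' @export
pa_county_graph <- function() {
  path <- system.file("extdata", "pa67_adjacency.txt", package = "staft")
  if (!nzchar(path)) stop("pa67_adjacency.txt fixture not found", call. = FALSE)
  read_edge_list(path)
}

#' CAR structure (precision-kernel) matrix of a graph
#'
#' Returns `D_omega - C`, the singular structure matrix of the intrinsic CAR
#' prior.  It is symmetric positive semi-definite with zero row sums; its
#' rank is `I` minus the number of connected components.
#'
#' @param graph An `aft_graph`.
#' @return An I x I numeric matrix with unit labels as dimnames.
#' @export
car_structure_matrix <- function(graph) {
  stopifnot(inherits(graph, "aft_graph"))
  M <- graph$D_omega - graph$C
  dimnames(M) <- list(graph$unit_labels, graph$unit_labels)
  M
}

#' Export a graph's adjacency matrix as labelled CSV
#'
#' @param graph An `aft_graph`.
#' @param path Output file.
#' @export
write_adjacency_csv <- function(graph, path) {
  stopifnot(inherits(graph, "aft_graph"))
  utils::write.csv(graph$C, path, row.names = TRUE)
  invisible(path)
}
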