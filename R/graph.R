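#' Neighbor graphs for multicell simulations
#'
#' A neighbor graph holds the adjacency and the per-edge averaging weights
#' that define the neighborhood means \code{<D>_i}, \code{<N>_i} of the
#' juxtacrine coupling. Weights are nonnegative and row-normalized: each
#' cell's incoming weights sum to 1 (cells with no neighbors get a zero
#' row, i.e. zero trans flux).
#'
#' @param adjacency list of integer neighbor vectors, one per cell.
#' @param weights optional list of per-edge weights matching
#'   \code{adjacency}; defaults to equal weights \code{1/degree}.
#' @param topology label, one of \code{"HEX_PERIODIC"},
#'   \code{"SQUARE_PERIODIC"}, \code{"CUSTOM"}.
#' @return object of class \code{neighbor_graph}.
#' @export
neighbor_graph <- function(adjacency, weights = NULL, topology = "CUSTOM") {
  n <- length(adjacency)
  for (i in seq_len(n)) {
    for (j in adjacency[[i]]) {
      if (j < 1 || j > n) stop("adjacency index out of range")
      if (!(i %in% adjacency[[j]])) stop("adjacency must be symmetric")
    }
  }
  if (is.null(weights))
    weights <- lapply(adjacency, function(nb)
      if (length(nb)) rep(1 / length(nb), length(nb)) else numeric(0))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    w <- weights[[i]]
    if (length(w) != length(adjacency[[i]])) stop("weights shape mismatch")
    if (any(w < 0)) stop("weights must be nonnegative")
    if (length(w) && abs(sum(w) - 1) > 1e-9) stop("weights must sum to 1 per cell")
    W[i, adjacency[[i]]] <- w
  }
  structure(list(n_cells = n, adjacency = adjacency, weights = weights,
                 topology = topology, W = W),
            class = "neighbor_graph")
}

# Accept a neighbor_graph or a bare weight matrix.
graph_weights <- function(graph) {
  if (inherits(graph, "neighbor_graph")) graph$W
  else if (is.matrix(graph)) graph
  else stop("graph must be a neighbor_graph or a weight matrix")
}

#' Build a periodic lattice neighbor graph
#'
#' Constructs the regular cell packings used for patterning analysis:
#' a periodic hexagonal lattice (6 neighbors per cell, the standard
#' epithelial packing) or a periodic square lattice (4 neighbors). Cells are
#' indexed row-major; the hexagonal lattice uses axial coordinates on a
#' rhombic torus, so every cell has exactly six neighbors.
#'
#' @param rows,cols lattice dimensions (both >= 2 for periodic topologies;
#'   a 2-cell graph degenerates gracefully to a mutual pair).
#' @param topology \code{"HEX_PERIODIC"} or \code{"SQUARE_PERIODIC"}.
#' @return a [neighbor_graph].
#' @export
build_lattice <- function(rows, cols, topology = c("HEX_PERIODIC", "SQUARE_PERIODIC")) {
  topology <- match.arg(topology)
  if (rows < 2 || cols < 2) stop("periodic lattices need rows >= 2 and cols >= 2")
  idx <- function(r, c) as.integer(((r - 1) %% rows) * cols + ((c - 1) %% cols) + 1)
  offsets <- switch(topology,
    SQUARE_PERIODIC = list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0)),
    HEX_PERIODIC = list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0), c(1, -1), c(-1, 1)))
  adjacency <- vector("list", rows * cols)
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    nb <- unique(vapply(offsets, function(o) idx(r + o[1], c + o[2]), integer(1)))
    nb <- setdiff(nb, idx(r, c))   # small lattices can wrap onto themselves
    adjacency[[idx(r, c)]] <- sort(nb)
  }
  neighbor_graph(adjacency, topology = topology)
}

#' Two-cell mutual-neighbor graph
#'
#' @return a [neighbor_graph] of two cells that are each other's sole
#'   neighbor, used for the pair-cell analyses.
#' @export
pair_graph <- function() {
  neighbor_graph(list(2L, 1L), topology = "CUSTOM")
}

#' Mosaic (checkerboard) score of a binary cell partition
#'
#' Fraction of graph edges whose endpoints carry different labels. A perfect
#' alternating pattern on a bipartite lattice scores 1; a uniform tissue
#' scores 0; i.i.d. fair random labels score 0.5 in expectation.
#'
#' @param labels logical or two-level vector, one entry per cell.
#' @param graph a [neighbor_graph].
#' @return fraction in \[0, 1\]; \code{NaN} for a graph with no edges.
#' @export
checkerboard_score <- function(labels, graph) {
  stopifnot(inherits(graph, "neighbor_graph"))
  if (length(labels) != graph$n_cells) stop("one label per cell required")
  diff_edges <- 0L; total <- 0L
  for (i in seq_len(graph$n_cells)) {
    for (j in graph$adjacency[[i]]) {
      if (j > i) {
        total <- total + 1L
        if (labels[i] != labels[j]) diff_edges <- diff_edges + 1L
      }
    }
  }
  if (total == 0L) return(NaN)
  diff_edges / total
}
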