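#' Network topologies for metapopulations
#'
#' A topology is an undirected simple graph over `n` wells (nodes), stored as
#' a 0-based two-column edge matrix plus optional role labels ("center",
#' "side") used in reporting. Constructors are provided for the topologies of
#' interest: star, fully connected, isolated nodes, Barabasi-Albert
#' scale-free and Watts-Strogatz small-world graphs.
#'
#' @param n Number of nodes.
#' @param edges Two-column integer matrix of 0-based node indices (may have
#'   zero rows).
#' @param labels Optional character vector of node roles, length `n`.
#' @return An object of class `topology`.
#' @export
topology <- function(n, edges, labels = NULL) {
  n <- as.integer(n)
  if (is.null(dim(edges))) edges <- matrix(as.integer(edges), ncol = 2L)
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (n < 1L) stop("'n' must be >= 1", call. = FALSE)
  if (nrow(edges) > 0L) {
    if (any(edges < 0L) || any(edges >= n))
      stop("edge endpoints must lie in [0, n)", call. = FALSE)
    if (any(edges[, 1L] == edges[, 2L]))
      stop("self-loops are not allowed", call. = FALSE)
    key <- paste(pmin(edges[, 1L], edges[, 2L]),
                 pmax(edges[, 1L], edges[, 2L]))
    if (anyDuplicated(key))
      stop("multi-edges are not allowed", call. = FALSE)
    # canonical order: undirected edge stored once, small index first
    edges <- unique(cbind(pmin(edges[, 1L], edges[, 2L]),
                          pmax(edges[, 1L], edges[, 2L])))
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  if (!is.null(labels) && length(labels) != n)
    stop("'labels' must have length n", call. = FALSE)
  structure(list(n = n, edges = edges, labels = labels), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("Topology: %d nodes, %d edges\n", x$n, nrow(x$edges)))
  if (!is.null(x$labels))
    cat("  roles:", paste(unique(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname topology
#' @param n_side Number of side nodes of a star (the center is node 0).
#' @export
#' @examples
#' star_topology(9)  # the 10-node star: one center, nine sides
star_topology <- function(n_side) {
  if (n_side < 1L) stop("'n_side' must be >= 1", call. = FALSE)
  n_side <- as.integer(n_side)
  topology(n_side + 1L,
           cbind(0L, seq_len(n_side)),
           labels = c("center", rep("side", n_side)))
}

#' @rdname topology
#' @export
fully_connected <- function(n) {
  if (n < 1L) stop("'n' must be >= 1", call. = FALSE)
  idx <- utils::combn(seq_len(n) - 1L, 2L)
  topology(n, t(idx), labels = rep("node", n))
}

#' @rdname topology
#' @export
isolated_nodes <- function(n) {
  topology(n, matrix(integer(0), ncol = 2L), labels = rep("node", n))
}

from_igraph <- function(g, labels = NULL) {
  e <- igraph::as_edgelist(g, names = FALSE) - 1L
  topology(igraph::vcount(g), e, labels = labels)
}

#' @rdname topology
#' @param m_attach Edges added per step in preferential attachment.
#' @param seed Integer seed; generation is reproducible given the seed.
#' @export
barabasi_albert <- function(n = 100, m_attach = 2, seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (m_attach >= n) stop("'m_attach' must be < n", call. = FALSE)
  g <- withr::with_seed(seed,
    igraph::sample_pa(n, m = m_attach, directed = FALSE))
  from_igraph(g)
}

#' @rdname topology
#' @param k Even number of ring-lattice neighbours per node.
#' @param p Rewiring probability; `p = 0` gives the ring lattice.
#' @export
watts_strogatz <- function(n = 100, k = 4, p = 0.1, seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (k %% 2 != 0) stop("'k' must be even", call. = FALSE)
  g <- withr::with_seed(seed,
    igraph::sample_smallworld(1, n, k / 2, p, loops = FALSE,
                              multiple = FALSE))
  g <- igraph::simplify(g)
  from_igraph(g)
}

#' Degree sequence and degree variance
#'
#' @param topo A [topology()].
#' @return `degrees()`: integer vector of node degrees. `degree_variance()`:
#'   the population variance (divisor `n`) of the degree sequence, the
#'   heterogeneity measure that separates star and scale-free graphs from
#'   regular ones.
#' @export
#' @examples
#' degree_variance(star_topology(9))   # 5.76
#' degree_variance(fully_connected(10))  # 0
degrees <- function(topo) {
  stopifnot(inherits(topo, "topology"))
  tabulate(c(topo$edges[, 1L], topo$edges[, 2L]) + 1L, nbins = topo$n)
}

#' @rdname degrees
#' @export
degree_variance <- function(topo) {
  d <- degrees(topo)
  mean((d - mean(d))^2)
}

#' Per-cycle migration operator
#'
#' Builds the column-stochastic dispersal matrix of a topology: each node with
#' at least one neighbour exports a fraction `m` of its cells per cycle,
#' divided evenly among its neighbours, and keeps the fraction `1 - m`;
#' isolated nodes keep everything. Because every node exports the same
#' fraction regardless of degree, while imports per link scale as
#' `m / deg(source)`, migration across links between unequal-degree nodes is
#' asymmetric: in a star the center receives `m` of each side node but
#' returns only `m / n_side` to each.
#'
#' @param topo A [topology()].
#' @param m Migration rate per cycle, in `[0, 1]`.
#' @return An object of class `migration_operator` with elements `M` (the
#'   n x n matrix, columns = source nodes, every column summing to 1) and `m`.
#' @export
#' @examples
#' op <- migration_matrix(star_topology(9), m = 0.6)
#' colSums(op$M)  # all exactly 1: cell numbers are conserved
migration_matrix <- function(topo, m) {
  stopifnot(inherits(topo, "topology"))
  if (length(m) != 1L || !is.finite(m) || m < 0 || m > 1)
    stop("'m' must be a single number in [0, 1]", call. = FALSE)
  n <- topo$n
  deg <- degrees(topo)
  M <- matrix(0, n, n)
  if (nrow(topo$edges) > 0L) {
    i <- topo$edges[, 1L] + 1L
    j <- topo$edges[, 2L] + 1L
    M[cbind(i, j)] <- m / deg[j]   # flow j -> i
    M[cbind(j, i)] <- m / deg[i]   # flow i -> j
  }
  diag(M) <- ifelse(deg >= 1L, 1 - m, 1)
  structure(list(M = M, m = m), class = "migration_operator")
}

#' Apply migration to a metapopulation state
#'
#' Redistributes both strains simultaneously with the same operator, computed
#' from the pre-migration state (all transfers happen at once, not
#' sequentially). Column-stochasticity makes the total of each strain exactly
#' conserved.
#'
#' @param state n x 2 state matrix (see [node_state()]).
#' @param op A [migration_matrix()] operator.
#' @return The post-migration n x 2 state matrix.
#' @export
migrate <- function(state, op) {
  stopifnot(inherits(op, "migration_operator"))
  validate_state(state)
  if (nrow(state) != nrow(op$M))
    stop(sprintf("state has %d nodes but operator expects %d",
                 nrow(state), nrow(op$M)), call. = FALSE)
  out <- op$M %*% state
  dimnames(out) <- dimnames(state)
  out
}

#' Read and write topologies as plain-text edge lists
#'
#' The file format is two whitespace-separated integer columns of 0-based
#' node indices, one edge per line. `n` is inferred as `max(index) + 1`
#' unless given.
#'
#' @param path File path.
#' @param topo A [topology()].
#' @param n Optional node count override (to include trailing isolated nodes).
#' @return `read_edgelist()` returns a [topology()]; `write_edgelist()`
#'   returns `path` invisibly.
#' @export
read_edgelist <- function(path, n = NULL) {
  e <- utils::read.table(path, header = FALSE,
                         colClasses = c("integer", "integer"))
  e <- as.matrix(e)
  if (is.null(n)) n <- max(e) + 1L
  topology(n, e)
}

#' @rdname read_edgelist
#' @export
write_edgelist <- function(topo, path) {
  stopifnot(inherits(topo, "topology"))
  utils::write.table(topo$edges, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
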