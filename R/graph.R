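# Graph representation, synthetic generators, partitions, and plain-text IO.
# Vertex ids and part ids are 0-based integers throughout the package.

#' Construct an SIS graph
#'
#' A fixed undirected graph with per-vertex epidemic states. Adjacency is
#' stored as per-vertex sorted 0-based neighbor lists; edges are
#' symmetrized and deduplicated. Self-loops are not allowed.
#'
#' @param n_vertices Number of vertices; ids are `0..n_vertices-1`.
#' @param edges Two-column integer matrix of 0-based vertex pairs (each
#'   undirected edge listed once, in either orientation).
#' @param initial_states Integer vector of per-vertex states
#'   (0 = susceptible, 1 = infected); defaults to all susceptible.
#' @return An object of class `sis_graph` with fields `n_vertices`,
#'   `adjacency` (list of sorted integer vectors) and `initial_states`.
#' @export
sis_graph <- function(n_vertices, edges = NULL, initial_states = NULL) {
  n_vertices <- as.integer(n_vertices)
  if (length(n_vertices) != 1L || is.na(n_vertices) || n_vertices < 1L)
    stop("n_vertices must be a positive integer")
  if (is.null(edges)) {
    edges <- matrix(integer(0), ncol = 2)
  }
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    if (anyNA(edges) || min(edges) < 0L || max(edges) >= n_vertices)
      stop("edge endpoints must be vertex ids in 0..n_vertices-1")
    if (any(edges[, 1] == edges[, 2]))
      stop("self-loops are not allowed")
  }
  if (is.null(initial_states)) initial_states <- integer(n_vertices)
  initial_states <- as.integer(initial_states)
  if (length(initial_states) != n_vertices ||
      anyNA(initial_states) || !all(initial_states %in% c(0L, 1L)))
    stop("initial_states must be a 0/1 vector of length n_vertices")

  # symmetrize + dedupe, then split into sorted per-vertex lists
  if (nrow(edges) > 0) {
    lo <- pmin(edges[, 1], edges[, 2])
    hi <- pmax(edges[, 1], edges[, 2])
    key <- as.numeric(lo) * n_vertices + hi
    keep <- !duplicated(key)
    lo <- lo[keep]; hi <- hi[keep]
    src <- c(lo, hi); dst <- c(hi, lo)
    ord <- order(src, dst)
    src <- src[ord]; dst <- dst[ord]
    adjacency <- unname(split(dst, factor(src, levels = 0:(n_vertices - 1L))))
  } else {
    adjacency <- rep(list(integer(0)), n_vertices)
  }
  structure(
    list(n_vertices = n_vertices, adjacency = adjacency,
         initial_states = initial_states),
    class = "sis_graph")
}

#' @export
print.sis_graph <- function(x, ...) {
  cat(sprintf("<sis_graph> %d vertices, %d edges, %d infected\n",
              x$n_vertices, sum(lengths(x$adjacency)) %/% 2L,
              sum(x$initial_states)))
  invisible(x)
}

#' Vertex degrees
#' @param graph An `sis_graph`.
#' @return Integer vector of vertex degrees (0-based vertex order).
#' @export
graph_degrees <- function(graph) lengths(graph$adjacency)

#' Number of undirected edges
#' @param graph An `sis_graph`.
#' @export
graph_n_edges <- function(graph) sum(lengths(graph$adjacency)) %/% 2L

#' Edge list of a graph
#' @param graph An `sis_graph`.
#' @return Two-column integer matrix, one row per undirected edge with
#'   the smaller endpoint first.
#' @export
graph_edges <- function(graph) {
  src <- rep.int(0:(graph$n_vertices - 1L), lengths(graph$adjacency))
  dst <- unlist(graph$adjacency, use.names = FALSE)
  if (length(src) == 0) return(matrix(integer(0), ncol = 2))
  keep <- src < dst
  cbind(src[keep], dst[keep])
}

# CSR view consumed by the compiled engine
graph_csr <- function(graph) {
  list(off = c(0L, cumsum(lengths(graph$adjacency))),
       nbr = as.integer(unlist(graph$adjacency, use.names = FALSE)))
}

#' Sparse adjacency matrix
#' @param graph An `sis_graph`.
#' @return A symmetric sparse 0/1 `dgCMatrix` (1-based row/column index
#'   `i+1` for vertex `i`).
#' @export
graph_adjacency_matrix <- function(graph) {
  src <- rep.int(0:(graph$n_vertices - 1L), lengths(graph$adjacency))
  dst <- unlist(graph$adjacency, use.names = FALSE)
  Matrix::sparseMatrix(i = src + 1L, j = dst + 1L, x = 1,
                       dims = c(graph$n_vertices, graph$n_vertices))
}

# run expr under a seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate an Erdos-Renyi random graph
#'
#' Samples G(n, p): each unordered vertex pair is an edge independently
#' with probability `edge_prob`. Deterministic under `seed`.
#'
#' @param n_vertices Number of vertices.
#' @param edge_prob Edge probability in \[0, 1\].
#' @param seed Integer seed.
#' @return An `sis_graph` (all vertices initially susceptible).
#' @export
generate_erdos_renyi <- function(n_vertices, edge_prob, seed) {
  if (!is.numeric(edge_prob) || edge_prob < 0 || edge_prob > 1)
    stop("edge_prob must be a probability in [0, 1]")
  if (n_vertices < 1) stop("n_vertices must be positive")
  el <- with_seed(seed, {
    g <- igraph::sample_gnp(n_vertices, edge_prob)
    igraph::as_edgelist(g, names = FALSE)
  })
  sis_graph(n_vertices, matrix(as.integer(el) - 1L, ncol = 2))
}

#' Generate a stochastic block model graph
#'
#' Blocks are the contiguous vertex ranges
#' `[k * block_size, (k + 1) * block_size)` for `k = 0..n_blocks-1`.
#' Within-block pairs are edges with probability `p_within`, cross-block
#' pairs with probability `p_between`.
#'
#' @param n_blocks Number of blocks.
#' @param block_size Vertices per block.
#' @param p_within Within-block edge probability.
#' @param p_between Cross-block edge probability.
#' @param seed Integer seed.
#' @return An `sis_graph`.
#' @export
generate_sbm <- function(n_blocks, block_size, p_within, p_between, seed) {
  for (p in c(p_within, p_between))
    if (!is.numeric(p) || p < 0 || p > 1)
      stop("block probabilities must be in [0, 1]")
  if (n_blocks < 1 || block_size < 1)
    stop("n_blocks and block_size must be positive")
  n <- n_blocks * block_size
  pref <- matrix(p_between, n_blocks, n_blocks)
  diag(pref) <- p_within
  el <- with_seed(seed, {
    g <- igraph::sample_sbm(n, pref.matrix = pref,
                            block.sizes = rep(block_size, n_blocks))
    igraph::as_edgelist(g, names = FALSE)
  })
  sis_graph(n, matrix(as.integer(el) - 1L, ncol = 2))
}

#' Within-block probability from a mean-degree constraint
#'
#' For a stochastic block model with `n_blocks` equal blocks of size `n`
#' in a graph of `N = total_vertices` vertices, the mean degree is
#' `<D> = p_i (n - 1) + p_o (N - n)`. Given the target mean degree and
#' the cross-block probability `p_o`, returns the within-block
#' probability `p_i` solving this identity.
#'
#' @param mean_degree Target mean degree `<D>`.
#' @param total_vertices Total number of vertices `N`.
#' @param block_size Block size `n`.
#' @param p_between Cross-block edge probability `p_o`.
#' @return The within-block probability `p_i`.
#' @export
sbm_within_prob <- function(mean_degree, total_vertices, block_size,
                            p_between) {
  p_i <- (mean_degree - p_between * (total_vertices - block_size)) /
    (block_size - 1)
  if (p_i < -1e-12 || p_i > 1 + 1e-12)
    stop(sprintf("infeasible parameters: p_i = %g is outside [0, 1]", p_i))
  min(max(p_i, 0), 1)
}

#' Uniform vertex partition
#'
#' Splits the vertex set into `n_parts` parts independent of vertex
#' states and connectivity. The default `"even"` method shuffles vertex
#' ids and assigns them round-robin, so part sizes differ by at most one.
#' Method `"iid"` draws each vertex's part independently and uniformly
#' (the idealization used by the load analysis); it errors if a part
#' comes out empty.
#'
#' @param graph An `sis_graph`.
#' @param n_parts Number of parts `M`.
#' @param seed Integer seed.
#' @param method `"even"` (default) or `"iid"`.
#' @return An `sis_partition`: list with `part_of` (0-based part index
#'   per vertex) and `n_parts`.
#' @export
partition_uniform <- function(graph, n_parts, seed,
                              method = c("even", "iid")) {
  method <- match.arg(method)
  n <- graph$n_vertices
  n_parts <- as.integer(n_parts)
  if (n_parts < 1 || n_parts > n)
    stop("n_parts must be between 1 and n_vertices (parts must be non-empty)")
  part_of <- integer(n)
  if (method == "even") {
    ord <- with_seed(seed, sample.int(n))
    part_of[ord] <- (seq_len(n) - 1L) %% n_parts
  } else {
    part_of <- with_seed(seed, sample.int(n_parts, n, replace = TRUE) - 1L)
    if (length(unique(part_of)) < n_parts)
      stop("iid partition produced an empty part; re-seed or use method='even'")
  }
  new_partition(part_of, n_parts)
}

#' Block-aligned partition
#'
#' Partitions contiguous vertex ranges into equal blocks, matching the
#' block structure of [generate_sbm()].
#'
#' @param graph An `sis_graph`.
#' @param n_parts Number of equal contiguous parts (must divide
#'   `n_vertices`).
#' @return An `sis_partition`.
#' @export
partition_blocks <- function(graph, n_parts) {
  n <- graph$n_vertices
  if (n %% n_parts != 0)
    stop("n_parts must divide n_vertices for a block partition")
  new_partition(rep(0:(n_parts - 1L), each = n %/% n_parts),
                as.integer(n_parts))
}

new_partition <- function(part_of, n_parts) {
  part_of <- as.integer(part_of)
  n_parts <- as.integer(n_parts)
  if (anyNA(part_of) || any(part_of < 0L) || any(part_of >= n_parts))
    stop("part indices must lie in 0..n_parts-1")
  if (length(unique(part_of)) < n_parts)
    stop("every part must be non-empty")
  structure(list(part_of = part_of, n_parts = n_parts),
            class = "sis_partition")
}

#' @export
print.sis_partition <- function(x, ...) {
  cat(sprintf("<sis_partition> %d parts, sizes %s\n", x$n_parts,
              paste(tabulate(x$part_of + 1L, x$n_parts), collapse = ", ")))
  invisible(x)
}

#' Infect a random vertex subset
#'
#' Marks `round(fraction * n)` vertices as initially infected, sampled
#' uniformly without replacement, independent of states and connectivity.
#'
#' @param graph An `sis_graph`.
#' @param fraction Fraction of vertices to infect.
#' @param seed Integer seed.
#' @return The graph with updated `initial_states`.
#' @export
infect_random <- function(graph, fraction, seed) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  k <- round(fraction * graph$n_vertices)
  ids <- with_seed(seed, sample.int(graph$n_vertices, k)) - 1L
  set_infected(graph, ids)
}

#' Set the initially infected vertex set
#' @param graph An `sis_graph`.
#' @param ids 0-based vertex ids to mark infected (all others susceptible).
#' @export
set_infected <- function(graph, ids) {
  ids <- as.integer(ids)
  if (length(ids) && (min(ids) < 0L || max(ids) >= graph$n_vertices))
    stop("infected ids out of range")
  st <- integer(graph$n_vertices)
  st[ids + 1L] <- 1L
  graph$initial_states <- st
  graph
}

# ---- plain-text IO ---------------------------------------------------------

#' Read an edge-list file
#'
#' Reads whitespace-separated vertex pairs, one per line (the common
#' SNAP-style dialect). Blank lines and lines starting with `#` are
#' ignored; repeated pairs are deduplicated, the edge set is
#' symmetrized, and self-loops are dropped. Cleaning counts are
#' reported via `message()`.
#'
#' @param path File path.
#' @param n_vertices Optional vertex count (defaults to max id + 1).
#' @return An `sis_graph`.
#' @export
read_edgelist <- function(path, n_vertices = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    if (is.null(n_vertices)) stop("empty edge list and no n_vertices given")
    return(sis_graph(n_vertices))
  }
  parts <- strsplit(lines, "[[:space:]]+")
  u <- as.integer(vapply(parts, `[[`, "", 1L))
  v <- as.integer(vapply(parts, `[[`, "", 2L))
  if (anyNA(u) || anyNA(v)) stop("malformed edge-list line")
  self <- u == v
  n_self <- sum(self)
  u <- u[!self]; v <- v[!self]
  if (is.null(n_vertices)) n_vertices <- max(u, v) + 1L
  lo <- pmin(u, v); hi <- pmax(u, v)
  n_dup <- sum(duplicated(as.numeric(lo) * n_vertices + hi))
  if (n_self > 0 || n_dup > 0)
    message(sprintf("read_edgelist: dropped %d self-loop(s), %d duplicate pair(s)",
                    n_self, n_dup))
  sis_graph(n_vertices, cbind(u, v))
}

#' Write an edge-list file
#' @param graph An `sis_graph`.
#' @param path File path; one `u v` pair per undirected edge.
#' @export
write_edgelist <- function(graph, path) {
  e <- graph_edges(graph)
  writeLines(paste(e[, 1], e[, 2]), path)
}

#' Read a partition file
#'
#' Line `i` (1-based) holds the part index of vertex `i - 1`, the
#' dialect written by standard graph partitioners.
#'
#' @param path File path.
#' @return An `sis_partition`.
#' @export
read_partition <- function(path) {
  part_of <- as.integer(readLines(path))
  if (anyNA(part_of)) stop("malformed partition file")
  new_partition(part_of, max(part_of) + 1L)
}

#' Write a partition file
#' @param partition An `sis_partition`.
#' @param path File path.
#' @export
write_partition <- function(partition, path) {
  writeLines(as.character(partition$part_of), path)
}

#' Read an initial-infected file (one 0-based vertex id per line)
#' @param path File path.
#' @return Integer vector of vertex ids.
#' @export
read_infected <- function(path) {
  ids <- as.integer(readLines(path))
  if (anyNA(ids)) stop("malformed infected-id file")
  ids
}

#' Write an initial-infected file
#' @param ids Integer vector of 0-based vertex ids.
#' @param path File path.
#' @export
write_infected <- function(ids, path) {
  writeLines(as.character(as.integer(ids)), path)
}
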