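# Border precomputation: which vertices of each part border which other
# parts, how many remote neighbors each vertex has per part, and the
# induced process graph. Computed once from (graph, partition) and never
# mutated during simulation.

#' Build the border table of a partitioned graph
#'
#' For every ordered process pair (P, Q), the border list `B_{P->Q}`
#' contains the vertices of P with at least one neighbor on Q, and
#' `N_{P->Q} = |B_{P->Q}|`. For every vertex v and remote part Q,
#' `n_{Q->v}` counts v's neighbors on Q. The directed process graph has
#' an edge (P, Q) whenever `N_{P->Q} > 0`.
#'
#' @param graph An `sis_graph`.
#' @param partition An `sis_partition` over the same vertex set.
#' @return An `sis_border_table`: list with `n_parts`, `channels`
#'   (data.frame `sender`, `receiver`, `border_size`), `border_lists`
#'   (list of sorted vertex-id vectors, parallel to `channels` rows),
#'   `remote_counts` (sparse `n x M` matrix; entry (v+1, Q+1) is
#'   `n_{Q->v}`) and `process_edges` (two-column matrix of directed
#'   part pairs).
#' @export
build_border_table <- function(graph, partition) {
  stopifnot(inherits(graph, "sis_graph"), inherits(partition, "sis_partition"))
  n <- graph$n_vertices
  if (length(partition$part_of) != n)
    stop("partition does not cover this graph's vertex set")
  M <- partition$n_parts
  part <- partition$part_of
  src <- rep.int(0:(n - 1L), lengths(graph$adjacency))
  dst <- unlist(graph$adjacency, use.names = FALSE)
  cross <- part[src + 1L] != part[dst + 1L]
  src <- src[cross]; dst <- dst[cross]
  # n_{Q->v}: directed cross edge (dst -> src orientation): neighbor dst of
  # vertex src lives on part[dst]
  remote_counts <- Matrix::sparseMatrix(
    i = src + 1L, j = part[dst + 1L] + 1L, x = 1, dims = c(n, M))
  tr <- Matrix::summary(remote_counts)  # (v, Q, n_{Q->v})
  if (nrow(tr) > 0) {
    v_id <- tr$i - 1L
    qp <- tr$j - 1L
    pp <- part[tr$i]
    key <- factor(paste(pp, qp, sep = ">"),
                  levels = unique(paste(pp, qp, sep = ">")[order(pp, qp)]))
    border_lists <- lapply(split(v_id, key), sort)
    pq <- do.call(rbind, strsplit(names(border_lists), ">", fixed = TRUE))
    channels <- data.frame(sender = as.integer(pq[, 1]),
                           receiver = as.integer(pq[, 2]),
                           border_size = lengths(border_lists))
    rownames(channels) <- NULL
    names(border_lists) <- NULL
  } else {
    channels <- data.frame(sender = integer(0), receiver = integer(0),
                           border_size = integer(0))
    border_lists <- list()
  }
  structure(
    list(n_parts = M, channels = channels, border_lists = border_lists,
         remote_counts = remote_counts,
         process_edges = cbind(channels$sender, channels$receiver)),
    class = "sis_border_table")
}

#' @export
print.sis_border_table <- function(x, ...) {
  cat(sprintf("<sis_border_table> %d parts, %d process-graph edges\n",
              x$n_parts, nrow(x$channels)))
  invisible(x)
}

channel_row <- function(borders, sender, receiver) {
  which(borders$channels$sender == sender &
          borders$channels$receiver == receiver)
}

#' Border size N_{P->Q}
#' @param borders An `sis_border_table`.
#' @param sender,receiver 0-based part ids P and Q.
#' @return Number of vertices of P bordering Q (0 when the parts share
#'   no edge).
#' @export
border_size <- function(borders, sender, receiver) {
  r <- channel_row(borders, sender, receiver)
  if (length(r) == 0) 0L else borders$channels$border_size[r]
}

#' Border vertex list B_{P->Q}
#' @inheritParams border_size
#' @return Sorted 0-based ids of the vertices of P bordering Q.
#' @export
border_vertices <- function(borders, sender, receiver) {
  r <- channel_row(borders, sender, receiver)
  if (length(r) == 0) integer(0) else borders$border_lists[[r]]
}

#' Remote neighbor count n_{Q->v}
#' @param borders An `sis_border_table`.
#' @param v 0-based vertex id.
#' @param q 0-based remote part id Q.
#' @export
remote_neighbor_count <- function(borders, v, q) {
  as.integer(borders$remote_counts[v + 1L, q + 1L])
}

#' Border infection summary n_{P->Q}
#'
#' The summary statistic a process sends: the number of infected
#' vertices on P bordering Q, evaluated on the given state vector.
#'
#' @param borders An `sis_border_table`.
#' @param states 0/1 state vector over all vertices.
#' @param sender,receiver 0-based part ids P and Q.
#' @export
compute_summary <- function(borders, states, sender, receiver) {
  r <- channel_row(borders, sender, receiver)
  if (length(r) == 0)
    stop("no channel: the parts share no edge")
  sum(states[borders$border_lists[[r]] + 1L])
}

#' Mean-field remote infection rate
#'
#' Rate of the event Inf(Q -> v): the number of v's neighbors on Q,
#' times the border infection probability `n_{Q->P} / N_{Q->P}`, times
#' the per-edge infection rate.
#'
#' @param n_neighbors_on_q Count of v's neighbors on the remote part Q.
#' @param n_qp Infected border count `n_{Q->P}` from the last message.
#' @param n_qp_total Border size `N_{Q->P}` (must be >= 1).
#' @param beta Per-edge infection rate.
#' @export
remote_infection_rate <- function(n_neighbors_on_q, n_qp, n_qp_total, beta) {
  if (n_qp_total < 1) stop("N_{Q->P} must be at least 1")
  if (n_qp < 0 || n_qp > n_qp_total)
    stop("n_{Q->P} must lie in 0..N_{Q->P}")
  n_neighbors_on_q * (n_qp / n_qp_total) * beta
}

#' Expected number of distinct bordered processes per vertex
#'
#' Under i.i.d. uniform part membership over M parts, a vertex of
#' degree D borders `mu_v = |{parts of its neighbors} \ {own part}|`
#' distinct remote processes, with expectation
#' `(M - 1) * (1 - psi(1 - 1/M))` where `psi` is the probability
#' generating function of the degree distribution.
#'
#' @param n_parts Number of parts M.
#' @param degree_pmf Probability vector over degrees `0, 1, 2, ...`
#'   (element `d + 1` is `Pr(D = d)`); must sum to 1.
#' @export
expected_border_process_count <- function(n_parts, degree_pmf) {
  if (abs(sum(degree_pmf) - 1) > 1e-8)
    stop("degree_pmf must sum to 1")
  if (any(degree_pmf < 0)) stop("degree_pmf must be non-negative")
  M <- n_parts
  x <- 1 - 1 / M
  psi <- sum(degree_pmf * x^(seq_along(degree_pmf) - 1))
  (M - 1) * (1 - psi)
}

#' Worst-case message count of the summary-mode engine
#'
#' Each process sends at most M - 1 summary payloads per epoch and the
#' epoch loop runs `ceil(H / Delta)` times, so the total message count
#' is at most `ceil(H / Delta) * M * (M - 1)`, with equality when the
#' process graph is complete.
#'
#' @param horizon Simulation horizon H.
#' @param delta Epoch length.
#' @param n_parts Number of parts M.
#' @export
message_bound <- function(horizon, delta, n_parts) {
  if (delta <= 0) stop("delta must be positive")
  ceiling(horizon / delta - 1e-12) * n_parts * (n_parts - 1)
}
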