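# Time-driven baselines: the practitioners' rejection-sampling scheme and
# the exact per-epoch transition-matrix variant.

#' Exact one-epoch transition matrix of a vertex
#'
#' For a vertex with constant infection pressure `beta_v` and recovery
#' rate `gamma` over an epoch of length `delta`, the state follows a
#' two-state continuous-time Markov chain with rate matrix
#' `Q = [[-gamma, gamma], [beta_v, -beta_v]]` over states (INF, SUS).
#' Returns `expm(delta * Q)` in closed form; the degenerate case
#' `gamma = beta_v = 0` (or `delta = 0`) gives the identity.
#'
#' @param beta_v Total infection rate toward the vertex.
#' @param gamma Recovery rate.
#' @param delta Epoch length (>= 0).
#' @return A 2x2 row-stochastic matrix with rows/columns ("INF", "SUS").
#' @export
epoch_transition_exact <- function(beta_v, gamma, delta) {
  if (beta_v < 0 || gamma < 0 || delta < 0)
    stop("beta_v, gamma and delta must be non-negative")
  s <- beta_v + gamma
  if (s == 0 || delta == 0) {
    m <- diag(2)
  } else {
    e <- exp(-delta * s)
    m <- matrix(c((beta_v + gamma * e) / s, gamma * (1 - e) / s,
                  beta_v * (1 - e) / s, (gamma + beta_v * e) / s),
                nrow = 2, byrow = TRUE)
  }
  dimnames(m) <- list(c("INF", "SUS"), c("INF", "SUS"))
  m
}

tds_loop <- function(graph, beta, gamma, delta, horizon, seed, step_fn) {
  check_sim_args(graph, beta, gamma, horizon)
  if (delta <= 0) stop("delta must be positive")
  A <- graph_adjacency_matrix(graph)
  states <- graph$initial_states
  L <- ceiling(horizon / delta - 1e-12)
  counts <- integer(L + 1L)
  counts[1L] <- sum(states)
  with_seed(seed, {
    for (l in seq_len(L)) {
      d <- min(delta, horizon - (l - 1) * delta)
      states <- step_fn(states, A, d)
      counts[l + 1L] <- sum(states)
    }
  })
  res <- list(counts = counts, final_states = states)
  new_trajectory(res, graph,
                 list(engine = "tds", beta = beta, gamma = gamma,
                      delta = delta, horizon = horizon, seed = seed),
                 delta)
}

#' Time-driven SIS simulation with rejection sampling
#'
#' Synchronous update in epochs of length `delta`: every infected
#' vertex recovers with probability `1 - exp(-gamma * delta)`; every
#' susceptible vertex with `n_v` infected neighbors (counted at the
#' epoch start) becomes infected with probability
#' `1 - exp(-n_v * beta * delta)`. All flips are applied simultaneously
#' at the epoch end, so a vertex changes state at most once per epoch.
#'
#' @inheritParams run_sequential
#' @param delta Epoch length.
#' @return An `sis_trajectory` (counts at multiples of `delta`; no
#'   event log, as the scheme has no within-epoch event times).
#' @export
run_tds_rejection <- function(graph, beta, gamma, delta, horizon, seed = 1L) {
  tds_loop(graph, beta, gamma, delta, horizon, seed, function(states, A, d) {
    n_inf_nbr <- as.vector(A %*% states)
    u <- stats::runif(length(states))
    flip <- ifelse(states == 1L,
                   u < 1 - exp(-gamma * d),
                   u < 1 - exp(-n_inf_nbr * beta * d))
    as.integer(xor(states == 1L, flip))
  })
}

#' Time-driven SIS simulation with the exact epoch transition matrix
#'
#' Like [run_tds_rejection()] but each vertex samples its end-of-epoch
#' state from the exact two-state CTMC transition matrix
#' [epoch_transition_exact()] with `beta_v = beta *` (infected-neighbor
#' count at the epoch start), which permits within-epoch re-infection
#' and recovery chains. This is the time-driven scheme the partitioned
#' engine degenerates to when every vertex is its own process.
#'
#' @inheritParams run_tds_rejection
#' @param rate_fn Optional `function(states, l)` returning the
#'   per-vertex infection pressure `beta_v` for epoch `l` (defaults to
#'   `beta` times the infected-neighbor count), allowing externally
#'   supplied mean-field rates.
#' @export
run_tds_exact <- function(graph, beta, gamma, delta, horizon, seed = 1L,
                          rate_fn = NULL) {
  l_cur <- 0L
  tds_loop(graph, beta, gamma, delta, horizon, seed, function(states, A, d) {
    l_cur <<- l_cur + 1L
    beta_v <- if (is.null(rate_fn)) beta * as.vector(A %*% states)
              else rate_fn(states, l_cur)
    s <- beta_v + gamma
    e <- exp(-d * s)
    # P(INF at epoch end): from INF row 1 col 1, from SUS row 2 col 1
    p_inf <- ifelse(s == 0, as.numeric(states == 1L),
                    ifelse(states == 1L,
                           (beta_v + gamma * e) / s,
                           beta_v * (1 - e) / s))
    as.integer(stats::runif(length(states)) < p_inf)
  })
}
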