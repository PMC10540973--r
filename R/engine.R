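# R surface over the compiled event engine: the sequential next-reaction
# baseline and the epoch-synchronized partitioned engine.

KIND_LEVELS <- c("recovery", "infection_local", "infection_remote")

new_trajectory <- function(res, graph, params, delta_obs) {
  has_events <- !is.null(res$time)
  events <- if (has_events) {
    data.frame(time = res$time,
               kind = factor(KIND_LEVELS[res$kind + 1L],
                             levels = KIND_LEVELS),
               source = res$source,
               target = res$target)
  } else NULL
  l <- seq_along(res$counts) - 1L
  counts <- data.frame(l = l, time = l * delta_obs, count = res$counts)
  structure(
    list(events = events, counts = counts,
         final_states = res$final_states, params = params),
    class = "sis_trajectory")
}

#' @export
print.sis_trajectory <- function(x, ...) {
  cat(sprintf("<sis_trajectory> %s events, %d sample points, final infected %d\n",
              if (is.null(x$events)) "no logged" else
                format(nrow(x$events), big.mark = ","),
              nrow(x$counts), sum(x$final_states)))
  invisible(x)
}

#' Draw the scheduled time of an exponential-clock event
#'
#' Returns `now + T` with `T ~ Exp(rate)`, or `NA` (no event is ever
#' scheduled) when the rate is zero. Uses R's RNG stream.
#'
#' @param now Current time.
#' @param rate Non-negative event rate.
#' @export
draw_event_time <- function(now, rate) {
  if (rate < 0) stop("rate must be non-negative")
  if (rate == 0) return(NA_real_)
  now + stats::rexp(1, rate)
}

check_sim_args <- function(graph, beta, gamma, horizon) {
  stopifnot(inherits(graph, "sis_graph"))
  if (beta < 0 || gamma < 0) stop("beta and gamma must be non-negative")
  if (horizon <= 0) stop("horizon must be positive")
}

#' Sequential event-driven SIS simulation
#'
#' The exact next-reaction baseline (the partitioned engine at M = 1):
#' exponential per-edge infection clocks and per-vertex recovery clocks
#' race in an indexed priority queue; events are processed in time order
#' until the queue empties or the horizon is reached.
#'
#' @param graph An `sis_graph` (its `initial_states` seed the epidemic).
#' @param beta Per-edge infection rate.
#' @param gamma Recovery rate.
#' @param horizon Simulation horizon H.
#' @param delta_obs Spacing of the infection-count observation grid.
#' @param seed Integer seed for the engine's own random stream.
#' @param validate Check state/queue consistency after every event
#'   (for testing on small graphs; slow).
#' @return An `sis_trajectory` with the event log, the infection counts
#'   `C_l` sampled at multiples of `delta_obs`, and the final states.
#' @export
run_sequential <- function(graph, beta, gamma, horizon, delta_obs = 1,
                           seed = 1L, validate = FALSE) {
  check_sim_args(graph, beta, gamma, horizon)
  if (delta_obs <= 0) stop("delta_obs must be positive")
  csr <- graph_csr(graph)
  res <- .cpp_run_sequential(csr$off, csr$nbr, graph$initial_states,
                             beta, gamma, horizon, delta_obs,
                             as.numeric(seed), validate)
  new_trajectory(res, graph,
                 list(engine = "sequential", beta = beta, gamma = gamma,
                      horizon = horizon, delta_obs = delta_obs, seed = seed),
                 delta_obs)
}

#' Partitioned epoch-synchronized SIS simulation
#'
#' Runs M per-part event-driven engines that advance in epochs of
#' length `delta`. At the start of every epoch each process sends, for
#' each neighboring process, either the border infection summary
#' `n_{P->Q}` (`mode = "summary"`) or the full border state bitmask
#' (`mode = "ghost"`, `ceiling(N_{P->Q}/64)` 64-bit words), computed
#' from its state at the epoch boundary. On receipt, every pending
#' remote-infection clock Inf(Q -> v) is re-drawn at the fresh rate
#' (summary mode: `n_{Q->v} * n_{Q->P}/N_{Q->P} * beta`; ghost mode:
#' `beta` times v's infected snapshot neighbors on Q) and dropped when
#' the rate vanishes. Local events keep their absolute times across
#' epoch boundaries. With M = 1 there are no channels and the run is
#' bit-identical to [run_sequential()] at the same seed.
#'
#' @inheritParams run_sequential
#' @param partition An `sis_partition` with non-empty parts.
#' @param delta Epoch length.
#' @param mode `"summary"` or `"ghost"`.
#' @param delta_obs Observation-grid spacing (defaults to `delta`).
#' @return A list with `trajectory` (an `sis_trajectory`, the merged
#'   time-sorted event log of all processes) and `messages` (an
#'   `sis_message_stats`: total payload count, per-channel counts, and
#'   the epoch count `ceil(H/delta)`).
#' @export
run_partitioned <- function(graph, partition, beta, gamma, delta, horizon,
                            mode = c("summary", "ghost"), seed = 1L,
                            delta_obs = delta, validate = FALSE) {
  mode <- match.arg(mode)
  check_sim_args(graph, beta, gamma, horizon)
  stopifnot(inherits(partition, "sis_partition"))
  if (length(partition$part_of) != graph$n_vertices)
    stop("partition does not cover this graph's vertex set")
  if (delta <= 0) stop("delta must be positive")
  if (delta_obs <= 0) stop("delta_obs must be positive")
  csr <- graph_csr(graph)
  res <- .cpp_run_partitioned(csr$off, csr$nbr, graph$initial_states,
                              partition$part_of, partition$n_parts,
                              beta, gamma, delta, horizon,
                              mode == "ghost", delta_obs,
                              as.numeric(seed), validate)
  traj <- new_trajectory(res, graph,
                         list(engine = "partitioned", mode = mode,
                              n_parts = partition$n_parts, beta = beta,
                              gamma = gamma, delta = delta,
                              horizon = horizon, delta_obs = delta_obs,
                              seed = seed),
                         delta_obs)
  msgs <- structure(
    list(total = res$total_messages,
         channels = data.frame(sender = res$chan_from,
                               receiver = res$chan_to,
                               border_size = res$chan_border_size,
                               messages = res$chan_messages),
         n_epochs = res$n_epochs, mode = mode),
    class = "sis_message_stats")
  list(trajectory = traj, messages = msgs)
}

#' @export
print.sis_message_stats <- function(x, ...) {
  cat(sprintf("<sis_message_stats> %s payloads over %d epochs on %d channels (%s mode)\n",
              format(x$total, big.mark = ","), x$n_epochs,
              nrow(x$channels), x$mode))
  invisible(x)
}

# ---- trajectory IO ---------------------------------------------------------

#' Write a trajectory to CSV/JSON files
#'
#' Writes `events.csv` (t, kind, source, target), `counts.csv`
#' (l, time, count) and `run.json` (parameters plus a hash of the final
#' state vector) under `dir`.
#'
#' @param trajectory An `sis_trajectory`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_trajectory <- function(trajectory, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(trajectory$events))
    utils::write.csv(trajectory$events, file.path(dir, "events.csv"),
                     row.names = FALSE)
  utils::write.csv(trajectory$counts, file.path(dir, "counts.csv"),
                   row.names = FALSE)
  meta <- trajectory$params
  meta$final_infected <- sum(trajectory$final_states)
  meta$final_state_hash <- sum(which(trajectory$final_states == 1L) %% 1e9)
  jsonlite::write_json(meta, file.path(dir, "run.json"), auto_unbox = TRUE)
  invisible(dir)
}
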