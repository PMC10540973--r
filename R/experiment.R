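# Replication harness: repeated runs, trajectory averaging, divergence
# from the M = 1 baseline, and (M, Delta) experiment grids.

#' Average infection-count trajectories over repetitions
#'
#' @param runs A list of `sis_trajectory` objects (or plain numeric
#'   count vectors) sharing one observation grid.
#' @return An `sis_avg_trajectory`: list with `l`, `time`, `mean`
#'   (exact arithmetic mean per grid point), `per_run` (R x L+1
#'   matrix) and `R`.
#' @export
average_infection_counts <- function(runs) {
  if (length(runs) == 0) stop("no runs supplied")
  counts <- lapply(runs, function(r) {
    if (inherits(r, "sis_trajectory")) r$counts$count else as.numeric(r)
  })
  L <- unique(vapply(counts, length, 0L))
  if (length(L) != 1) stop("runs do not share an observation grid")
  tim <- if (inherits(runs[[1]], "sis_trajectory")) runs[[1]]$counts$time
         else seq_len(L) - 1
  per_run <- do.call(rbind, counts)
  structure(list(l = seq_len(L) - 1L, time = tim,
                 mean = colMeans(per_run), per_run = per_run,
                 R = length(runs)),
            class = "sis_avg_trajectory")
}

#' @export
print.sis_avg_trajectory <- function(x, ...) {
  cat(sprintf("<sis_avg_trajectory> R = %d runs, %d grid points, final mean %.1f\n",
              x$R, length(x$mean), x$mean[length(x$mean)]))
  invisible(x)
}

#' Relative divergence from a baseline trajectory
#'
#' Per grid point, `(Cbar_l - Cbar_l^base) / Cbar_l^base`. Grid points
#' are matched by time, so a baseline sampled on a finer grid can serve
#' several cell grids. Points with a zero baseline are flagged and
#' excluded with a warning. The equilibrium (type-2) divergence is the
#' mean of the series over the final `equilibrium_frac` of grid points;
#' the lag (type-1) divergence is the maximum absolute value over the
#' preceding growth phase.
#'
#' @param traj An `sis_avg_trajectory`.
#' @param baseline An `sis_avg_trajectory` whose grid contains `traj`'s
#'   grid times.
#' @param equilibrium_frac Fraction of trailing grid points forming the
#'   equilibrium window (default 0.1).
#' @return A list with `series` (data.frame `time`, `divergence`,
#'   `defined`), `type2` (signed equilibrium divergence) and `type1`
#'   (growth-phase max absolute divergence).
#' @export
relative_divergence <- function(traj, baseline, equilibrium_frac = 0.1) {
  idx <- match(round(traj$time, 9), round(baseline$time, 9))
  if (anyNA(idx))
    stop("baseline grid does not contain the trajectory's grid times")
  base <- baseline$mean[idx]
  defined <- base > 0
  if (!all(defined))
    warning(sprintf("%d grid point(s) with zero baseline excluded",
                    sum(!defined)))
  div <- rep(NA_real_, length(base))
  div[defined] <- (traj$mean[defined] - base[defined]) / base[defined]
  L <- length(div)
  n_eq <- max(1L, ceiling(equilibrium_frac * L))
  eq_idx <- (L - n_eq + 1L):L
  growth_idx <- setdiff(seq_len(L), eq_idx)
  list(series = data.frame(time = traj$time, divergence = div,
                           defined = defined),
       type2 = mean(div[eq_idx], na.rm = TRUE),
       type1 = if (length(growth_idx) && any(!is.na(div[growth_idx])))
                 max(abs(div[growth_idx]), na.rm = TRUE) else NA_real_)
}

#' Experiment configuration
#'
#' Bundles a prepared graph (with initial states already set) and the
#' (M, Delta) grid of a replication experiment. Repetition `r` of any
#' cell uses engine seed `master_seed + r`, and the partition for `M`
#' parts uses seed `master_seed + 104729 + M`, so cells with equal `M`
#' share a partition and all modes see matched randomness.
#'
#' @param graph An `sis_graph` with initial infected states set.
#' @param m_grid Integer vector of part counts (include 1 for the
#'   baseline).
#' @param delta_grid Numeric vector of epoch lengths.
#' @param beta,gamma Rates.
#' @param horizon Simulation horizon H.
#' @param reps Repetitions R per cell.
#' @param mode `"summary"` or `"ghost"`.
#' @param master_seed Master integer seed.
#' @param partition_method Passed to [partition_uniform()].
#' @export
experiment_config <- function(graph, m_grid, delta_grid, beta, gamma,
                              horizon, reps, mode = c("summary", "ghost"),
                              master_seed = 1L,
                              partition_method = "even") {
  mode <- match.arg(mode)
  stopifnot(inherits(graph, "sis_graph"), reps >= 1)
  structure(list(graph = graph, m_grid = as.integer(m_grid),
                 delta_grid = delta_grid, beta = beta, gamma = gamma,
                 horizon = horizon, reps = as.integer(reps), mode = mode,
                 master_seed = as.integer(master_seed),
                 partition_method = partition_method),
            class = "sis_experiment_config")
}

#' The Erdos-Renyi replication profile
#'
#' The standard configuration of the package's replication study: a
#' G(N, p) graph of mean degree 10 with 1% of vertices initially
#' infected, `gamma = 0.25`, `beta = 0.05`, `H = 60`. The default
#' scaled profile uses N = 20000, p = 5e-4 and R = 5 repetitions so the
#' full grid runs in minutes on one core; `scaled = FALSE` gives the
#' full N = 100000, p = 1e-4, R = 20 setting.
#'
#' @param master_seed Master integer seed (also seeds the graph, offset
#'   +0, and the infected set, offset +7919).
#' @param scaled Use the desk-scale profile (default) or the full one.
#' @param m_grid,delta_grid,reps,mode Overrides of the grid.
#' @return An `sis_experiment_config`.
#' @export
er_experiment_profile <- function(master_seed = 1L, scaled = TRUE,
                                  m_grid = c(1L, 2L, 4L, 8L),
                                  delta_grid = c(0.1, 1.0),
                                  reps = if (scaled) 5L else 20L,
                                  mode = "summary") {
  n <- if (scaled) 20000L else 100000L
  p <- if (scaled) 5e-4 else 1e-4
  g <- generate_erdos_renyi(n, p, seed = master_seed)
  g <- infect_random(g, 0.01, seed = master_seed + 7919L)
  experiment_config(g, m_grid = m_grid, delta_grid = delta_grid,
                    beta = 0.05, gamma = 0.25, horizon = 60,
                    reps = reps, mode = mode, master_seed = master_seed)
}

#' Run an (M, Delta) experiment grid
#'
#' For every cell, runs `reps` repetitions (`M = 1` cells through the
#' sequential engine, `M > 1` through the partitioned engine in the
#' configured mode), averages the infection counts, and computes the
#' divergence of each `M > 1` cell from the `M = 1` baseline at the
#' same `Delta`. Infeasible cells are recorded with their error and do
#' not abort the grid.
#'
#' @param config An `sis_experiment_config`.
#' @return An `sis_experiment` list: `config`, `cells` (one entry per
#'   grid cell with `m`, `delta`, `avg`, `messages`, `divergence` or
#'   `error`).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "sis_experiment_config"))
  g <- config$graph
  cells <- list()
  baselines <- list()
  for (delta in config$delta_grid) {
    runs <- lapply(seq_len(config$reps), function(r) {
      run_sequential(g, config$beta, config$gamma, config$horizon,
                     delta_obs = delta, seed = config$master_seed + r)
    })
    baselines[[as.character(delta)]] <- average_infection_counts(runs)
  }
  for (m in config$m_grid) {
    partition <- if (m > 1)
      partition_uniform(g, m, seed = config$master_seed + 104729L + m,
                        method = config$partition_method)
    for (delta in config$delta_grid) {
      key <- as.character(delta)
      cell <- tryCatch({
        if (m == 1) {
          list(m = m, delta = delta, avg = baselines[[key]],
               messages = NULL,
               divergence = relative_divergence(baselines[[key]],
                                                baselines[[key]]))
        } else {
          runs <- vector("list", config$reps)
          msg_total <- 0
          for (r in seq_len(config$reps)) {
            out <- run_partitioned(g, partition, config$beta, config$gamma,
                                   delta, config$horizon,
                                   mode = config$mode,
                                   seed = config$master_seed + r,
                                   delta_obs = delta)
            runs[[r]] <- out$trajectory
            msg_total <- msg_total + out$messages$total
          }
          avg <- average_infection_counts(runs)
          list(m = m, delta = delta, avg = avg,
               messages = msg_total / config$reps,
               divergence = relative_divergence(avg, baselines[[key]]))
        }
      }, error = function(e) list(m = m, delta = delta,
                                  error = conditionMessage(e)))
      cells[[length(cells) + 1L]] <- cell
    }
  }
  structure(list(config = config, cells = cells), class = "sis_experiment")
}

#' @export
print.sis_experiment <- function(x, ...) {
  cat(sprintf("<sis_experiment> %d cells (%s mode)\n", length(x$cells),
              x$config$mode))
  for (cell in x$cells) {
    if (!is.null(cell$error)) {
      cat(sprintf("  M = %d, delta = %.3g: ERROR %s\n", cell$m, cell$delta,
                  cell$error))
    } else {
      cat(sprintf("  M = %d, delta = %.3g: equilibrium divergence %+.3f%%\n",
                  cell$m, cell$delta, 100 * cell$divergence$type2))
    }
  }
  invisible(x)
}

#' Equilibrium divergence summary of an experiment
#'
#' @param experiment An `sis_experiment`.
#' @return data.frame with one row per successful `M > 1` cell:
#'   `m`, `delta`, `type1`, `type2`, `messages`.
#' @export
divergence_summary <- function(experiment) {
  rows <- lapply(experiment$cells, function(cell) {
    if (!is.null(cell$error) || cell$m == 1) return(NULL)
    data.frame(m = cell$m, delta = cell$delta,
               type1 = cell$divergence$type1,
               type2 = cell$divergence$type2,
               messages = cell$messages)
  })
  do.call(rbind, rows)
}
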