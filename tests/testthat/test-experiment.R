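test_that("trajectory averaging is the exact arithmetic mean", {
  r1 <- c(0, 5, 10, 10)
  avg1 <- average_infection_counts(list(r1))
  expect_equal(avg1$mean, r1)  # R = 1 identity
  avg2 <- average_infection_counts(list(c(0, 0, 0, 10), c(0, 0, 0, 20)))
  expect_equal(avg2$mean[4], 15)
  avg3 <- average_infection_counts(rep(list(c(4, 4, 4)), 20))
  expect_equal(avg3$mean, c(4, 4, 4))  # idempotent on constants
  expect_equal(avg3$R, 20)
  expect_error(average_infection_counts(list(1:3, 1:4)), "grid")
})

test_that("relative divergence matches hand arithmetic", {
  mk <- function(x) structure(list(l = seq_along(x) - 1L,
                                   time = seq_along(x) - 1,
                                   mean = x, per_run = rbind(x), R = 1L),
                              class = "sis_avg_trajectory")
  base <- mk(rep(1000, 10))
  expect_equal(relative_divergence(mk(rep(1000, 10)), base)$series$divergence,
               rep(0, 10))
  d <- relative_divergence(mk(rep(950, 10)), base)
  expect_equal(d$series$divergence, rep(-0.05, 10))
  expect_equal(d$type2, -0.05)

  d2 <- relative_divergence(mk(c(100, 110)), mk(c(100, 100)))
  expect_equal(d2$series$divergence, c(0, 0.10))

  # zero baseline points are flagged and excluded
  expect_warning(
    d3 <- relative_divergence(mk(c(5, 10)), mk(c(0, 10))), "zero baseline")
  expect_true(is.na(d3$series$divergence[1]))
  expect_false(d3$series$defined[1])
})

test_that("the equilibrium window is the trailing tenth of the grid", {
  mk <- function(x) structure(list(l = seq_along(x) - 1L,
                                   time = seq_along(x) - 1,
                                   mean = x, per_run = rbind(x), R = 1L),
                              class = "sis_avg_trajectory")
  x <- rep(100, 100); x[91:100] <- 120   # +20% only inside the window
  d <- relative_divergence(mk(x), mk(rep(100, 100)))
  expect_equal(d$type2, 0.20)
  expect_equal(d$type1, 0)  # growth phase untouched
})

test_that("divergence can be evaluated on a finer baseline grid", {
  mk <- function(x, t) structure(list(l = seq_along(x) - 1L, time = t,
                                      mean = x, per_run = rbind(x), R = 1L),
                                 class = "sis_avg_trajectory")
  base <- mk(101:121, seq(0, 2, by = 0.1))
  traj <- mk(c(110, 121), c(0, 2))  # multiples of 1.0 inside the 0.1 grid
  d <- relative_divergence(traj, base)
  expect_equal(d$series$divergence, c(110 / 101 - 1, 0))
  expect_error(relative_divergence(mk(1:2, c(0, 0.35)), base), "grid times")
})

test_that("experiment grids run, summarize, and reproduce bit-identically", {
  g <- infect_random(generate_erdos_renyi(400, 0.02, seed = 1), 0.05,
                     seed = 2)
  cfg <- experiment_config(g, m_grid = c(1L, 2L), delta_grid = c(0.5, 1),
                           beta = 0.08, gamma = 0.25, horizon = 10,
                           reps = 3, mode = "summary", master_seed = 11)
  ex1 <- run_experiment(cfg)
  expect_length(ex1$cells, 4)
  m1 <- ex1$cells[[1]]
  expect_equal(m1$m, 1)
  expect_equal(m1$divergence$series$divergence,
               rep(0, nrow(m1$divergence$series)))  # baseline vs itself
  s <- divergence_summary(ex1)
  expect_equal(nrow(s), 2)  # only the M = 2 cells
  expect_true(all(is.finite(s$type2)))
  expect_true(all(s$messages > 0))

  ex2 <- run_experiment(cfg)
  expect_identical(divergence_summary(ex2), s)
})

test_that("block-diagonal SBM grids exchange no messages in any cell", {
  g <- infect_random(generate_sbm(4, 60, 0.15, 0, seed = 3), 0.3, seed = 4)
  cfg <- experiment_config(g, m_grid = c(1L, 4L), delta_grid = 1,
                           beta = 0.05, gamma = 0.25, horizon = 5, reps = 2,
                           master_seed = 5)
  # align the experiment's uniform partition with the blocks via the
  # partitioned runner directly
  p <- partition_blocks(g, 4)
  out <- run_partitioned(g, p, 0.05, 0.25, 1, 5, seed = 6)
  expect_equal(out$messages$total, 0)
})

test_that("the scaled replication profile carries the study conditions", {
  cfg <- er_experiment_profile(master_seed = 3, scaled = TRUE,
                               m_grid = c(1L, 8L), delta_grid = 1, reps = 2)
  expect_equal(cfg$graph$n_vertices, 20000L)
  expect_equal(sum(cfg$graph$initial_states), 200)  # 1% infected
  expect_equal(cfg$beta, 0.05)
  expect_equal(cfg$gamma, 0.25)
  expect_equal(cfg$horizon, 60)
  expect_lt(abs(mean(graph_degrees(cfg$graph)) - 10), 0.5)
})

test_that("summary mode overestimates growth at small delta, underestimates at large", {
  cfg <- er_experiment_profile(master_seed = 1, scaled = TRUE,
                               m_grid = c(1L, 8L), delta_grid = c(0.1, 1.0),
                               reps = 10, mode = "summary")
  ex <- run_experiment(cfg)
  growth_sign <- vapply(ex$cells, function(cell) {
    if (cell$m == 1) return(NA_real_)
    ser <- cell$divergence$series
    grow <- ser$time > 5 & ser$time < 30
    mean(ser$divergence[grow], na.rm = TRUE)
  }, 0)
  deltas <- vapply(ex$cells, `[[`, 0, "delta")
  m8 <- vapply(ex$cells, function(cell) cell$m == 8, TRUE)
  expect_gt(growth_sign[m8 & deltas == 0.1], 0)  # mean-field border inflates
  expect_lt(growth_sign[m8 & deltas == 1.0], 0)  # stale borders lag
})

test_that("ghost mode shrinks the equilibrium divergence of summary mode", {
  run_mode <- function(mode) {
    cfg <- er_experiment_profile(master_seed = 1, scaled = TRUE,
                                 m_grid = c(1L, 8L), delta_grid = 1.0,
                                 reps = 5, mode = mode)
    abs(divergence_summary(run_experiment(cfg))$type2)
  }
  expect_lt(run_mode("ghost"), run_mode("summary"))
})
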