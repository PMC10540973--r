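test_that("partitioned run with M = 1 reduces exactly to sequential", {
  g <- infect_random(generate_erdos_renyi(400, 0.03, seed = 1), 0.05,
                     seed = 2)
  seq_tr <- run_sequential(g, 0.06, 0.25, horizon = 25, delta_obs = 1,
                           seed = 9)
  out <- run_partitioned(g, partition_uniform(g, 1, seed = 3), 0.06, 0.25,
                         delta = 0.5, horizon = 25, mode = "summary",
                         seed = 9, delta_obs = 1)
  expect_identical(out$trajectory$events, seq_tr$events)
  expect_identical(out$trajectory$counts, seq_tr$counts)
  expect_equal(out$messages$total, 0)
})

test_that("disconnected process graph exchanges no messages", {
  g <- infect_random(generate_sbm(4, 50, 0.2, 0, seed = 2), 0.2, seed = 3)
  out <- run_partitioned(g, partition_blocks(g, 4), 0.1, 0.25, delta = 1,
                         horizon = 20, seed = 5)
  expect_equal(out$messages$total, 0)
  expect_equal(nrow(out$messages$channels), 0)
  expect_gt(nrow(out$trajectory$events), 0)
})

test_that("summary-mode message count meets the per-epoch channel law", {
  # dense ER: uniform 8-way split makes the process graph complete
  g <- infect_random(generate_erdos_renyi(400, 0.05, seed = 4), 0.05,
                     seed = 5)
  p <- partition_uniform(g, 8, seed = 6)
  bt <- build_border_table(g, p)
  expect_equal(nrow(bt$channels), 8 * 7)  # complete process graph
  out <- run_partitioned(g, p, 0.05, 0.25, delta = 1, horizon = 60,
                         mode = "summary", seed = 7)
  expect_equal(out$messages$total, message_bound(60, 1, 8))
  expect_equal(out$messages$total, 3360)
  # one payload per channel per epoch
  expect_true(all(out$messages$channels$messages == out$messages$n_epochs))
  expect_equal(sum(out$messages$channels$messages), out$messages$total)

  # sparser process graphs stay below the bound
  g2 <- infect_random(generate_erdos_renyi(300, 0.01, seed = 8), 0.05,
                      seed = 9)
  p2 <- partition_uniform(g2, 8, seed = 10)
  out2 <- run_partitioned(g2, p2, 0.05, 0.25, delta = 0.7, horizon = 10,
                          seed = 11)
  expect_lte(out2$messages$total, message_bound(10, 0.7, 8))
  expect_equal(out2$messages$n_epochs, ceiling(10 / 0.7))
})

test_that("ghost-cell payloads count 64-bit words of the border bitmask", {
  g <- infect_random(generate_erdos_renyi(600, 0.03, seed = 12), 0.05,
                     seed = 13)
  p <- partition_uniform(g, 4, seed = 14)
  bt <- build_border_table(g, p)
  out <- run_partitioned(g, p, 0.05, 0.25, delta = 1, horizon = 10,
                         mode = "ghost", seed = 15)
  # engine border sizes agree with the R border table
  ch <- out$messages$channels
  for (r in seq_len(nrow(ch)))
    expect_equal(ch$border_size[r],
                 border_size(bt, ch$sender[r], ch$receiver[r]))
  words <- sum(ceiling(ch$border_size / 64))
  expect_equal(out$messages$total, 10 * words)
})

test_that("an all-susceptible border drives no remote infections", {
  # two cliques joined by a cross edge; all infection confined to part 0
  # by beta = 0, so summaries stay 0 and no remote event can fire
  e <- rbind(t(utils::combn(0:4, 2)), t(utils::combn(5:9, 2)), c(4L, 5L))
  g <- set_infected(sis_graph(10, e), 0:2)
  p <- new_partition_for_test(rep(c(0L, 1L), each = 5))
  out <- run_partitioned(g, p, beta = 0, gamma = 0.5, delta = 0.5,
                         horizon = 50, seed = 21, validate = TRUE)
  expect_true(all(out$trajectory$events$kind == "recovery"))
  expect_gt(out$messages$total, 0)
})

test_that("remote infections arrive through the border mean-field clock", {
  # vertices 0-1 on different parts; 0 infected and immortal (gamma = 0).
  # n_{Q->v} = 1, n/N = 1, so the Inf(Q->v) rate is beta.
  g <- set_infected(path_graph(2), 0L)
  p <- new_partition_for_test(c(0L, 1L))
  out <- run_partitioned(g, p, beta = 2, gamma = 0, delta = 0.5,
                         horizon = 100, seed = 31, validate = TRUE)
  ev <- out$trajectory$events
  expect_equal(nrow(ev), 1)
  expect_equal(as.character(ev$kind), "infection_remote")
  expect_equal(ev$target, 1L)
  expect_equal(ev$source, 0L)  # source logged as the remote part id
  expect_equal(sum(out$trajectory$final_states), 2)
})

test_that("merged event logs are bit-identical across same-seed runs", {
  g <- infect_random(generate_erdos_renyi(300, 0.04, seed = 16), 0.1,
                     seed = 17)
  p <- partition_uniform(g, 4, seed = 18)
  for (mode in c("summary", "ghost")) {
    a <- run_partitioned(g, p, 0.08, 0.25, 0.5, 15, mode = mode, seed = 19)
    b <- run_partitioned(g, p, 0.08, 0.25, 0.5, 15, mode = mode, seed = 19)
    expect_identical(a$trajectory$events, b$trajectory$events)
    expect_equal(a$messages$total, b$messages$total)
  }
})

test_that("shrinking the epoch drives ghost mode toward the M = 1 baseline", {
  g <- infect_random(generate_erdos_renyi(500, 0.016, seed = 22), 0.05,
                     seed = 23)
  p <- partition_uniform(g, 4, seed = 24)
  R <- 30
  eq_mean <- function(run_fn) {
    finals <- vapply(seq_len(R), function(r) {
      tr <- run_fn(400 + r)
      mean(utils::tail(tr$counts$count, 5))
    }, 0)
    c(mean(finals), stats::sd(finals) / sqrt(R))
  }
  base <- eq_mean(function(s)
    run_sequential(g, 0.1, 0.25, horizon = 20, delta_obs = 1, seed = s))
  coarse <- eq_mean(function(s)
    run_partitioned(g, p, 0.1, 0.25, delta = 4, horizon = 20,
                    mode = "ghost", seed = s, delta_obs = 1)$trajectory)
  fine <- eq_mean(function(s)
    run_partitioned(g, p, 0.1, 0.25, delta = 0.25, horizon = 20,
                    mode = "ghost", seed = s, delta_obs = 1)$trajectory)
  err_coarse <- abs(coarse[1] - base[1])
  err_fine <- abs(fine[1] - base[1])
  mc <- 3 * sqrt(base[2]^2 + coarse[2]^2 + fine[2]^2)
  expect_lt(err_fine, err_coarse + mc)
})
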