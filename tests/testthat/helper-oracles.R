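# Independent oracles: a brute-force Gillespie direct-method SIS
# simulator and a jump-chain sampler for the single-vertex two-state
# CTMC. Both use R's RNG and share no code with the package engine.

# Direct method: at each step compute all transition rates from the full
# state, draw the holding time from the summed rate, and pick the event
# proportionally. Returns the first event type, the extinction time (NA
# if still endemic at the horizon) and the final infected count.
gillespie_direct <- function(graph, beta, gamma, horizon) {
  n <- graph$n_vertices
  adj <- graph$adjacency
  state <- graph$initial_states
  t <- 0
  first_type <- NA_character_
  extinction <- NA_real_
  repeat {
    inf <- which(state == 1L)
    if (length(inf) == 0) { extinction <- t; break }
    n_inf_nbr <- vapply(seq_len(n), function(v)
      sum(state[adj[[v]] + 1L]), 0L)
    sus <- which(state == 0L)
    inf_rates <- beta * n_inf_nbr[sus]
    rates <- c(rep(gamma, length(inf)), inf_rates)
    total <- sum(rates)
    if (total == 0) break
    t <- t + stats::rexp(1, total)
    if (t > horizon) break
    k <- sample.int(length(rates), 1, prob = rates)
    if (is.na(first_type))
      first_type <- if (k <= length(inf)) "recovery" else "infection"
    if (k <= length(inf)) state[inf[k]] <- 0L
    else state[sus[k - length(inf)]] <- 1L
  }
  list(first_type = first_type, extinction = extinction,
       final = sum(state))
}

# One-epoch end state of the two-state CTMC with rates
# INF -> SUS at gamma, SUS -> INF at beta_v, by explicit jump simulation.
ctmc_epoch_sample <- function(state0, beta_v, gamma, delta) {
  s <- state0
  t <- 0
  repeat {
    rate <- if (s == 1L) gamma else beta_v
    if (rate == 0) break
    t <- t + stats::rexp(1, rate)
    if (t > delta) break
    s <- 1L - s
  }
  s
}
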