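# sispart

Partitioned event-driven simulation of SIS epidemics on graphs.

`sispart` is for modelers who need stochastic
susceptible–infected–susceptible (SIS) dynamics on large fixed contact
graphs — the regime where exact event-driven simulation is statistically
faithful but stubbornly serial. The package implements an
epoch-synchronized partitioned engine: the vertex set is split into `M`
parts, each part runs its own event-driven simulator, and parts
exchange only a tiny summary of their border state every `Δ` time
units. The result is a tunable trade-off between parallel structure
(message counts bounded by `⌈H/Δ⌉·M(M−1)`) and statistical
faithfulness (divergence from the exact `M = 1` baseline that shrinks
with `Δ`), together with the exact sequential baseline, time-driven
baselines, and the quenched mean-field theory needed to reason about
all of them.

## The model

Each vertex is susceptible or infected. An infected vertex recovers at
rate `γ`; each infected–susceptible edge transmits at rate `β`, so a
susceptible vertex with `n_v` infected neighbors is infected at rate
`n_v β`. All clocks are exponential (a continuous-time Markov chain).

**Sequential engine** (`run_sequential`): next-reaction–style
event-driven simulation — per-edge infection clocks `Inf(u→v)` and
recovery clocks `Rec(v)` race in an indexed priority queue.

**Partitioned engine** (`run_partitioned`): a vertex of part `P` with a
neighbor on part `Q` *borders* `Q`; `B_{P→Q}` is the set of such
vertices and `N_{P→Q}` its size. Once per epoch each process sends, per
neighboring process, either

* the **summary** `n_{P→Q}` = number of infected vertices in `B_{P→Q}`
  (one 64-bit integer per channel) — the receiver gives each
  susceptible border vertex `v` a remote-infection clock `Inf(Q→v)` of
  mean-field rate `n_{Q→v} · (n_{Q→P}/N_{Q→P}) · β`, or
* the full border state as a bitmask (**ghost-cell mode**,
  `⌈N/64⌉` words per channel) — the remote rate is then `β` times the
  snapshot-infected neighbor count.

Local events keep their absolute times across epochs; only remote
clocks are re-drawn when a genuinely new value arrives. With `M = 1`
the engine reduces bit-identically to the sequential baseline.

**Theory** (`epidemic_threshold`, `solve_fixed_point`,
`integrate_master`, `discrete_map_step`): quenched mean-field master
equation `dP_v/dt = β(1−P_v)ΣA_uv P_u − γP_v`, its epoch-limit discrete
map `P_v ← r_v/(γ+r_v)`, the shared fixed points, and the spectral
epidemic threshold `β* = γ/λ₁(A)`.

**Time-driven baselines** (`run_tds_rejection`, `run_tds_exact`):
synchronous per-epoch updates with rejection-sampling probabilities
`1−e^{−γΔ}` / `1−e^{−n_vβΔ}`, or with the exact two-state transition
matrix `epoch_transition_exact` they linearize.

## A worked example

```r
library(sispart)

g <- generate_erdos_renyi(2000, 5e-3, seed = 42)   # mean degree ~ 10
g <- infect_random(g, 0.01, seed = 7)              # 1% initially infected

base <- run_sequential(g, beta = 0.05, gamma = 0.25, horizon = 30,
                       delta_obs = 1, seed = 3)
base
#> <sis_trajectory> 7,324 events, 31 sample points, final infected 896

p4  <- partition_uniform(g, 4, seed = 5)
out <- run_partitioned(g, p4, beta = 0.05, gamma = 0.25, delta = 0.5,
                       horizon = 30, mode = "summary", seed = 3,
                       delta_obs = 1)
out$messages
#> <sis_message_stats> 720 payloads over 60 epochs on 12 channels (summary mode)

d <- relative_divergence(average_infection_counts(list(out$trajectory)),
                         average_infection_counts(list(base)))
round(d$type2, 4)
#> [1] 0.0175

epidemic_threshold(g, gamma = 0.25)$beta_star
#> [1] 0.02249903
```

Read: the epidemic grows from 20 seeds to an endemic plateau near 900
infected (the mean-field fixed point predicts prevalence ≈ 0.50 here,
and `β = 0.05` sits at about twice the spectral threshold 0.022). The
4-part summary-mode run exchanged exactly one payload per channel per
epoch — `60 × 12 = 720`, the theoretical count for its complete process
graph — and its equilibrium infection count sits within ~1.7% of the
exact baseline for this single pair of runs.

A thin CLI over the same functions is provided in `exec/sispart`
(`generate`, `partition`, `infect`, `simulate`, `analyze`) for
file-based workflows with SNAP-style edge lists and standard
partitioner output files.

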