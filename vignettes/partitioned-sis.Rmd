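---
title: "Epoch-partitioned event-driven simulation of SIS epidemics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epoch-partitioned event-driven simulation of SIS epidemics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The model and the problem

`sispart` simulates Markovian susceptible–infected–susceptible (SIS)
epidemics on a fixed undirected graph $G = (V, E)$. Every vertex is
either susceptible (SUS) or infected (INF). An infected vertex recovers
at rate $\gamma$; each edge between an infected and a susceptible vertex
transmits at rate $\beta$, so a susceptible vertex with $n_v$ infected
neighbors is infected at total rate $n_v \beta$. All waiting times are
exponential, so the joint state is a continuous-time Markov chain.

The exact reference algorithm is event-driven simulation (EDS) in the
next-reaction style: every possible transition owns an exponential
clock, the clocks race in an indexed priority queue, and the simulation
hops from the earliest event to the next. EDS is statistically faithful
but inherently serial — events must be consumed in time order.

The package's core is a *partitioned* engine that trades a controlled
amount of statistical faithfulness for parallel structure. The vertex
set is split into $M$ non-empty parts, each conceptually owned by one
process with private memory. Processes advance in synchronized *epochs*
of length $\Delta$ and exchange information only at epoch boundaries,
through channels that carry one 64-bit payload at a time. Within an
epoch each process runs ordinary EDS on its own vertices.

## Border summaries and the ghost-cell variant

A vertex of part $P$ with at least one neighbor on part $Q$ *borders*
$Q$. Writing $B_{P \to Q}$ for the set of such vertices and
$N_{P \to Q} = |B_{P \to Q}|$ (computed once, the graph being fixed),
the engine supports two payloads per channel and epoch:

* **summary mode** — the single integer
  $n_{P \to Q} = |\{v \in B_{P \to Q} : v \text{ infected}\}|$.
  The receiver treats every border neighbor as infected independently
  with probability $n_{Q \to P} / N_{Q \to P}$ — a mean-field
  approximation on the border. A susceptible border vertex $v$ carries
  one aggregate remote-infection clock per bordered part $Q$ with rate
  $$ n_{Q \to v} \cdot \frac{n_{Q \to P}}{N_{Q \to P}} \cdot \beta, $$
  where $n_{Q \to v}$ counts $v$'s neighbors on $Q$.
* **ghost mode** — the full border state, packed as a bitmask of
  $B_{Q \to P}$ in list order into $\lceil N_{Q \to P}/64 \rceil$
  64-bit words. The remote clock rate is then exactly $\beta$ times the
  number of *snapshot-infected* neighbors, removing the mean-field
  averaging but not the staleness.

Only these remote clocks are touched at epoch boundaries; local events
(recoveries, local infections) keep their absolute scheduled times.
Re-draws follow the received value: a clock whose rate is unchanged is
left in place, which is distributionally neutral because the residual
of an exponential clock is exponential at the same rate. Rate changes
trigger a fresh draw at the new rate rather than the classical
next-reaction time-rescaling, matching the update rule the algorithm
prescribes. A border vertex that recovers mid-epoch immediately regains
remote clocks at the current epoch's rates — the epoch snapshot is the
best information available until the next exchange.

The loop runs $\lceil H/\Delta \rceil$ times for horizon $H$, with an
exchange at $t = 0$ so the first epoch sees the initial border states.
Summary payloads are sent every epoch on every channel, so the total
message count is exactly $\lceil H/\Delta \rceil \cdot |\mathcal{E}|$
for process-graph edge set $\mathcal{E}$, and at most
$\lceil H/\Delta \rceil M (M - 1)$ — with equality exactly when the
process graph is complete. `message_bound()` exposes the bound and
every run reports its observed count.

With $M = 1$ there are no channels and the engine *is* sequential EDS:
`run_partitioned()` with one part produces a bit-identical event log to
`run_sequential()` at the same seed (this is asserted in the tests).

## The emulation backend

The package executes all $M$ processes inside one R process. Because
processes interact only at epoch boundaries — remote information is
frozen into per-pair rates when messages are applied — the within-epoch
interleaving of different parts is immaterial. The backend exploits
this: all live events sit in a single indexed binary heap and are
processed in global time order, while every draw for a vertex of part
$P$ consumes part $P$'s private random stream. The observable behavior
(per-process event sequences, draws, and the merged log) is identical
to genuinely independent per-process queues, and the merged, time-sorted
trajectory comes out for free. Message and channel accounting follows
the capacity-one channel contract: one payload per channel per epoch
(ghost mode: one per 64-bit word). A true message-passing backend would
behave identically at the trajectory level; none is bundled, as every
analysis in the package runs on the emulation backend.

Determinism: each part's stream is a `mt19937_64` generator seeded by a
splitmix64 hash of (seed, part id), and exponentials are inverse-CDF
transforms, so merged logs are bitwise reproducible across platforms.
Equal scheduled times (a measure-zero event under continuous draws) are
broken by the engine's integer event key — recoveries before local
infections before remote infections, then by a fixed source/target
encoding — so even degenerate ties resolve deterministically.

## Time-driven baselines

`run_tds_rejection()` is the practitioners' scheme: per epoch, an
infected vertex recovers with probability $1 - e^{-\gamma\Delta}$ and a
susceptible vertex with $n_v$ infected neighbors (counted at the epoch
start) is infected with probability $1 - e^{-n_v\beta\Delta}$, all
flips applied synchronously. A vertex flips at most once per epoch, so
re-infection chains within an epoch are impossible.

`run_tds_exact()` replaces the flip probabilities with the exact
two-state transition matrix over the epoch,
`epoch_transition_exact(beta_v, gamma, delta)` $= e^{\Delta Q_v}$ with
$$ Q_v = \begin{pmatrix} -\gamma & \gamma \\ \beta_v & -\beta_v
\end{pmatrix}, \qquad \beta_v = \beta \cdot n_v, $$
states ordered (INF, SUS). Rejection sampling is the linearization of
this matrix: the per-epoch flip probabilities of the two schemes differ
by $O(\Delta^2)$, which the tests check numerically. The exact variant
is the dynamics the partitioned engine degenerates to when every vertex
is its own process, and `rate_fn` lets callers drive it with externally
supplied mean-field rates to study that regime directly.

## Mean-field theory

Under the one-vertex quenched mean-field closure (each vertex
independent of its neighborhood), the infection probabilities
$P_v(t)$ obey the master equation
$$ \frac{\partial P_v}{\partial t}
   = \beta (1 - P_v) \sum_u A_{uv} P_u - \gamma P_v, $$
integrated by `integrate_master()` (classical RK4, fixed step — the
order-4 convergence is verified by a Richardson test, and equilibria
are exact fixed points of the RK4 map because the right-hand side
vanishes there). In the opposite extreme — every vertex its own
process and $\Delta \to \infty$ — each vertex relaxes to the
stationary distribution of its within-epoch chain and forgets its
starting state, giving the discrete map
$$ P_v' = \frac{r_v}{\gamma + r_v}, \qquad
   r_v = \beta \sum_u A_{uv} P_u $$
(`discrete_map_step()`). Both systems share their fixed points
$\pi_v = r_v(\pi) / (\gamma + r_v(\pi))$, and both lose stability of
the disease-free state at the spectral threshold
$\beta^* = \gamma / \lambda_1(A)$ (`epidemic_threshold()`).

Numerical choices worth recording:

* $\lambda_1$ is computed by power iteration on $A + I$ from the
  all-ones vector (tolerance $10^{-10}$). The shift matters: bipartite
  graphs have symmetric spectra ($\pm\lambda_1$), on which unshifted
  power iteration oscillates indefinitely.
* `solve_fixed_point()` iterates the map from $p = 1$. The map is
  monotone and $p = 1$ dominates every fixed point, so the iteration
  decreases monotonically to the *largest* fixed point — the endemic
  equilibrium when it exists, else $0$. Starting from small $p$ would
  risk converging to $0$ in the supercritical regime.
* `engine_load_bounds()` evaluates the closed-form mean-field ceilings
  on a process's expected queue size,
  $N^* = |V| (\langle D\rangle + M^2)^2 / (4\langle D\rangle M^2)$, and
  total event rate,
  $\Lambda^* = |V| (\beta\langle D\rangle + \gamma)^2 /
  (4\beta\langle D\rangle M)$. They are diagnostics — loose upper
  bounds under idealized uniform i.i.d. partitioning — not assertions.

## The replication harness and its study conditions

`run_experiment()` executes an $(M, \Delta)$ grid with $R$ repetitions
per cell, averages infection counts $\bar C_l$ at multiples of
$\Delta$, and reports each cell's relative divergence
$(\bar C_l - \bar C_l^{M=1}) / \bar C_l^{M=1}$ from the sequential
baseline. Two scalar summaries are derived: the *equilibrium* (type-2)
divergence, the mean of the series over the final 10% of grid points,
and the *lag* (type-1) divergence, the maximum absolute value over the
preceding growth phase. The 10% window is a package choice — the long
quasi-stationary tail of a supercritical run — and is configurable via
`equilibrium_frac`.

Seed policy: repetition $r$ of any cell uses engine seed
`master_seed + r`; the graph, the infected set and the per-$M$
partitions use fixed documented offsets of the master seed. Identical
configurations therefore reproduce bit-identical result bundles, and
summary/ghost comparisons see matched randomness.

`er_experiment_profile()` pins the standard study conditions: a
$G(N, p)$ graph of mean degree 10, 1% of vertices infected uniformly at
random, $\gamma = 0.25$, $\beta = 0.05$ (about twice the mean-field
threshold, so the epidemic settles near 50% prevalence), $H = 60$,
$M \in \{1, 2, 4, 8\}$ with even shuffled partitions. The full profile
is $N = 100000$, $p = 10^{-4}$, $R = 20$; the default scaled profile
preserves the mean degree at $N = 20000$, $p = 5 \times 10^{-4}$ with
$R = 5$ so a grid finishes in minutes on one core.

Problem sizes in the shipped checks reflect measurement precision, not
preference: the summary-mode equilibrium bound (5%) is evaluated on the
scaled profile, where the Monte-Carlo standard error of a cell's
equilibrium divergence is about 0.5 percentage points — an order below
the bound. The ghost-cell bound (1%) is evaluated on the full
$N = 100000$ graph with $R = 5$, because at the scaled size that same
0.5-point noise floor is of the bound's own order and a single noisy
cell can cross the line in either direction; at full size the error is
roughly 0.2 points and the measurement is meaningful.

## What the generator emulates — and what it does not

The synthetic inputs are Erdős–Rényi graphs and stochastic block
models; `sbm_within_prob()` converts a target mean degree and
cross-block probability into the within-block probability via
$\langle D \rangle = p_i(n - 1) + p_o(N - n)$. These graphs have
near-Poisson, uncorrelated degrees and (for ER) no community
structure. Real contact and collaboration networks have heavy-tailed
degrees, degree correlations and strong communities; on such graphs a
uniform partition inflates borders and the summary approximation
degrades, while a structure-aware partitioner (the package reads the
standard one-part-per-line partition files) shrinks borders and
improves both faithfulness and message economy. Passing tests on the
synthetic profiles therefore validate the engine's mechanics and its
scaling claims, not the quality of any particular partitioning scheme
on irregular graphs.

## Degenerate inputs and edge semantics

Zero-rate clocks are never queued (no infinite sentinels), so
$\gamma = 0$ means recoveries never fire and $\beta = 0$ yields exactly
one recovery per initially infected vertex. The all-susceptible state
is absorbing in every engine. The last epoch truncates at $H$ when
$H/\Delta$ is not an integer; no event time exceeds $H$. Observation
grids use integer multiples of `delta_obs` computed by index, so a
trajectory always has $\lfloor H/\delta_{obs}\rfloor + 1$ sample
points regardless of floating-point drift. The edge-list reader
deduplicates, symmetrizes and drops self-loops (reporting counts)
rather than failing on the minor inconsistencies common in public
edge-list files.

## Known limitations

* Exponential waiting times and homogeneous rates only; no
  heterogeneous, non-Markovian or higher-order infection mechanisms.
* The graph is fixed for the duration of a run.
* One in-process emulation backend; no MPI bindings are bundled, and
  wall-clock scalability is outside the package's measured claims —
  message counts are the communication metric.
* Multilevel graph partitioning is delegated to external tools via
  partition files; only uniform and block partitions are built in.

## A worked example

```{r, eval = FALSE}
library(sispart)

g <- generate_erdos_renyi(2000, 5e-3, seed = 42)   # mean degree ~10
g <- infect_random(g, 0.01, seed = 7)

base <- run_sequential(g, beta = 0.05, gamma = 0.25, horizon = 30,
                       delta_obs = 1, seed = 3)
p4 <- partition_uniform(g, 4, seed = 5)
out <- run_partitioned(g, p4, beta = 0.05, gamma = 0.25, delta = 0.5,
                       horizon = 30, mode = "summary", seed = 3,
                       delta_obs = 1)

out$messages                 # 720 payloads = 60 epochs x 12 channels
avg_b <- average_infection_counts(list(base))
avg_p <- average_infection_counts(list(out$trajectory))
relative_divergence(avg_p, avg_b)$type2

epidemic_threshold(g, gamma = 0.25)$beta_star
```
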