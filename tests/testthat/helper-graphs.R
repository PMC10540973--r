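# Small graph fixtures built in code.

complete_graph <- function(n, infected = integer(0)) {
  e <- t(utils::combn(n, 2)) - 1L
  set_infected(sis_graph(n, e), infected)
}

path_graph <- function(n, infected = integer(0)) {
  e <- cbind(0:(n - 2L), 1:(n - 1L))
  set_infected(sis_graph(n, e), infected)
}

star_graph <- function(n_leaves, infected = integer(0)) {
  e <- cbind(0L, seq_len(n_leaves))
  set_infected(sis_graph(n_leaves + 1L, e), infected)
}

# complete bipartite K_{2,2}: parts {0,1} and {2,3}
k22_graph <- function(infected = integer(0)) {
  e <- cbind(rep(c(0L, 1L), each = 2), rep(c(2L, 3L), 2))
  set_infected(sis_graph(4, e), infected)
}

# n isolated vertices (no edges)
empty_graph <- function(n, infected = integer(0)) {
  set_infected(sis_graph(n), infected)
}

# arbitrary hand-specified partition
new_partition_for_test <- function(part_of) {
  sispart:::new_partition(part_of, max(part_of) + 1L)
}
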