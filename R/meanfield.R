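# Quenched mean-field companion: master equation, epoch-limit discrete
# map, spectral epidemic threshold, fixed points, and the load-bound
# formulas used as run-time diagnostics.

#' Right-hand side of the quenched mean-field master equation
#'
#' `dP_v/dt = beta * (1 - P_v) * sum_u A_uv P_u - gamma * P_v`, the
#' one-vertex mean-field closure of the exact SIS master equation.
#'
#' @param p Probability vector over vertices (entries in \[0, 1\]).
#' @param graph An `sis_graph`.
#' @param beta,gamma Infection and recovery rates.
#' @return Numeric vector of the same length as `p`.
#' @export
master_rhs <- function(p, graph, beta, gamma) {
  if (length(p) != graph$n_vertices)
    stop("length(p) must equal n_vertices")
  A <- graph_adjacency_matrix(graph)
  as.vector(beta * (1 - p) * (A %*% p) - gamma * p)
}

#' Integrate the mean-field master equation
#'
#' Classical 4th-order Runge-Kutta with a fixed step; entries are
#' clamped to \[0, 1\] (the equation keeps them there up to roundoff).
#'
#' @inheritParams master_rhs
#' @param p0 Initial probability vector.
#' @param horizon Integration end time.
#' @param step Fixed step size.
#' @return A list with `times` (the step grid) and `p` (matrix, one row
#'   per time point).
#' @export
integrate_master <- function(graph, p0, beta, gamma, horizon, step) {
  if (step <= 0) stop("step must be positive")
  if (length(p0) != graph$n_vertices)
    stop("length(p0) must equal n_vertices")
  A <- graph_adjacency_matrix(graph)
  rhs <- function(p) as.vector(beta * (1 - p) * (A %*% p) - gamma * p)
  n_steps <- ceiling(horizon / step - 1e-12)
  times <- pmin(step * (0:n_steps), horizon)
  out <- matrix(NA_real_, n_steps + 1L, graph$n_vertices)
  p <- pmin(pmax(p0, 0), 1)
  out[1L, ] <- p
  for (k in seq_len(n_steps)) {
    h <- times[k + 1L] - times[k]
    k1 <- rhs(p)
    k2 <- rhs(p + h / 2 * k1)
    k3 <- rhs(p + h / 2 * k2)
    k4 <- rhs(p + h * k3)
    p <- p + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    p <- pmin(pmax(p, 0), 1)
    out[k + 1L, ] <- p
  }
  list(times = times, p = out)
}

#' One step of the large-epoch discrete mean-field map
#'
#' In the epoch limit where every vertex equilibrates within an epoch
#' and forgets its starting state, the infection probabilities follow
#' `P_v' = r_v / (gamma + r_v)` with `r_v = beta * sum_u A_uv P_u`.
#'
#' @inheritParams master_rhs
#' @export
discrete_map_step <- function(p, graph, beta, gamma) {
  if (length(p) != graph$n_vertices)
    stop("length(p) must equal n_vertices")
  A <- graph_adjacency_matrix(graph)
  r <- as.vector(beta * (A %*% p))
  out <- numeric(length(p))
  nz <- (gamma + r) > 0
  out[nz] <- r[nz] / (gamma + r[nz])
  out
}

#' Spectral epidemic threshold
#'
#' The disease-free state of the quenched mean-field dynamics is
#' locally stable iff `beta < beta* = gamma / lambda1(A)` where
#' `lambda1(A)` is the largest adjacency eigenvalue. `lambda1` is
#' computed by power iteration on the shifted matrix `A + I` from the
#' all-ones vector to tolerance 1e-10; the shift makes the Perron root
#' strictly dominant on bipartite graphs, whose spectrum is symmetric.
#'
#' @param graph An `sis_graph` with at least one edge.
#' @param gamma Recovery rate.
#' @param tol Convergence tolerance on the eigenvalue estimate.
#' @param max_iter Iteration cap.
#' @return A list with `lambda1` and `beta_star = gamma / lambda1`.
#' @export
epidemic_threshold <- function(graph, gamma, tol = 1e-10, max_iter = 100000L) {
  if (graph_n_edges(graph) == 0)
    stop("graph has no edges: the threshold is undefined")
  A <- graph_adjacency_matrix(graph)
  x <- rep(1, graph$n_vertices)
  x <- x / sqrt(sum(x^2))
  lambda <- 0
  for (i in seq_len(max_iter)) {
    y <- as.vector(A %*% x) + x  # power step on A + I
    lambda_new <- sum(x * y) - 1
    ny <- sqrt(sum(y^2))
    if (ny == 0) stop("power iteration degenerated (zero vector)")
    x <- y / ny
    if (abs(lambda_new - lambda) < tol * max(1, abs(lambda_new))) {
      lambda <- lambda_new
      break
    }
    lambda <- lambda_new
  }
  list(lambda1 = lambda, beta_star = gamma / lambda)
}

#' Largest fixed point of the mean-field dynamics
#'
#' Iterates the discrete map `P_v <- r_v / (gamma + r_v)` from the
#' all-infected vector `p = 1`, along which the iteration is
#' monotonically decreasing, until the max-norm change drops below
#' `tol`. The limit solves the stationarity condition of both the
#' master equation and the discrete epoch map (they share fixed
#' points).
#'
#' @inheritParams master_rhs
#' @param tol Max-norm convergence tolerance.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @return The fixed-point probability vector.
#' @export
solve_fixed_point <- function(graph, beta, gamma, tol = 1e-12,
                              max_iter = 1000000L) {
  if (tol <= 0) stop("tol must be positive")
  p <- rep(1, graph$n_vertices)
  A <- graph_adjacency_matrix(graph)
  for (i in seq_len(max_iter)) {
    r <- as.vector(beta * (A %*% p))
    p_new <- ifelse(gamma + r > 0, r / (gamma + r), 0)
    if (max(abs(p_new - p)) < tol) return(p_new)
    p <- p_new
  }
  stop("fixed-point iteration did not converge within max_iter")
}

#' Mean-field load bounds of one process
#'
#' Under uniform i.i.d. partitioning and neighborhood independence, the
#' expected per-process queue size and total event rate are bounded at
#' all times by
#' `N* = |V| (<D> + M^2)^2 / (4 <D> M^2)` and
#' `Lambda* = |V| (beta <D> + gamma)^2 / (4 beta <D> M)`.
#' Used as loose run-time diagnostics of engine load.
#'
#' @param n_vertices Graph size |V|.
#' @param mean_degree Mean degree `<D>` (> 0).
#' @param n_parts Number of parts M.
#' @param beta,gamma Infection and recovery rates (`beta` > 0).
#' @return Named vector with `queue_size` (N*) and `total_rate`
#'   (Lambda*).
#' @export
engine_load_bounds <- function(n_vertices, mean_degree, n_parts, beta,
                               gamma) {
  if (mean_degree <= 0 || beta <= 0)
    stop("mean_degree and beta must be positive")
  M <- n_parts
  c(queue_size = n_vertices * (mean_degree + M^2)^2 / (4 * mean_degree * M^2),
    total_rate = n_vertices * (beta * mean_degree + gamma)^2 /
      (4 * beta * mean_degree * M))
}
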