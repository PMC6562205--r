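# Independent oracles used across the suite. Each reimplements the checked
# quantity from first principles, never through the package's own code path.

# Step-up BH directly from the definition: q_i = min_{j: p_j ranked >= i}
# p_(j) * m / rank_j, computed by explicit enumeration.
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(o == i)
    q[i] <- min(vapply(rank_i:m, function(j) p[o[j]] * m / j, numeric(1)), 1)
  }
  q
}

# Upper hypergeometric tail by explicit combinatorial summation:
# P(overlap >= k) drawing n from a universe of N with K marked.
bf_hyper_tail <- function(k, K, N, n) {
  js <- k:min(K, n)
  js <- js[js >= max(0, n - (N - K))]
  if (length(js) == 0) return(0)
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}

# Fourth-order Runge-Kutta integration of the competing-fates ODE system;
# independent of the closed-form expressions in the package.
rk4_pulse_chase <- function(k_deg, k_sec, k_ret, label0, t_end, dt = 1e-3) {
  deriv <- function(y) {
    c(free = -(k_deg + k_sec + k_ret) * y[["free"]],
      deg = k_deg * y[["free"]],
      sec = k_sec * y[["free"]],
      ret = k_ret * y[["free"]])
  }
  y <- c(free = label0, deg = 0, sec = 0, ret = 0)
  steps <- ceiling(t_end / dt)
  h <- t_end / steps
  for (s in seq_len(steps)) {
    k1 <- deriv(y); k2 <- deriv(y + h / 2 * k1)
    k3 <- deriv(y + h / 2 * k2); k4 <- deriv(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

# Connected components of an edge list via igraph (an implementation
# independent of the package's BFS flood fill).
igraph_components <- function(n_sites, edges) {
  g <- igraph::make_empty_graph(n = n_sites, directed = FALSE)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, rbind(edges$from, edges$to))
  }
  igraph::components(g)$membership
}

# Two labelings agree iff they induce the same partition.
same_partition <- function(a, b) {
  identical(as.integer(match(a, unique(a))), as.integer(match(b, unique(b))))
}

# Noise-free single-exponential FRAP trace in the package's table dialect:
# three pre-bleach frames at 100%, then the bleach frame (the first
# post-bleach sample) and the recovery.
make_exp_frap_trace <- function(F0, plateau, k, n_post = 80, dt = 0.5) {
  t_post <- seq(0, by = dt, length.out = n_post)
  tibble::tibble(
    time_s = c(0, dt, 2 * dt, 3 * dt + t_post),
    frame = seq_len(3 + n_post),
    roi_id = "bleach",
    intensity = c(100, 100, 100, F0 + (plateau - F0) * (1 - exp(-k * t_post))),
    is_bleach_frame = c(FALSE, FALSE, FALSE, TRUE, rep(FALSE, n_post - 1))
  )
}

# Binomial central 95% interval for an estimated proportion.
binom_interval <- function(p, n) {
  c(stats::qbinom(0.025, n, p), stats::qbinom(0.975, n, p)) / n
}
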