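# Independent brute-force oracles used to check the analytical paths.

# Exact two-sided rank-sum p by enumerating every assignment of group
# labels to the pooled ranks (subset enumeration).
enum_rank_sum_p <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  sets <- utils::combn(n + m, n)
  u_all <- apply(sets, 2, function(ix) sum(r[ix]) - n * (n + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Exact two-sided signed-rank p via the generating-polynomial (dynamic
# programming) route: a different algorithm from the package's direct
# sign-pattern enumeration. Midranks are doubled to keep integer steps.
dp_signed_rank_p <- function(d) {
  d <- d[d != 0]
  r2 <- as.integer(round(2 * rank(abs(d))))
  v_obs <- sum(r2[d > 0])
  dist <- c(1, rep(0, sum(r2)))  # dist[v + 1] = count of patterns with sum v
  for (rr in r2) {
    shifted <- c(rep(0, rr), dist[seq_len(length(dist) - rr)])
    dist <- dist + shifted
  }
  total <- sum(dist)
  v_grid <- seq_along(dist) - 1L
  min(1, 2 * min(sum(dist[v_grid <= v_obs]) / total,
                 sum(dist[v_grid >= v_obs]) / total))
}

# Step-up BH adjustment written out directly from its definition.
bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in rev(seq_len(m))) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- running
  }
  adj
}

# Per-bin membership test for the exclusion step (brute force over
# edges, independent of the vectorized implementation).
brute_force_retained <- function(low, high, width, ranges) {
  n_bins <- round((high - low) / width)
  keep <- logical(n_bins)
  for (k in seq_len(n_bins)) {
    center <- low + (k - 1) * width + width / 2
    inside <- FALSE
    for (r in ranges) {
      if (center > r[1] && center < r[2]) inside <- TRUE
    }
    keep[k] <- !inside
  }
  keep
}

# small fast cohorts for the multivariate tests
quick_design <- function(..., axis_points = 4096) {
  cohort_design(..., axis = default_ppm_axis(axis_points))
}
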