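# Independent oracles used across the suite. These deliberately share no
# code with the implementation: the run-length oracle walks every start
# voxel; the T2 oracle grid-searches the sum of squared errors on the
# exponential model with S0 profiled out.

# Brute-force run-length walker: for every voxel that starts a run (its
# predecessor along -direction is outside the mask/volume or differs in
# level), walk forward and count. Returns a counts matrix like
# run_length_matrix()$counts.
oracle_rlm_counts <- function(q, mask, direction, G = max(q[mask])) {
  d <- dim(q)
  inside <- function(p) all(p >= 1L) && all(p <= d)
  at <- function(p) q[p[1], p[2], p[3]]
  mk <- function(p) mask[p[1], p[2], p[3]]
  lev <- integer(0)
  len <- integer(0)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    p <- c(x, y, z)
    if (!mk(p)) next
    prev <- p - direction
    if (inside(prev) && mk(prev) && at(prev) == at(p)) next
    l <- 1L
    nxt <- p + direction
    while (inside(nxt) && mk(nxt) && at(nxt) == at(p)) {
      l <- l + 1L
      nxt <- nxt + direction
    }
    lev <- c(lev, at(p))
    len <- c(len, l)
  }
  jmax <- max(len)
  counts <- matrix(0L, G, jmax)
  for (i in seq_along(lev)) counts[lev[i], len[i]] <- counts[lev[i], len[i]] + 1L
  counts
}

expect_rlm_matches_oracle <- function(q, mask, direction) {
  m <- run_length_matrix(q, mask, direction)
  oc <- oracle_rlm_counts(q, mask, direction, G = nrow(m$counts))
  # pad to common width
  w <- max(ncol(m$counts), ncol(oc))
  pad <- function(a) cbind(a, matrix(0L, nrow(a), w - ncol(a)))
  expect_identical(unname(pad(m$counts)), unname(pad(oc)))
}

# Grid-search T2 oracle: minimizes SSE of S0*exp(-TE/T2) over a T2 grid,
# with the optimal S0 for each candidate T2 given in closed form.
# `sig` is a voxels x echoes matrix.
oracle_t2_grid <- function(sig, te, t2_grid = seq(20, 80, by = 0.01)) {
  E <- exp(outer(-1 / t2_grid, te))     # grid x echoes
  e2 <- rowSums(E^2)
  apply(sig, 1, function(s) {
    es <- as.vector(E %*% s)
    s0 <- es / e2
    sse <- s0^2 * e2 - 2 * s0 * es + sum(s^2)
    t2_grid[which.min(sse)]
  })
}

# small noiseless multi-echo volume with a given per-voxel T2 array
make_decay_volume <- function(t2, te = seq(10, 100, 10), s0 = 1000,
                              noise_sd = 0, voxel_size = c(1, 1, 1)) {
  d <- dim(t2)
  sig <- array(0, c(d, length(te)))
  for (e in seq_along(te)) sig[, , , e] <- s0 * exp(-te[e] / t2)
  if (noise_sd > 0)
    sig <- sig + array(rnorm(length(sig), 0, noise_sd), dim(sig))
  multi_echo_volume(sig, te, voxel_size)
}
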