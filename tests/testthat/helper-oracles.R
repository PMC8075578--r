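# Brute-force oracles, kept deliberately naive and independent of the
# package's implementation paths.

# pooled coactivity null: builds every shuffled raster explicitly
oracle_coactivity_threshold <- function(B, n_shuffles, alpha, seed) {
  set.seed(seed)
  pool <- c()
  for (s in seq_len(n_shuffles)) {
    Bs <- matrix(0L, nrow(B), ncol(B))
    for (i in seq_len(nrow(B))) {
      k <- sum(B[i, ])
      if (k > 0) Bs[i, sample.int(ncol(B), k)] <- 1L
    }
    pool <- c(pool, colSums(Bs))
  }
  c_sig <- 0L
  while (mean(pool >= c_sig) >= alpha) c_sig <- c_sig + 1L
  max(c_sig - 1L, 1L)
}

# frame-by-frame peak scan with the plateau-start rule
oracle_peaks <- function(counts, thr) {
  out <- integer(0)
  t <- 1L
  n <- length(counts)
  while (t <= n) {
    run_end <- t
    while (run_end < n && counts[run_end + 1L] == counts[t]) run_end <- run_end + 1L
    prev_ok <- t == 1L || counts[t - 1L] < counts[t]
    next_ok <- run_end == n || counts[run_end + 1L] < counts[t]
    if (prev_ok && next_ok && counts[t] > thr) out <- c(out, t)
    t <- run_end + 1L
  }
  out
}
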