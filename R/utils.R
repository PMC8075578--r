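# Internal helpers shared across modules.

# round-half-up on non-negative values; base round() is half-to-even, which
# would make frame-window arithmetic depend on parity.
round_half_up <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# shoelace polygon area (vertices in order, not necessarily closed)
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

convex_hull_area <- function(xy) {
  if (nrow(xy) < 3L) return(NA_real_)
  h <- grDevices::chull(xy)
  if (length(h) < 3L) return(NA_real_)
  polygon_area(xy[h, , drop = FALSE])
}

# deterministic per-stage sub-seed below 2^31 (polynomial hash of the stage
# name folded with the base seed; stays in exact double range throughout)
stage_seed <- function(seed, stage) {
  h <- 17
  for (b in utf8ToInt(stage)) h <- (h * 31 + b) %% 2147483647
  as.integer((as.numeric(seed) * 1103515245 + h) %% 2147483647)
}

# polynomial string hash as hex; used for config provenance
fnv1a_hex <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# circular shift of a vector by k (k >= 0 moves content rightwards)
circshift <- function(x, k) {
  n <- length(x)
  k <- k %% n
  if (k == 0) return(x)
  c(x[(n - k + 1L):n], x[1L:(n - k)])
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x)

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
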