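# Independent oracles, deliberately kept apart from the package internals.

# Buck saturation pressure written out directly (hand transcription of the
# published constants), for spot-checking the packaged function.
oracle_buck <- function(t) {
  6.1121 * exp((18.678 - t / 234.5) * t / (t + 257.14))
}

# Dew point by bisection on the oracle formula (the package inverts the
# quadratic in closed form).
oracle_dew_point_bisect <- function(temp_c, rh, tol = 1e-9) {
  target <- rh * oracle_buck(temp_c)
  lo <- -40; hi <- temp_c + 1e-9
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (oracle_buck(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Exact Mann-Whitney by explicit enumeration of all labelings (feasible for
# group sizes <= 5).
oracle_mw_enumerate <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  combos <- utils::combn(n, nx)
  ws <- colSums(matrix(r[combos], nrow = nx))
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  list(u = w_obs - nx * (nx + 1) / 2,
       p_two_sided = min(1, 2 * min(p_le, p_ge)))
}

# Two-pass mean / population SD reference.
oracle_mean_sd <- function(v) {
  m <- sum(v) / length(v)
  list(mean = m, sd = sqrt(sum((v - m)^2) / length(v)))
}

table1_ab <- function() {
  t1 <- table1_fixture()
  t1[t1$group %in% c("a", "b"), ]
}
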