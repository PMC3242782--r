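# Independent oracles and small fixtures used across the suite.

# Brute-force per-pixel karyometry: a scalar loop over mask pixels,
# written without reference to the vectorized implementation.
oracle_measure <- function(values, idx, pitch, cutoff) {
  A_T <- 0; A_C <- 0; n_cond <- 0L
  for (i in idx) {
    v <- values[i]
    A_T <- A_T + v
    if (v > cutoff) {
      A_C <- A_C + v
      n_cond <- n_cond + 1L
    }
  }
  S_T <- length(idx) * pitch^2
  S_C <- n_cond * pitch^2
  list(
    A_T = A_T, A_C = A_C,
    Ac_pct = if (A_T > 0) 100 * A_C / A_T else NA_real_,
    S_T_um2 = S_T, S_C_um2 = S_C,
    Sc_pct = 100 * S_C / S_T,
    AAR = if (n_cond > 0L) (A_C / S_C) / (A_T / S_T) else NA_real_
  )
}

# Exact two-sided Mann-Whitney p by full enumeration of all
# C(n_a + n_b, n_a) assignments of the pooled values to group a.
# Assumes tie-free samples. U counts pairs (x in a, y in b) with x > y;
# two-sided p doubles the smaller tail, capped at 1.
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(sel) {
    xa <- pooled[sel]
    xb <- pooled[-sel]
    sum(outer(xa, xb, ">"))
  }
  u_obs <- sum(outer(a, b, ">"))
  combos <- utils::combn(length(pooled), na)
  us <- apply(combos, 2L, u_of)
  p_low <- mean(us <= u_obs)
  p_high <- mean(us >= u_obs)
  min(1, 2 * min(p_low, p_high))
}

# Random absorbance image whose OD values are dyadic rationals
# (multiples of 2^-10), so scalar and long-double accumulation agree
# bit-for-bit and exact equality checks are meaningful.
random_dyadic_image <- function(nr, nc, pitch = 0.5) {
  vals <- sample.int(308L, nr * nc, replace = TRUE) - 1L  # 0 .. 0.2998
  absorbance_image(matrix(vals / 1024, nr, nc), pitch,
                   source = "synthetic")
}

# Small flat absorbance image from a literal matrix.
tiny_img <- function(values, pitch = 0.5) {
  absorbance_image(values, pitch, source = "synthetic")
}
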