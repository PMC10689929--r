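# Independent oracles, deliberately naive: exhaustive pairwise loops for
# distances, hypergeometric enumeration for the exact 2x2 p-value, and
# full rank-assignment enumeration for the exact rank-sum p-value. They
# share no code with the implementation paths they check.

oracle_min_pairwise <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt(sum((a[i, ] - b[j, ])^2))
      if (d < best) best <- d
    }
  }
  best
}

heavy_coords <- function(df) {
  df <- df[!df$is_hydrogen, , drop = FALSE]
  cbind(df$x, df$y, df$z)
}

# exact two-sided Fisher p: sum of hypergeometric point probabilities (at
# the observed margins) not exceeding the observed one
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  support <- max(0, r1 - c2):min(r1, c1)
  probs <- stats::dhyper(support, c1, c2, r1)
  p_obs <- stats::dhyper(a, c1, c2, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided rank-sum p by enumerating every assignment of the
# pooled ranks to the first sample (tie-free data only)
oracle_wilcox_p <- function(a, b) {
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  all_u <- apply(utils::combn(n + m, n), 2,
                 function(idx) sum(r[idx]) - n * (n + 1) / 2)
  p_lo <- mean(all_u <= u_obs)
  p_hi <- mean(all_u >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# eigen-decomposition oracle for the principal direction of a point cloud
oracle_principal_direction <- function(xyz) {
  centered <- sweep(xyz, 2, colMeans(xyz))
  eigen(crossprod(centered) / (nrow(xyz) - 1))$vectors[, 1]
}
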