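# Shared fixtures and independent oracles.

# five-gene worked micro-example: z = (2, -1, 0.5, -0.2, 3)
# -> r = (4, 3, 2, 1, 5), s = (+, -, +, -, +)
sig5 <- function() {
  tibble::tibble(gene = paste0("g", 1:5), z = c(2, -1, 0.5, -0.2, 3))
}

reg5 <- function() {
  tibble::tibble(regulator = "r1", target = c("g1", "g5"), aw = 1, am = 0.5)
}

# Exhaustive enumeration oracle for the Maximum-Entropy null: targets are
# i.i.d. uniform over the G observed (r, s) entries WITH replacement, so all
# G^N placements are enumerated and the empirical mean/variance/covariance
# of (DES, UES) computed by brute force. Kept independent of the package's
# analytical formulas.
enum_null_moments <- function(r, s, aw, am) {
  G <- length(r)
  N <- length(aw)
  grids <- rep(list(seq_len(G)), N)
  placements <- as.matrix(expand.grid(grids))
  des <- numeric(nrow(placements))
  ues <- numeric(nrow(placements))
  for (i in seq_len(nrow(placements))) {
    pos <- placements[i, ]
    des[i] <- sum(aw * am * r[pos] * s[pos])
    ues[i] <- sum(aw * (1 - abs(am)) * r[pos])
  }
  n <- length(des)
  list(
    e_des = mean(des),
    v_des = mean(des^2) - mean(des)^2,
    e_ues = mean(ues),
    v_ues = mean(ues^2) - mean(ues)^2,
    cov = mean(des * ues) - mean(des) * mean(ues)
  )
}

# Monte-Carlo draws of the full per-regulon score pipeline under the null
# (targets placed i.i.d. uniform with replacement), used for calibration
# properties. Uses the package's scoring path on each draw.
mc_null_scores <- function(rss, aw, am, n_draws, seed = 1) {
  set.seed(seed)
  np <- narnea:::null_params(rss$moments, aw, am)
  N <- length(aw)
  idx <- matrix(sample.int(rss$G, n_draws * N, replace = TRUE), n_draws, N)
  out <- matrix(NA_real_, n_draws, 9)
  colnames(out) <- c("ndes", "nues", "phi", "nes_pos", "nes_neg",
                     "p_pos", "p_neg", "p", "nes")
  for (i in seq_len(n_draws)) {
    r <- rss$r[idx[i, ]]
    s <- rss$s[idx[i, ]]
    sc <- narnea:::score_from_raw(sum(aw * am * r * s),
                                  sum(aw * (1 - abs(am)) * r), np)
    out[i, ] <- c(sc$ndes, sc$nues, sc$phi, sc$nes_pos, sc$nes_neg,
                  sc$p_pos, sc$p_neg, sc$p, sc$nes)
  }
  as.data.frame(out)
}
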