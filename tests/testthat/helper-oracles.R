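# Independent oracles: deliberately naive per-gene loops and closed forms,
# kept free of the package's vectorized code paths.

oracle_specificity <- function(r, z) {
  num <- 0L; den <- 0L
  for (i in seq_along(r$values)) {
    if (r$values[[i]] != 0L) {
      den <- den + 1L
      if (z$values[[i]] != 0L) num <- num + 1L
    }
  }
  num / den
}

oracle_concordance <- function(r, z) {
  conc <- 0L; disc <- 0L
  for (i in seq_along(r$values)) {
    p <- r$values[[i]] * z$values[[i]]
    if (p > 0L) conc <- conc + 1L
    if (p < 0L) disc <- disc + 1L
  }
  list(n_concordant = conc, n_discordant = disc,
       adj_cr = (conc + 1) / (disc + 1))
}

# Explicit label-shuffling permutation null: independently re-randomizes the
# positions of both signatures' +1/-1 labels, preserving (n_pos, n_neg).
oracle_perm_null <- function(r, z, n_perm, seed) {
  set.seed(seed)
  n <- length(r$values)
  vapply(seq_len(n_perm), function(i) {
    rp <- integer(n); zp <- integer(n)
    rp[sample.int(n, r$n_pos + r$n_neg)] <- c(rep(1L, r$n_pos), rep(-1L, r$n_neg))
    zp[sample.int(n, z$n_pos + z$n_neg)] <- c(rep(1L, z$n_pos), rep(-1L, z$n_neg))
    pr <- rp * zp
    (sum(pr > 0L) + 1) / (sum(pr < 0L) + 1)
  }, numeric(1))
}

# Hypergeometric upper-tail P(X >= k) from first principles (log-binomials).
oracle_hyper_tail <- function(k, K, n, N) {
  js <- k:min(K, n)
  if (length(js) == 0L || k > min(K, n)) return(0)
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}

random_ternary <- function(universe, n_pos, n_neg, provenance = "aging") {
  vals <- integer(length(universe))
  idx <- sample.int(length(universe), n_pos + n_neg)
  vals[idx] <- c(rep(1L, n_pos), rep(-1L, n_neg))
  ternary_signature(stats::setNames(vals, universe), provenance)
}

make_universe <- function(n) sprintf("g%04d", seq_len(n))
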