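# Independent brute-force oracles, written against the textbook definitions
# and kept free of any package internals.

# Nei pi with unbiased correction: mean pairwise difference over all
# distinct (unordered) sequence pairs.
oracle_pi <- function(x) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  diffs <- 0L
  for (i in 1:(n - 1)) for (j in (i + 1):n) diffs <- diffs + (x[i] != x[j])
  diffs / choose(n, 2)
}

# d_xy: mean difference over all cross-population sequence pairs.
oracle_dxy <- function(x, y) {
  diffs <- 0L
  for (i in seq_along(x)) for (j in seq_along(y)) diffs <- diffs + (x[i] != y[j])
  diffs / (length(x) * length(y))
}

# Weir & Cockerham theta for haploid samples, coded component-wise with
# explicit loops over alleles and demes.
oracle_fst_wc <- function(counts) {
  counts <- as.matrix(counts)
  r <- nrow(counts)
  ni <- rowSums(counts)
  ntot <- sum(ni)
  nc <- (ntot - sum(ni^2) / ntot) / (r - 1)
  num <- 0
  den <- 0
  for (al in seq_len(ncol(counts))) {
    p <- counts[, al] / ni
    pbar <- sum(counts[, al]) / ntot
    msp <- 0
    ssg <- 0
    for (i in seq_len(r)) {
      msp <- msp + ni[i] * (p[i] - pbar)^2
      ssg <- ssg + ni[i] * p[i] * (1 - p[i])
    }
    msp <- msp / (r - 1)
    msg <- ssg / (ntot - r)
    a <- (msp - msg) / nc
    num <- num + a
    den <- den + a + msg
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Pearson r^2 computed from the 2x2 haplotype table via D^2 / (pA qA pB qB).
oracle_r2 <- function(x, y) {
  pA <- mean(x)
  pB <- mean(y)
  D <- mean(x * y) - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}
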