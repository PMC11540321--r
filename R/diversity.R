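#' Within-population nucleotide diversity at one locus
#'
#' Nei's pi with the unbiased sample-size correction:
#' `pi = n/(n-1) * (1 - sum_i x_i^2)` where `x_i` are the frequencies of the
#' distinct allelic states among the `n` sampled sequences (for a diallelic
#' locus this is `2 p (1-p) n/(n-1)`). States are compared by exact value
#' identity, so multiallelic continuum-of-alleles loci are handled.
#'
#' @param x Vector of allelic states (one sequence each).
#' @return Diversity (>= 0), or `NA` when `n < 2`.
#' @examples
#' nuc_div(c(0, 0, 1, 1))      # 2/3
#' nuc_div(rep(1, 10))         # 0
#' @export
nuc_div <- function(x) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  p <- tabulate(match(x, unique(x))) / n
  (1 - sum(p^2)) * n / (n - 1)
}

#' Between-population diversity at one locus
#'
#' Average pairwise difference between one sequence from each population:
#' `d_xy = 1 - sum_s fA(s) fB(s)` over the union of states (diallelic:
#' `pA (1 - pB) + pB (1 - pA)`). No sample-size correction is applied.
#'
#' @param x,y State vectors for the two populations.
#' @return `d_xy` in \[0, 1\], or `NA` if either sample is empty.
#' @export
dxy <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) return(NA_real_)
  states <- unique(c(x, y))
  fx <- tabulate(match(x, states), nbins = length(states)) / length(x)
  fy <- tabulate(match(y, states), nbins = length(states)) / length(y)
  1 - sum(fx * fy)
}

# Weir-Cockerham variance components for haploid-sampled allele counts.
# counts: demes x alleles matrix. Returns c(a, b): among- and within-deme
# components summed over alleles (the within-individual component of the
# diploid estimator is identically 0 for haplotype sampling).
fst_components <- function(counts) {
  counts <- as.matrix(counts)
  r <- nrow(counts)
  if (r < 2) stop("F_ST requires at least two populations")
  ni <- rowSums(counts)
  if (any(ni < 1)) stop("every population needs at least one sampled allele")
  n_tot <- sum(ni)
  nc <- (n_tot - sum(ni^2) / n_tot) / (r - 1)
  p <- counts / ni
  pbar <- colSums(counts) / n_tot
  msp <- colSums(ni * sweep(p, 2, pbar)^2) / (r - 1)
  msg <- colSums(ni * p * (1 - p)) / (n_tot - r)
  a <- sum((msp - msg) / nc)
  b <- sum(msg)
  c(a = a, b = b)
}

#' Weir-Cockerham F_ST from per-population allele counts at one locus
#'
#' The variance-components (ANOVA) estimator `theta = a / (a + b)` for
#' haploid-sampled allele counts; multiallelic loci use the ratio of
#' allele-summed components. Slightly negative values are retained. Returns
#' `NA` when the pooled sample is monomorphic.
#'
#' @param counts A `populations x alleles` matrix of allele counts.
#' @return `theta` (typically in \[-small, 1\]), or `NA` if monomorphic.
#' @examples
#' fst_wc(rbind(c(80, 20), c(20, 80)))
#' @export
fst_wc <- function(counts) {
  counts <- as.matrix(counts)
  pooled <- colSums(counts)
  if (sum(pooled > 0) < 2) return(NA_real_)
  ab <- fst_components(counts)
  denom <- ab[["a"]] + ab[["b"]]
  if (denom == 0) return(NA_real_)
  ab[["a"]] / denom
}

#' Multi-locus Weir-Cockerham F_ST (ratio of sums)
#'
#' Averaged-over-loci F_ST as the ratio of summed variance components, the
#' standard aggregation for the Weir-Cockerham estimator.
#'
#' @param counts_list List of per-locus `populations x alleles` count
#'   matrices; monomorphic loci are skipped.
#' @return Global `theta`, or `NA` if every locus is monomorphic.
#' @export
fst_wc_global <- function(counts_list) {
  comps <- lapply(counts_list, function(ct) {
    if (sum(colSums(as.matrix(ct)) > 0) < 2) return(c(a = 0, b = 0))
    fst_components(ct)
  })
  a <- sum(vapply(comps, `[[`, numeric(1), "a"))
  b <- sum(vapply(comps, `[[`, numeric(1), "b"))
  if (a + b == 0) return(NA_real_)
  a / (a + b)
}

#' Linkage disequilibrium r^2 between a selected and a neutral locus
#'
#' Squared Pearson correlation between the 0/1 neutral allele and the
#' selected-locus allele-class indicator across pooled haplotypes. Selected
#' continuum alleles are dichotomized by effect sign (>= 0 vs < 0) via
#' [dichotomize_effect()] before calling.
#'
#' @param x,y Haplotype state vectors (same length, pooled metapopulation).
#' @return `r^2` in \[0, 1\], or `NA` if either locus is monomorphic.
#' @examples
#' ld_r2(rep(c(0, 1), c(50, 50)), rep(c(0, 1, 0, 1), c(40, 10, 10, 40)))
#' @export
ld_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
  cor(x, y)^2
}

#' Dichotomize selected-locus allele effects by sign
#'
#' @param x Allelic effect values.
#' @return 0/1 indicator (`1` for effect >= 0).
#' @export
dichotomize_effect <- function(x) as.numeric(x >= 0)

# Vectorized W&C theta for diallelic loci with equal deme sizes.
# P: loci x d matrix of allele frequencies; n: haplotypes per deme.
fst_wc_binary_vec <- function(P, n) {
  r <- ncol(P)
  n_tot <- n * r
  nc <- (n_tot - r * n^2 / n_tot) / (r - 1)
  pbar <- rowMeans(P)
  msp <- n * rowSums((P - pbar)^2) / (r - 1)
  msg <- n * rowSums(P * (1 - P)) / (n_tot - r)
  # both alleles contribute equal components; the factor 2 cancels
  theta <- (msp - msg) / nc / ((msp - msg) / nc + msg)
  theta[pbar <= 0 | pbar >= 1] <- NA_real_
  theta
}

#' Per-locus diversity metrics from a metapopulation state
#'
#' Computes, for every locus at one time point: within-patch nucleotide
#' diversity `pi_w` (per patch), between-patch `dxy` (per patch pair),
#' pooled total diversity `pi_total`, Weir-Cockerham `fst` across all
#' patches, and `r2` (linkage disequilibrium with the complement's selected
#' locus, pooled haplotypes, selected alleles dichotomized by sign). Also
#' emits per-patch `adaptive_freq_pos` (frequency of positive-effect alleles
#' at each selected locus) and `mean_phenotype` (per patch, `locus_id` NA).
#' Census statistics over all `2 N` haplotypes, no subsampling.
#'
#' @param state List of per-patch haplotype matrices (as returned by
#'   [initialize_metapop()] or carried by a `wf_sim`).
#' @param map The `genetic_map`.
#' @param generation Generation stamp for the output rows.
#' @return Tidy tibble: `generation`, `patch` (patch index, `"i-j"` for
#'   pairs, `"all"` for pooled metrics), `locus_id`, `kind`, `distance_cM`,
#'   `metric`, `value`.
#' @export
locus_metrics <- function(state, map, generation = NA_integer_) {
  d <- length(state)
  L <- nrow(map)
  hapn <- nrow(state[[1]])
  n_corr <- hapn / (hapn - 1)
  neu <- which(map$kind == "neutral")
  sel <- which(map$kind == "selected")

  rows <- list()
  add <- function(patch, locus_idx, metric, value) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      generation = generation, patch = patch,
      locus_id = if (is.null(locus_idx)) NA_integer_ else map$locus_id[locus_idx],
      kind = if (is.null(locus_idx)) NA_character_ else map$kind[locus_idx],
      distance_cM = if (is.null(locus_idx)) NA_real_
                    else abs(map$signed_distance_cM[locus_idx]),
      metric = metric, value = value)
  }

  # --- neutral (binary) loci, vectorized ---------------------------------
  P <- vapply(state, function(h) colMeans(h[, neu, drop = FALSE]),
              numeric(length(neu)))               # loci x d
  P <- matrix(P, ncol = d)
  for (p in seq_len(d))
    add(as.character(p), neu, "pi_w", 2 * P[, p] * (1 - P[, p]) * n_corr)
  for (i in seq_len(d - 1)) for (j in seq((i + 1), d))
    add(paste0(i, "-", j), neu, "dxy",
        P[, i] * (1 - P[, j]) + P[, j] * (1 - P[, i]))
  pbar <- rowMeans(P)
  tot_corr <- (hapn * d) / (hapn * d - 1)
  add("all", neu, "pi_total", 2 * pbar * (1 - pbar) * tot_corr)
  add("all", neu, "fst", fst_wc_binary_vec(P, hapn))

  # --- selected loci (possibly multiallelic), per locus ------------------
  for (s in sel) {
    cols <- lapply(state, function(h) h[, s])
    for (p in seq_len(d)) add(as.character(p), s, "pi_w", nuc_div(cols[[p]]))
    for (i in seq_len(d - 1)) for (j in seq((i + 1), d))
      add(paste0(i, "-", j), s, "dxy", dxy(cols[[i]], cols[[j]]))
    pooled <- unlist(cols)
    add("all", s, "pi_total", nuc_div(pooled))
    states_u <- unique(pooled)
    if (length(states_u) < 2) {
      add("all", s, "fst", NA_real_)
    } else {
      counts <- matrix(unlist(lapply(cols, function(v)
        tabulate(match(v, states_u), nbins = length(states_u)))),
        nrow = d, byrow = TRUE)
      add("all", s, "fst", fst_wc(counts))
    }
    for (p in seq_len(d))
      add(as.character(p), s, "adaptive_freq_pos", mean(cols[[p]] > 0))
  }

  # --- LD with the complement's selected locus (pooled haplotypes) -------
  for (cid in unique(map$complement_id)) {
    s <- sel[map$complement_id[sel] == cid]
    ind <- dichotomize_effect(unlist(lapply(state, function(h) h[, s])))
    cneu <- neu[map$complement_id[neu] == cid]
    if (length(cneu) > 0) {
      X <- do.call(rbind, lapply(state, function(h) h[, cneu, drop = FALSE]))
      r2 <- if (length(unique(ind)) < 2) rep(NA_real_, length(cneu)) else {
        sx <- apply(X, 2, stats::sd)
        r <- suppressWarnings(as.vector(cor(X, ind)))
        r2v <- r^2
        r2v[sx == 0] <- NA_real_
        r2v
      }
      add("all", cneu, "r2", r2)
    }
  }

  # --- patch phenotype means --------------------------------------------
  for (p in seq_len(d))
    add(as.character(p), NULL, "mean_phenotype",
        sum(state[[p]][, sel, drop = FALSE]) / (hapn / 2))

  dplyr::bind_rows(rows)
}
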