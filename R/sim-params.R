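#' Simulation parameters for one migration-selection run
#'
#' Bundles everything one run needs: landscape (`d` patches of `N` diploids,
#' forward migration rate `m`), Gaussian stabilizing selection of strength
#' `V_S` towards patch optima `theta`, the genetic architecture of the
#' selected trait (`n_adaptive` loci under one of three effect models) and
#' the two mutation rates. The run length defaults to `25 * N * d`
#' generations with metrics sampled every `N * d / 2` generations.
#'
#' Effect models:
#' * `"continuum"`: multiallelic selected loci; each mutation adds a
#'   Normal(0, 1) increment to the allelic effect (continuum of alleles);
#'   initial state controlled by `continuum_init`.
#' * `"nonredundant_diallelic"`: diallelic loci with effects
#'   `± 1 / (2 * n_adaptive)`, so the optimum (±1) requires the optimal
#'   homozygote at every locus; house-of-cards mutation flips the allele.
#' * `"redundant_diallelic"`: diallelic loci with effects ±0.25 regardless
#'   of locus number, so any two optimal homozygous loci reach the optimum.
#'
#' @param N Diploid individuals per patch.
#' @param d Number of patches (2 = island pair; >= 3 = linear stepping stone).
#' @param m Forward migration rate per generation, in \[0, 1\].
#' @param V_S Variance of the Gaussian fitness function
#'   `W(z) = exp(-(z - theta)^2 / (2 V_S))`; `1e9` is the neutral control.
#' @param theta Patch optima (length `d`). Defaults to `c(-1, 1)` for two
#'   patches and a linear gradient from -1 to +1 otherwise.
#' @param n_adaptive Number of selected loci `l`.
#' @param effect_model One of `"continuum"`, `"nonredundant_diallelic"`,
#'   `"redundant_diallelic"`.
#' @param adaptive_allele_effect Magnitude of the diallelic allele effect.
#'   Fixed by the model (`1/(2 l)` nonredundant, `0.25` redundant); supplying
#'   a conflicting value is an error.
#' @param selection_on Which patch optimum a parent's fitness is evaluated
#'   against: `"natal"` (default) evaluates every parent against its own
#'   resident patch optimum (viability selection strictly before
#'   dispersal); `"destination"` weighs candidate parents by fitness
#'   against the optimum of the patch their offspring will live in —
#'   equivalent to juveniles dispersing first and surviving viability
#'   selection in the destination patch. See the vignette.
#' @param continuum_init Initial state of continuum selected loci:
#'   `"standing"` (default) draws every initial allele copy from the
#'   mutational kernel Normal(0, 1), extending the maximal-standing-variation
#'   initialization to the selected locus; `"monomorphic"` starts all copies
#'   at effect 0 so divergence is entirely mutation-driven. See the vignette
#'   for why the standing start is the default.
#' @param mu_neutral,mu_adaptive Per-locus per-generation mutation rates.
#' @param generations Run length (default `25 * N * d`).
#' @param sample_every Metric sampling interval (default `N * d / 2`).
#' @param seed Integer seed; the run is fully reproducible from it.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(N = 1000L, d = 2L, m = 0, V_S = 5,
                       theta = NULL, n_adaptive = 1L,
                       effect_model = c("continuum", "nonredundant_diallelic",
                                        "redundant_diallelic"),
                       adaptive_allele_effect = NULL,
                       selection_on = c("natal", "destination"),
                       continuum_init = c("standing", "monomorphic"),
                       mu_neutral = 1e-5, mu_adaptive = 1e-5,
                       generations = NULL, sample_every = NULL,
                       seed = 1L) {
  effect_model <- match.arg(effect_model)
  selection_on <- match.arg(selection_on)
  continuum_init <- match.arg(continuum_init)
  N <- as.integer(N); d <- as.integer(d)
  if (N < 2) stop("N must be >= 2")
  if (d < 2) stop("d must be >= 2")
  if (m < 0 || m > 1) stop("m must lie in [0, 1]")
  if (V_S <= 0) stop("V_S must be positive")
  if (n_adaptive < 1) stop("n_adaptive must be >= 1")
  if (mu_neutral < 0 || mu_neutral > 1 || mu_adaptive < 0 || mu_adaptive > 1)
    stop("mutation rates must lie in [0, 1]")

  theta <- theta %||% (if (d == 2) c(-1, 1) else seq(-1, 1, length.out = d))
  if (length(theta) != d) stop("theta must have length d")

  expected_effect <- switch(effect_model,
    continuum = NA_real_,
    nonredundant_diallelic = 1 / (2 * n_adaptive),
    redundant_diallelic = 0.25)
  if (is.null(adaptive_allele_effect)) {
    adaptive_allele_effect <- expected_effect
  } else if (!is.na(expected_effect) &&
             abs(adaptive_allele_effect - expected_effect) > 1e-12) {
    stop("adaptive_allele_effect must be ", format(expected_effect),
         " for the ", effect_model, " model")
  }

  generations <- as.integer(generations %||% (25 * N * d))
  sample_every <- as.integer(sample_every %||% max(1L, N * d %/% 2L))
  if (generations < sample_every)
    stop("generations must be >= sample_every")

  structure(list(
    N = N, d = d, m = m, V_S = V_S, theta = theta,
    n_adaptive = as.integer(n_adaptive), effect_model = effect_model,
    selection_on = selection_on, continuum_init = continuum_init,
    adaptive_allele_effect = adaptive_allele_effect,
    mu_neutral = mu_neutral, mu_adaptive = mu_adaptive,
    generations = generations, sample_every = sample_every,
    seed = as.integer(seed)
  ), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params> ", x$effect_model,
      sprintf(": d = %d patches x N = %d, m = %g, V_S = %g, l = %d\n",
              x$d, x$N, x$m, x$V_S, x$n_adaptive),
      sprintf("  theta = [%s], mu_neutral = %g, mu_adaptive = %g\n",
              paste(signif(x$theta, 3), collapse = ", "),
              x$mu_neutral, x$mu_adaptive),
      sprintf("  %d generations, sampled every %d, seed %d\n",
              x$generations, x$sample_every, x$seed), sep = "")
  invisible(x)
}

#' Backward migration matrix for an island pair or linear stepping stone
#'
#' Row `i` gives the probability that an offspring born in patch `i` draws
#' its parents from each source patch. For `d = 2` each patch receives
#' fraction `m` from the other. For `d >= 3` (linear stepping stone,
#' dispersal only between adjacent patches) an interior patch receives
#' `m/2` from each neighbour while a terminal patch receives `m/2` from its
#' single neighbour, so the expected immigrant fraction of an interior patch
#' is twice that of a terminal patch.
#'
#' @param m Forward migration rate in \[0, 1\] (`d = 2`) or \[0, 0.5\]
#'   contribution split for stepping stones.
#' @param d Number of patches.
#' @return A `d x d` matrix with rows summing to 1.
#' @examples
#' migration_matrix(0.1, 2)
#' migration_matrix(0.1, 10)[5, 4:6]
#' @export
migration_matrix <- function(m, d) {
  d <- as.integer(d)
  if (d < 2) stop("d must be >= 2")
  if (m < 0 || m > 1) stop("m must lie in [0, 1]")
  M <- matrix(0, d, d)
  if (d == 2) {
    M[1, ] <- c(1 - m, m)
    M[2, ] <- c(m, 1 - m)
  } else {
    for (i in seq_len(d)) {
      if (i > 1) M[i, i - 1] <- m / 2
      if (i < d) M[i, i + 1] <- m / 2
      M[i, i] <- 1 - sum(M[i, ])
    }
  }
  stopifnot(all(abs(rowSums(M) - 1) < 1e-12), all(M >= 0))
  M
}
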