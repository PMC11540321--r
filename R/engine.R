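#' Gaussian stabilizing-selection fitness
#'
#' `W(z) = exp(-(z - theta)^2 / (2 V_S))`. Vectorized over `z`. Within a
#' patch, relative fitness is this value divided by the patch mean; the
#' scaling does not change fitness-proportional parent sampling (the engine
#' skips it) but is applied when fitness itself is reported via
#' `relative = TRUE`.
#'
#' @param z Phenotypic value(s).
#' @param theta Patch optimum.
#' @param V_S Variance of the fitness function (> 0).
#' @param relative If `TRUE`, divide by the mean fitness of `z`.
#' @return Fitness value(s) in (0, 1\] (relative fitness may exceed 1).
#' @export
fitness_gaussian <- function(z, theta, V_S, relative = FALSE) {
  if (V_S <= 0) stop("V_S must be positive")
  w <- exp(-(z - theta)^2 / (2 * V_S))
  if (relative) w / mean(w) else w
}

#' Additive phenotype of diploid genotypes
#'
#' The trait is the sum of both allele effect values over all selected loci
#' (no dominance, no epistasis); neutral loci contribute nothing.
#'
#' @param haps Haplotype matrix (`2 N` rows, one column per locus);
#'   individual `i` owns rows `2i - 1` and `2i`.
#' @param map The `genetic_map` the columns follow.
#' @return Numeric vector of `N` phenotypes.
#' @export
phenotypes <- function(haps, map) {
  stopifnot(nrow(haps) %% 2 == 0, ncol(haps) == nrow(map))
  sel <- which(map$kind == "selected")
  per_hap <- if (length(sel) == 1L) haps[, sel] else rowSums(haps[, sel, drop = FALSE])
  per_hap[seq(1, nrow(haps), by = 2)] + per_hap[seq(2, nrow(haps), by = 2)]
}

#' Initialize the metapopulation state
#'
#' Neutral allele copies are drawn Bernoulli(0.5) — maximal standing
#' variation. Continuum-of-alleles selected loci follow
#' `params$continuum_init`: every allele copy drawn Normal(0, 1)
#' (`"standing"`, the default) or all copies at effect 0
#' (`"monomorphic"`). Diallelic selected loci are initialized
#' Bernoulli(0.5) over the two effect states.
#'
#' @param params A [sim_params()] object.
#' @param map A [build_flanking_map()] map whose selected-locus count equals
#'   `params$n_adaptive`.
#' @return List of `d` haplotype matrices (`2 N` x loci).
#' @export
initialize_metapop <- function(params, map) {
  stopifnot(inherits(params, "sim_params"), inherits(map, "genetic_map"))
  n_sel <- sum(map$kind == "selected")
  if (n_sel != params$n_adaptive)
    stop("map has ", n_sel, " selected loci but params expect ",
         params$n_adaptive)
  L <- nrow(map)
  hapn <- 2L * params$N
  sel <- which(map$kind == "selected")
  a <- params$adaptive_allele_effect
  with_seed(params$seed, {
    lapply(seq_len(params$d), function(p) {
      h <- matrix(rbinom(hapn * L, 1L, 0.5), hapn, L)
      if (params$effect_model == "continuum") {
        h[, sel] <- if (identical(params$continuum_init, "monomorphic")) 0
                    else rnorm(hapn * length(sel))
      } else {
        h[, sel] <- a * (2 * h[, sel, drop = FALSE] - 1)
      }
      storage.mode(h) <- "double"
      h
    })
  })
}

#' Run a forward-time migration-selection simulation
#'
#' Executes the Wright-Fisher life cycle (backward migration, soft
#' fitness-proportional parent sampling against the parent's resident-patch
#' optimum, per-interval recombination, mutation) for
#' `params$generations` generations, computing per-locus diversity metrics
#' at every sampling point. Fully reproducible from `params$seed`.
#'
#' @param params A [sim_params()] object.
#' @param map A `genetic_map`.
#' @param metrics If `FALSE`, skip metric computation (only the final state
#'   is returned; much faster for runs that only need selected-locus
#'   summaries).
#' @param final_only If `TRUE`, compute metrics at the final generation only.
#' @return An object of class `wf_sim`: a list with `metrics` (tidy tibble:
#'   `generation`, `patch`, `locus_id`, `kind`, `distance_cM`, `metric`,
#'   `value`), `final_state` (list of haplotype matrices), `params`, `map`.
#' @seealso [locus_metrics()] for the metric definitions, [tidy.wf_sim()].
#' @export
simulate_metapop <- function(params, map, metrics = TRUE, final_only = FALSE) {
  stopifnot(inherits(params, "sim_params"), inherits(map, "genetic_map"))
  state0 <- initialize_metapop(params, map)
  eng_par <- list(
    theta = params$theta, V_S = params$V_S,
    mu_neutral = params$mu_neutral, mu_adaptive = params$mu_adaptive,
    adaptive_model = if (params$effect_model == "continuum") 0L else 1L,
    selection_on_destination =
      as.integer(identical(params$selection_on %||% "destination",
                           "destination")),
    migration = migration_matrix(params$m, params$d)
  )
  ptr <- engine_create(state0, rec_fractions(map),
                       which(map$kind == "selected"), eng_par,
                       as.double(derive_seed(params$seed, 1L)))
  times <- unique(c(seq(params$sample_every, params$generations,
                        by = params$sample_every), params$generations))
  if (final_only) times <- params$generations
  out <- vector("list", length(times))
  at <- 0L
  for (k in seq_along(times)) {
    engine_run(ptr, times[k] - at)
    at <- times[k]
    if (metrics) {
      out[[k]] <- locus_metrics(engine_state(ptr), map, generation = at)
    }
  }
  structure(list(
    metrics = if (metrics) dplyr::bind_rows(out) else NULL,
    final_state = engine_state(ptr),
    params = params, map = map
  ), class = "wf_sim")
}

#' @export
print.wf_sim <- function(x, ...) {
  cat(sprintf("<wf_sim> %d generations, %d patches x N = %d, %d loci\n",
              x$params$generations, x$params$d, x$params$N, nrow(x$map)))
  if (!is.null(x$metrics))
    cat(sprintf("  metrics: %d rows at %d sampling points\n",
                nrow(x$metrics), dplyr::n_distinct(x$metrics$generation)))
  invisible(x)
}

#' Tidy the metric stream of a simulation
#'
#' @param x A `wf_sim`.
#' @param ... Unused.
#' @return The tidy per-locus metric tibble.
#' @export
#' @exportS3Method generics::tidy
tidy.wf_sim <- function(x, ...) x$metrics

#' One-row summary of a simulation
#'
#' @param x A `wf_sim`.
#' @param ... Unused.
#' @return One-row tibble: run parameters plus final-generation means of
#'   neutral within-patch diversity and F_ST.
#' @export
#' @exportS3Method generics::glance
glance.wf_sim <- function(x, ...) {
  p <- x$params
  res <- tibble::tibble(
    model = p$effect_model, N = p$N, d = p$d, m = p$m, V_S = p$V_S,
    n_adaptive = p$n_adaptive, generations = p$generations, seed = p$seed,
    mean_pi_w = NA_real_, mean_fst = NA_real_
  )
  if (!is.null(x$metrics)) {
    fin <- dplyr::filter(x$metrics, .data$generation == max(.data$generation),
                         .data$kind == "neutral")
    res$mean_pi_w <- mean(fin$value[fin$metric == "pi_w"], na.rm = TRUE)
    res$mean_fst <- mean(fin$value[fin$metric == "fst"], na.rm = TRUE)
  }
  res
}

#' Sample gametes from one diploid parent (testing / exploration helper)
#'
#' Builds each gamete by choosing a random starting haplotype and switching
#' haplotypes at interval `i` with probability `rec[i]`, independently per
#' interval.
#'
#' @param parent A `2 x L` haplotype matrix.
#' @param rec Recombination fractions, length `L - 1`.
#' @param n Number of gametes.
#' @param seed Integer seed.
#' @return An `n x L` matrix of gametes.
#' @export
sim_gametes <- function(parent, rec, n, seed = 1L) {
  sim_gametes_cpp(parent, rec, as.integer(n), as.double(seed))
}
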