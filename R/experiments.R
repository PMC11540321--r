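#' Migration-rate grid
#'
#' Forward migration rates from 10^-5 to 10^-0.5 with four equal increments
#' per order of magnitude on the log10 scale, plus `m = 0`.
#'
#' @param include_zero Include `m = 0`.
#' @return Sorted numeric vector (length 20 with zero).
#' @export
migration_grid <- function(include_zero = TRUE) {
  g <- 10^seq(-5, -0.5, by = 0.25)
  if (include_zero) c(0, g) else g
}

#' Neutral diversity expectation in the finite island model
#'
#' Per-locus expected within-population diversity for an unlinked neutral
#' locus: `4 N mu` when `m = 0` (single-deme expectation) and `4 d N mu`
#' when `m > 0` (metapopulation expectation); the small-theta
#' approximation used to scale diversity axes.
#'
#' @param N Individuals per patch.
#' @param d Number of demes.
#' @param mu Per-locus mutation rate.
#' @param m Migration rate.
#' @return Expected diversity (vectorized).
#' @export
neutral_expectation <- function(N, d, mu, m) {
  ifelse(m == 0, 4 * N * mu, 4 * d * N * mu)
}

table1_defaults <- list(
  single2patch = list(
    V_S = c(2, 5, 10, 25, 100, 1e9), N = c(500, 1000, 2000, 10000),
    l = 1L, mu_adaptive_ok = function(mu, N) mu %in% c(1e-5) | abs(mu - 1e-2 / N) < 1e-15,
    effect_model = "continuum", d = 2L, theta_modes = "divergent"),
  multi_nonredundant = list(
    V_S = 5, N = 1000, l = c(1L, 2L, 4L, 10L, 20L, 50L, 100L),
    mu_adaptive_ok = function(mu, N) mu == 1e-5,
    effect_model = "nonredundant_diallelic", d = 2L, theta_modes = "divergent"),
  multi_redundant = list(
    V_S = 5, N = 1000, l = c(4L, 10L, 20L, 50L, 100L),
    mu_adaptive_ok = function(mu, N) mu %in% c(1e-5, 1e-4),
    effect_model = "redundant_diallelic", d = 2L,
    theta_modes = c("divergent", "uniform")),
  single10patch = list(
    V_S = 5, N = 1000, l = 1L,
    mu_adaptive_ok = function(mu, N) mu == 1e-5,
    effect_model = "continuum", d = 10L, theta_modes = "divergent")
)

#' Expand an experiment grid into per-replicate simulation parameters
#'
#' Builds the Cartesian product of the requested grid dimensions,
#' restricted to the combinations the study design defines for each model
#' (e.g. the patch-size grid only exists for the single-locus two-patch
#' model; uniform optima only for the redundant model), with deterministic
#' per-cell-per-replicate seeds derived from `base_seed`. A global
#' `scale` shrinks N and the 25 N d horizon together, preserving the drift
#' time scale for desk-sized runs.
#'
#' @param model One of `"single2patch"`, `"multi_nonredundant"`,
#'   `"multi_redundant"`, `"single10patch"`.
#' @param m Migration grid (default [migration_grid()]).
#' @param V_S,N,l,mu_adaptive Grid values; defaults are the study grids
#'   (scalars where the design fixes them).
#' @param mu_adaptive_scaled For `single2patch`: use the population-size
#'   scaled adaptive mutation rate `1e-2 / N` instead of `1e-5`.
#' @param theta_mode `"divergent"` (optima -1, +1) or `"uniform"`
#'   (+1, +1; redundant model only).
#' @param replicates Replicates per cell.
#' @param base_seed Root seed.
#' @param scale Global down-scaling factor for N (and hence the horizon).
#' @return Tibble with one row per (cell, replicate): grid columns,
#'   `replicate`, `seed`, `scale`, and a `params` list-column of
#'   [sim_params()] objects.
#' @export
expand_sim_grid <- function(model = c("single2patch", "multi_nonredundant",
                                      "multi_redundant", "single10patch"),
                            m = migration_grid(), V_S = NULL, N = NULL,
                            l = NULL, mu_adaptive = NULL,
                            mu_adaptive_scaled = FALSE,
                            theta_mode = "divergent",
                            replicates = 1L, base_seed = 1L, scale = 1) {
  model <- match.arg(model)
  def <- table1_defaults[[model]]
  V_S <- V_S %||% def$V_S
  N <- N %||% (if (model == "single2patch") 1000 else def$N)
  l <- l %||% (if (length(def$l) > 1) def$l[1] else def$l)
  if (!all(l %in% def$l))
    stop("number of adaptive loci ", paste(setdiff(l, def$l), collapse = ", "),
         " is not part of the ", model, " design (allowed: ",
         paste(def$l, collapse = ", "), ")")
  if (!all(N %in% def$N))
    stop("patch size ", paste(setdiff(N, def$N), collapse = ", "),
         " is not part of the ", model, " design (allowed: ",
         paste(def$N, collapse = ", "), ")")
  if (!all(theta_mode %in% def$theta_modes))
    stop("theta_mode '", theta_mode, "' is not part of the ", model, " design")
  if (any(m < 0 | m > 10^-0.5 + 1e-12))
    stop("migration rates must lie in [0, 10^-0.5]")

  grid <- tidyr::expand_grid(model = model, m = m, V_S = V_S, N = N, l = l,
                             theta_mode = theta_mode,
                             replicate = seq_len(replicates))
  grid$mu_adaptive <- mu_adaptive %||%
    (if (mu_adaptive_scaled && model == "single2patch") 1e-2 / grid$N else 1e-5)
  ok <- mapply(def$mu_adaptive_ok, grid$mu_adaptive, grid$N)
  if (!all(ok))
    stop("adaptive mutation rate not part of the ", model, " design")

  grid$scale <- scale
  grid$seed <- vapply(seq_len(nrow(grid)),
                      function(i) derive_seed(base_seed, i), integer(1))
  d <- def$d
  grid$params <- purrr::pmap(
    list(grid$m, grid$V_S, grid$N, grid$l, grid$mu_adaptive, grid$seed,
         grid$theta_mode),
    function(m, vs, n, li, mua, seed, tm) {
      n_sc <- max(2L, as.integer(round(n * scale)))
      theta <- if (tm == "uniform") rep(1, d)
               else if (d == 2) c(-1, 1) else seq(-1, 1, length.out = d)
      sim_params(N = n_sc, d = d, m = m, V_S = vs, theta = theta,
                 n_adaptive = li, effect_model = def$effect_model,
                 mu_adaptive = mua, seed = seed)
    })
  grid
}

#' Mean, median and quantile bands across replicates
#'
#' Per group (everything in `by`): arithmetic mean, median and the
#' 5/25/75/95 percent quantiles of `value`, plus the replicate count.
#' Means feed the headline curves; medians are reported alongside because
#' at very low migration the mean is inflated by rare replicates that
#' recently received a migrant while the median tracks the typical
#' replicate.
#'
#' @param data Tidy per-replicate metric tibble.
#' @param value Value column (tidy-selected).
#' @param by Character vector of grouping columns (defaults to every
#'   column except `value` and `replicate`).
#' @return Tibble with one row per group: `mean`, `median`, `q05`, `q25`,
#'   `q75`, `q95`, `n_rep`.
#' @export
summarize_replicates <- function(data, value = value, by = NULL) {
  vcol <- rlang::as_name(rlang::enquo(value))
  by <- by %||% setdiff(names(data), c(vcol, "replicate", "seed", "params"))
  dplyr::summarise(
    dplyr::group_by(data, dplyr::across(dplyr::all_of(by))),
    mean = mean(.data[[vcol]], na.rm = TRUE),
    median = median(.data[[vcol]], na.rm = TRUE),
    q05 = quantile(.data[[vcol]], 0.05, na.rm = TRUE, names = FALSE),
    q25 = quantile(.data[[vcol]], 0.25, na.rm = TRUE, names = FALSE),
    q75 = quantile(.data[[vcol]], 0.75, na.rm = TRUE, names = FALSE),
    q95 = quantile(.data[[vcol]], 0.95, na.rm = TRUE, names = FALSE),
    n_rep = dplyr::n(),
    .groups = "drop")
}

config_keys <- c("schema", "model", "m", "V_S", "N", "l", "mu_adaptive",
                 "mu_adaptive_scaled", "theta_mode", "replicates",
                 "base_seed", "scale", "n_flank_per_side", "final_only")

#' Run an experiment grid from a YAML config
#'
#' Reads a flat YAML config (`schema: 1`), expands the grid via
#' [expand_sim_grid()], runs every cell x replicate through
#' [simulate_metapop()], and writes per-cell tidy metric TSVs, a
#' per-replicate signature TSV, and a manifest (file name + MD5) to
#' `out_dir`. Cells whose output file already exists are skipped (resume),
#' never overwritten silently. Reruns with identical config and seed
#' produce byte-identical TSVs.
#'
#' @param config Path to a YAML file or an equivalent named list.
#' @param out_dir Output directory (created if missing).
#' @param quiet Suppress per-cell log messages.
#' @return Invisibly, the manifest tibble (`file`, `md5`).
#' @export
run_experiment <- function(config, out_dir, quiet = FALSE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  # YAML 1.1 reads a bare key `N` as the boolean FALSE; map it back
  names(cfg)[names(cfg) %in% c("FALSE", "F")] <- "N"
  bad <- setdiff(names(cfg), config_keys)
  if (length(bad) > 0)
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (is.null(cfg$schema) || cfg$schema != 1)
    stop("config must declare 'schema: 1'")
  if (is.null(cfg$model)) stop("config must name a 'model'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  grid <- expand_sim_grid(
    model = cfg$model, m = unlist(cfg$m %||% migration_grid()),
    V_S = cfg$V_S, N = cfg$N, l = cfg$l, mu_adaptive = cfg$mu_adaptive,
    mu_adaptive_scaled = isTRUE(cfg$mu_adaptive_scaled),
    theta_mode = cfg$theta_mode %||% "divergent",
    replicates = cfg$replicates %||% 1L,
    base_seed = cfg$base_seed %||% 1L, scale = cfg$scale %||% 1)

  nfps <- cfg$n_flank_per_side %||% 37L
  cells <- dplyr::group_split(grid, .data$m, .data$V_S, .data$N, .data$l,
                              .data$mu_adaptive, .data$theta_mode)
  files <- character(0)
  sig_rows <- list()
  for (ci in seq_along(cells)) {
    cell <- cells[[ci]]
    tag <- sprintf("cell_m%0.5g_VS%g_N%g_l%d_%s", cell$m[1], cell$V_S[1],
                   cell$N[1], cell$l[1], cell$theta_mode[1])
    path <- file.path(out_dir, paste0(tag, ".tsv"))
    files <- c(files, path)
    if (file.exists(path)) {
      if (!quiet) message("[", Sys.time(), "] resume: keeping ", path)
      next
    }
    if (!quiet) message("[", Sys.time(), "] running ", tag, " (",
                        nrow(cell), " replicates)")
    map <- build_flanking_map(n_selected = cell$l[1],
                              n_flank_per_side = nfps)
    res <- purrr::map2_dfr(cell$params, cell$replicate, function(p, rep) {
      sim <- simulate_metapop(p, map, final_only = isTRUE(cfg$final_only))
      sig_rows[[length(sig_rows) + 1L]] <<- dplyr::mutate(
        signature_report(sim), model = cfg$model, m = p$m, V_S = p$V_S,
        N = p$N, l = p$n_adaptive, replicate = rep, seed = p$seed,
        .before = 1)
      dplyr::mutate(sim$metrics, replicate = rep, seed = p$seed, .before = 1)
    })
    readr::write_tsv(res, path)
  }
  sig_path <- file.path(out_dir, "signatures.tsv")
  if (length(sig_rows) > 0) {
    sig <- dplyr::bind_rows(sig_rows)
    if (file.exists(sig_path)) {
      old <- readr::read_tsv(sig_path, show_col_types = FALSE)
      old$patch <- as.character(old$patch)
      sig <- dplyr::bind_rows(old, sig)
    }
    readr::write_tsv(sig, sig_path)
  }
  if (file.exists(sig_path)) files <- c(files, sig_path)
  manifest <- tibble::tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files)))
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(manifest)
}

#' Write tidy metrics as TSV
#'
#' @param metrics Tidy metric tibble (e.g. `tidy(sim)`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(metrics, path) {
  readr::write_tsv(metrics, path)
  invisible(path)
}
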