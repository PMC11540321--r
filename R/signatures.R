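#' Diversity-distance regression (dd-slope)
#'
#' Ordinary least squares of a per-locus metric (within-patch diversity or
#' F_ST) on the log10-transformed map distance from the selected locus,
#' pooling both flanks. A positive slope marks a trough around the selected
#' site, a negative slope a peak. Returns the slope with the two-sided
#' t-test p-value for slope = 0; a constant metric yields slope 0, p = 1.
#'
#' @param data Data frame with one row per neutral locus.
#' @param value,distance Columns holding the metric and the (absolute or
#'   signed) distance in cM; tidy-selected.
#' @param average_flanks If `TRUE`, average mirrored loci at equal distances
#'   before regressing (default pools both flanks).
#' @return An object of class `dd_fit` with elements `slope`, `p_value`,
#'   `intercept`, `n`, and the underlying `lm` fit (`NULL` when degenerate).
#' @examples
#' df <- data.frame(distance_cM = 10^seq(-3, 1, 0.5))
#' df$pi_w <- 0.1 + 0.02 * log10(df$distance_cM)
#' tidy(dd_slope(df))
#' @export
dd_slope <- function(data, value = pi_w, distance = distance_cM,
                     average_flanks = FALSE) {
  y <- dplyr::pull(data, {{ value }})
  x <- abs(dplyr::pull(data, {{ distance }}))
  keep <- is.finite(x) & is.finite(y) & x > 0
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("dd_slope needs at least 3 loci with positive distance")
  if (average_flanks) {
    agg <- tapply(y, signif(x, 10), mean)
    x <- as.numeric(names(agg)); y <- as.numeric(agg)
  }
  lx <- log10(x)
  if (stats::sd(y) == 0 || stats::sd(lx) == 0) {
    return(structure(list(slope = 0, p_value = 1, intercept = mean(y),
                          n = length(y), fit = NULL), class = "dd_fit"))
  }
  fit <- lm(y ~ lx)
  sm <- summary(fit)$coefficients
  structure(list(slope = unname(coef(fit)[2]),
                 p_value = unname(sm[2, 4]),
                 intercept = unname(coef(fit)[1]),
                 n = length(y), fit = fit), class = "dd_fit")
}

#' @export
print.dd_fit <- function(x, ...) {
  cat(sprintf("<dd_fit> slope = %.4g (p = %.3g, n = %d loci)\n",
              x$slope, x$p_value, x$n))
  invisible(x)
}

#' @rdname dd_slope
#' @param x A `dd_fit`.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::tidy
tidy.dd_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "log10_distance"),
                 estimate = c(x$intercept, x$slope),
                 p.value = c(NA_real_, x$p_value))
}

#' @rdname dd_slope
#' @export
#' @exportS3Method generics::glance
glance.dd_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, p.value = x$p_value, n = x$n,
                 r.squared = if (is.null(x$fit)) NA_real_
                             else summary(x$fit)$r.squared)
}

#' Diversity contrast between the nearest and farthest neutral loci
#'
#' Mean metric over the flanking loci at exactly `near` cM vs those at
#' exactly `far` cM from the selected locus (the default map places loci at
#' both). A far/near ratio above 1 marks a trough, below 1 a peak.
#'
#' @inheritParams dd_slope
#' @param near,far Distances (cM) of the contrast loci.
#' @return One-row tibble: `near_pi`, `far_pi`, `ratio_far_near`.
#' @export
near_far_contrast <- function(data, value = pi_w, distance = distance_cM,
                              near = 1e-3, far = 10) {
  y <- dplyr::pull(data, {{ value }})
  x <- abs(dplyr::pull(data, {{ distance }}))
  near_i <- abs(x - near) < 1e-9 * max(near, 1)
  far_i <- abs(x - far) < 1e-9 * max(far, 1)
  if (!any(near_i) || !any(far_i))
    stop("map has no loci at the requested contrast distances")
  tibble::tibble(near_pi = mean(y[near_i]), far_pi = mean(y[far_i]),
                 ratio_far_near = far_pi / near_pi)
}

#' Genome-wide background diversity from neutral-control runs
#'
#' Mean within-patch diversity over all neutral loci 9-10 cM from the
#' selected locus, taken from neutral-control runs (`V_S = 1e9`) on a map
#' extended with [add_background_loci()] at matching N, d, m and mu.
#'
#' @inheritParams dd_slope
#' @param range Distance band (cM) defining "background" loci.
#' @return Scalar mean background diversity.
#' @export
background_level <- function(data, value = pi_w, distance = distance_cM,
                             range = c(9, 10)) {
  y <- dplyr::pull(data, {{ value }})
  x <- abs(dplyr::pull(data, {{ distance }}))
  keep <- x >= range[1] - 1e-9 & x <= range[2] + 1e-9
  if (!any(keep)) stop("no loci in the background distance band")
  mean(y[keep], na.rm = TRUE)
}

#' Detect a peak in diversity around the selected locus
#'
#' A peak requires (i) a significantly negative diversity-distance slope
#' (t-test, `alpha`) and (ii) at least `min_prop` of neutral loci with
#' diversity above `excess` times the genome-wide background level.
#'
#' @inheritParams dd_slope
#' @param background Genome-wide background diversity (> 0), from
#'   [background_level()].
#' @param alpha Slope-test significance threshold.
#' @param min_prop Minimum proportion of loci above the excess threshold.
#' @param excess Multiplier of background defining "elevated" diversity.
#' @return One-row tibble: `peak_detected`, `slope`, `slope_p`,
#'   `prop_above`.
#' @export
detect_peak <- function(data, background, value = pi_w,
                        distance = distance_cM, alpha = 0.05,
                        min_prop = 0.25, excess = 1.1) {
  if (!is.finite(background) || background <= 0)
    stop("background must be a positive number")
  fit <- dd_slope(data, {{ value }}, {{ distance }})
  y <- dplyr::pull(data, {{ value }})
  prop <- mean(y > excess * background, na.rm = TRUE)
  tibble::tibble(
    peak_detected = fit$slope < 0 && fit$p_value < alpha && prop >= min_prop,
    slope = fit$slope, slope_p = fit$p_value, prop_above = prop)
}

#' Width of a diversity peak
#'
#' The diversity excess over background of the qualifying neutral loci is
#' regressed on linear cM distance; the x-intercept of the fitted line
#' (where it returns to the background level) is half the peak width.
#' Linear distance is used so that the intercept is directly a distance in
#' cM. Loci qualify when their diversity exceeds `qualify_excess` times
#' the background — the same 1.1 multiplier used by [detect_peak()]. The
#' buffer is load-bearing: with a literal "above background" rule, every
#' baseline locus whose expected diversity equals the background qualifies
#' with probability one half in any finite sample, and those far-flung
#' near-zero excesses drag the x-intercept to chromosome scale. Returns
#' `NA` (with a warning where informative) when fewer than 3 loci qualify,
#' when the qualifying loci span no distance, or when the fitted line never
#' returns to background (non-positive intercept / non-negative slope).
#'
#' @inheritParams detect_peak
#' @param qualify_excess Multiplier of background a locus must exceed to
#'   enter the width regression.
#' @return Peak width in cM, or `NA`.
#' @export
peak_width <- function(data, background, value = pi_w,
                       distance = distance_cM, qualify_excess = 1.1) {
  y <- dplyr::pull(data, {{ value }})
  x <- abs(dplyr::pull(data, {{ distance }}))
  keep <- is.finite(y) & y > qualify_excess * background
  if (sum(keep) < 3) return(NA_real_)
  x <- x[keep]; y <- y[keep] - background
  if (stats::sd(x) == 0) return(NA_real_)
  fit <- lm(y ~ x)
  a <- unname(coef(fit)[1]); b <- unname(coef(fit)[2])
  if (!is.finite(a) || !is.finite(b) || b >= 0 || a <= 0) {
    warning("peak regression has no positive x-intercept; width undefined")
    return(NA_real_)
  }
  2 * (-a / b)
}

#' Proportion of highly differentiated adaptive loci
#'
#' Fraction of adaptive loci whose allele-frequency difference between the
#' two patches is at least `threshold`.
#'
#' @param p1,p2 Per-locus allele frequencies in patch 1 and patch 2 (same
#'   allele), or pass a two-column data frame / matrix as `p1`.
#' @param threshold Differentiation threshold (default 0.95).
#' @return Proportion in \[0, 1\].
#' @export
adaptive_differentiation <- function(p1, p2 = NULL, threshold = 0.95) {
  if (is.null(p2)) {
    p1 <- as.matrix(p1)
    stopifnot(ncol(p1) == 2)
    p2 <- p1[, 2]; p1 <- p1[, 1]
  }
  stopifnot(length(p1) == length(p2))
  mean(abs(p1 - p2) >= threshold)
}

#' Whether a run maintained local adaptation
#'
#' Phenotype criterion (default): the difference in patch-mean phenotype
#' between the two extreme patches at the final sampling point exceeds half
#' the optimum difference. Allele-frequency alternative: the
#' positive-allele frequency difference at the selected locus between the
#' extreme patches is at least 0.5.
#'
#' @param sim A `wf_sim` (run with metrics).
#' @param criterion `"phenotype"` or `"allele_freq"`.
#' @return Logical.
#' @export
maintained_local_adaptation <- function(sim,
                                        criterion = c("phenotype",
                                                      "allele_freq")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(sim, "wf_sim"), !is.null(sim$metrics))
  fin <- dplyr::filter(sim$metrics, .data$generation == max(.data$generation))
  th <- sim$params$theta
  lo <- as.character(which.min(th)); hi <- as.character(which.max(th))
  if (criterion == "phenotype") {
    z <- dplyr::filter(fin, .data$metric == "mean_phenotype")
    zx <- setNames(z$value, z$patch)
    abs(zx[[hi]] - zx[[lo]]) > (max(th) - min(th)) / 2
  } else {
    fr <- dplyr::filter(fin, .data$metric == "adaptive_freq_pos")
    fr <- dplyr::summarise(dplyr::group_by(fr, .data$patch),
                           f = mean(.data$value))
    fx <- setNames(fr$f, fr$patch)
    abs(fx[[hi]] - fx[[lo]]) >= 0.5
  }
}

#' Critical migration rate from a grid of runs
#'
#' The largest migration rate on the grid at which local adaptation is
#' maintained, where each (m, replicate) run votes via its `maintained`
#' flag and a rate counts as maintained when the majority of its replicates
#' are.
#'
#' @param results Data frame with columns `m` and logical `maintained`
#'   (one row per replicate).
#' @return The largest maintained `m`, `0` if only `m = 0` is maintained,
#'   or `NA` if none is.
#' @export
critical_migration <- function(results) {
  stopifnot(all(c("m", "maintained") %in% names(results)))
  by_m <- dplyr::summarise(dplyr::group_by(results, .data$m),
                           keep = mean(.data$maintained) > 0.5)
  kept <- by_m$m[by_m$keep]
  if (length(kept) == 0) return(NA_real_)
  max(kept)
}

#' Summarize segregating adaptive alleles per patch
#'
#' Continuum-of-alleles selected loci carry real-valued effects; alleles
#' are clustered into classes by rounding to `resolution` and per-patch
#' class frequencies are reported, together with the number of segregating
#' classes.
#'
#' @param state List of per-patch haplotype matrices.
#' @param map The `genetic_map`.
#' @param resolution Effect-size rounding step (default 0.05).
#' @return Tibble: `patch`, `locus_id`, `allele_class`, `freq`,
#'   `n_classes` (segregating classes at that locus in that patch).
#' @export
summarize_adaptive_alleles <- function(state, map, resolution = 0.05) {
  sel <- which(map$kind == "selected")
  out <- list()
  for (p in seq_along(state)) {
    for (s in sel) {
      cls <- round(state[[p]][, s] / resolution) * resolution
      tab <- table(cls) / length(cls)
      out[[length(out) + 1L]] <- tibble::tibble(
        patch = p, locus_id = map$locus_id[s],
        allele_class = as.numeric(names(tab)),
        freq = as.numeric(tab), n_classes = length(tab))
    }
  }
  dplyr::bind_rows(out)
}

#' Per-patch signature report at the final sampling point
#'
#' Combines the diversity-distance slope (for `pi_w` and `fst`), the
#' near/far contrast, and (when `background` is supplied) peak detection
#' and width into one row per patch.
#'
#' @param sim A `wf_sim` run with metrics.
#' @param background Optional genome-wide background diversity for peak
#'   detection.
#' @return Tibble with one row per patch: `patch`, `generation`,
#'   `dd_slope`, `slope_p`, `fst_slope`, `near_pi`, `far_pi`,
#'   `peak_detected`, `peak_width_cM`.
#' @export
signature_report <- function(sim, background = NULL) {
  stopifnot(inherits(sim, "wf_sim"), !is.null(sim$metrics))
  gmax <- max(sim$metrics$generation)
  fin <- dplyr::filter(sim$metrics, .data$generation == gmax,
                       .data$kind == "neutral")
  # fst is undefined at monomorphic loci; slopes need >= 3 informative loci
  safe_fit <- function(df) {
    if (sum(is.finite(df$value) & df$distance_cM > 0) < 3)
      return(list(slope = NA_real_, p_value = NA_real_))
    dd_slope(df, value)
  }
  fst <- dplyr::filter(fin, .data$metric == "fst")
  fst_sl <- safe_fit(fst)$slope
  patches <- sort(unique(fin$patch[fin$metric == "pi_w"]))
  purrr::map_dfr(patches, function(p) {
    pw <- dplyr::filter(fin, .data$metric == "pi_w", .data$patch == p)
    fit <- safe_fit(pw)
    nf <- near_far_contrast(pw, value)
    pk <- if (is.null(background) || !is.finite(fit$slope)) NULL
          else detect_peak(pw, background, value)
    tibble::tibble(
      patch = p, generation = gmax,
      dd_slope = fit$slope, slope_p = fit$p_value, fst_slope = fst_sl,
      near_pi = nf$near_pi, far_pi = nf$far_pi,
      peak_detected = if (is.null(pk)) NA else pk$peak_detected,
      peak_width_cM = if (is.null(pk) || !pk$peak_detected) NA_real_
                      else suppressWarnings(peak_width(pw, background, value)))
  })
}
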