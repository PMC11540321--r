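#' Build a genetic map of selected loci with log-spaced neutral flanks
#'
#' Each divergently selected locus sits at the centre of a "complement":
#' `n_flank_per_side` neutral loci on either side at map distances spaced
#' evenly on the log10 scale between `min_cM` and `max_cM`. Complements are
#' separated by `complement_gap_cM` so that, under the linear
#' centimorgan-to-recombination convention of [cm_to_recfrac()], loci in
#' different complements are completely unlinked (r = 0.5) at the default
#' 50 cM gap.
#'
#' @param n_selected Number of selected loci (one per complement).
#' @param n_flank_per_side Neutral loci per side of each selected locus
#'   (default 37, i.e. 74 flanking loci per complement).
#' @param min_cM,max_cM Closest and farthest flank distance in centimorgans.
#' @param complement_gap_cM Map gap between the outermost loci of adjacent
#'   complements.
#' @return A tibble of class `genetic_map` with columns `locus_id`, `kind`
#'   (`"selected"` or `"neutral"`), `complement_id`, `signed_distance_cM`
#'   (negative = left flank, 0 at the selected locus) and `position_cM`
#'   (absolute chromosome coordinate).
#' @examples
#' map <- build_flanking_map()
#' nrow(map)            # 75
#' range(abs(map$signed_distance_cM[map$kind == "neutral"]))
#' @export
build_flanking_map <- function(n_selected = 1L, n_flank_per_side = 37L,
                               min_cM = 1e-3, max_cM = 10,
                               complement_gap_cM = 50) {
  if (n_selected < 1) stop("n_selected must be >= 1")
  if (n_flank_per_side < 1) stop("n_flank_per_side must be >= 1")
  if (min_cM <= 0) stop("flank distances must be positive: min_cM = ", min_cM)
  if (max_cM < min_cM) stop("max_cM must be >= min_cM")
  if (max_cM > min_cM && n_flank_per_side == 1)
    stop("n_flank_per_side = 1 requires min_cM == max_cM")
  if (min_cM == max_cM && n_flank_per_side > 1)
    stop("min_cM == max_cM requires n_flank_per_side = 1")
  if (complement_gap_cM <= 0) stop("complement_gap_cM must be positive")

  dists <-
    if (n_flank_per_side == 1) max_cM
    else 10^seq(log10(min_cM), log10(max_cM), length.out = n_flank_per_side)
  signed <- c(-rev(dists), 0, dists)
  kind <- c(rep("neutral", n_flank_per_side), "selected",
            rep("neutral", n_flank_per_side))
  span <- 2 * max_cM + complement_gap_cM

  per <- length(signed)
  map <- tibble::tibble(
    locus_id = seq_len(per * n_selected),
    kind = rep(kind, n_selected),
    complement_id = rep(seq_len(n_selected), each = per),
    signed_distance_cM = rep(signed, n_selected),
    position_cM = rep(signed, n_selected) + max_cM +
      (rep(seq_len(n_selected), each = per) - 1) * span
  )
  new_genetic_map(map)
}

new_genetic_map <- function(map) {
  stopifnot(all(diff(map$position_cM) > 0))
  class(map) <- c("genetic_map", class(tibble::tibble()))
  map
}

#' Add evenly spaced background neutral loci 9-10 cM from the selected locus
#'
#' Used for background-diversity calibration: extra neutral loci are placed
#' at linear even steps between 9 and 10 cM on either side of the (single)
#' selected locus, so that each side carries exactly `n_per_side` loci in
#' the 9-10 cM band. Added positions colliding with existing loci are
#' dropped (the existing locus is kept), and locus ids are reassigned in
#' map order.
#'
#' @param map A single-complement [build_flanking_map()] map.
#' @param n_per_side Loci per side spanning 9 to 10 cM in even steps.
#' @return A `genetic_map` tibble.
#' @export
add_background_loci <- function(map, n_per_side = 100L) {
  stopifnot(inherits(map, "genetic_map"))
  if (max(map$complement_id) != 1L)
    stop("background loci are only supported for single-complement maps")
  if (n_per_side == 0L) return(map)
  if (n_per_side < 0L) stop("n_per_side must be >= 0")

  dists <- if (n_per_side == 1L) 9 else seq(9, 10, length.out = n_per_side)
  signed_new <- c(-rev(dists), dists)
  # dedupe against existing positions (keep existing)
  keep <- !vapply(signed_new, function(s)
    any(abs(map$signed_distance_cM - s) < 1e-9), logical(1))
  signed_new <- signed_new[keep]

  sel_pos <- map$position_cM[map$kind == "selected"]
  add <- tibble::tibble(
    locus_id = NA_integer_,
    kind = "neutral",
    complement_id = 1L,
    signed_distance_cM = signed_new,
    position_cM = sel_pos + signed_new
  )
  out <- dplyr::arrange(dplyr::bind_rows(map, add), .data$position_cM)
  out$locus_id <- seq_len(nrow(out))
  new_genetic_map(out)
}

#' Convert a map distance in centimorgans to a recombination fraction
#'
#' The engine treats each adjacent-locus interval independently (no
#' interference, no map function): `r = min(d_cM / 100, 0.5)`. This linear
#' convention makes a 50 cM gap fully unlinked (r = 0.5), which is how the
#' complement spacing is meant to behave; Haldane's map function would not
#' reach 0.5 at any finite distance.
#'
#' @param d_cM Non-negative distance(s) in centimorgans.
#' @return Recombination fraction(s) in \[0, 0.5\].
#' @export
cm_to_recfrac <- function(d_cM) {
  if (any(d_cM < 0)) stop("distances must be non-negative")
  pmin(d_cM / 100, 0.5)
}

#' Per-interval recombination fractions of a genetic map
#'
#' @param map A `genetic_map`.
#' @return Numeric vector of length `nrow(map) - 1`.
#' @export
rec_fractions <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  cm_to_recfrac(diff(map$position_cM))
}

#' Write / read a genetic map as a 4-column TSV
#'
#' Columns: `locus_id`, `kind`, `complement_id`, `signed_distance_cM`, with
#' a header line. Absolute positions are reconstructed on read from the
#' signed distances and the complement gap.
#'
#' @param map A `genetic_map`.
#' @param path File path.
#' @param complement_gap_cM Gap used to reconstruct positions on read.
#' @return `write_genetic_map()` returns `path` invisibly;
#'   `read_genetic_map()` returns a `genetic_map`.
#' @export
write_genetic_map <- function(map, path) {
  stopifnot(inherits(map, "genetic_map"))
  readr::write_tsv(map[c("locus_id", "kind", "complement_id",
                         "signed_distance_cM")], path)
  invisible(path)
}

#' @rdname write_genetic_map
#' @export
read_genetic_map <- function(path, complement_gap_cM = 50) {
  map <- readr::read_tsv(path, col_types = readr::cols(
    locus_id = readr::col_integer(),
    kind = readr::col_character(),
    complement_id = readr::col_integer(),
    signed_distance_cM = readr::col_double()
  ))
  max_cM <- max(abs(map$signed_distance_cM))
  span <- 2 * max_cM + complement_gap_cM
  map$position_cM <- map$signed_distance_cM + max_cM +
    (map$complement_id - 1) * span
  new_genetic_map(map)
}
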