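#' Export a diallelic snapshot as VCF
#'
#' Writes the diallelic loci of a metapopulation state (all neutral loci,
#' plus selected loci under the diallelic models) as a minimal VCF 4.2 file
#' with haploid-phased diploid GT records, for cross-checking against
#' external population-genetics tooling. Continuum-of-alleles selected loci
#' are skipped. Map positions (cM) are scaled to integer coordinates at
#' 1e6 units per cM.
#'
#' @param state List of per-patch haplotype matrices.
#' @param map The `genetic_map`.
#' @param path Output file (plain text).
#' @param chrom Chromosome name.
#' @return `path`, invisibly.
#' @export
write_snapshot_vcf <- function(state, map, path, chrom = "1") {
  keep <- vapply(seq_len(nrow(map)), function(l) {
    vals <- unique(unlist(lapply(state, function(h) h[, l])))
    length(vals) <= 2
  }, logical(1))
  idx <- which(keep)
  ids <- unlist(lapply(seq_along(state), function(p)
    sprintf("p%d_i%d", p, seq_len(nrow(state[[p]]) / 2))))
  pos <- as.integer(round(map$position_cM[idx] * 1e6)) + 1L
  pos <- pos + cumsum(c(0L, as.integer(diff(pos) <= 0L)))  # force increasing

  header <- c("##fileformat=VCFv4.2",
              "##source=ladsim",
              sprintf("##contig=<ID=%s>", chrom),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", ids), collapse = "\t"))
  body <- vapply(seq_along(idx), function(k) {
    l <- idx[k]
    vals <- sort(unique(unlist(lapply(state, function(h) h[, l]))))
    ref_val <- vals[1]
    gt <- unlist(lapply(state, function(h) {
      g <- as.integer(h[, l] != ref_val)
      paste(g[seq(1, length(g), 2)], g[seq(2, length(g), 2)], sep = "|")
    }))
    paste(c(chrom, pos[k], sprintf("locus%d", map$locus_id[l]), "A", "T",
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
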