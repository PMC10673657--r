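# GFF3/BED export of called loci and phasiRNAs via rtracklayer.

loci_granges <- function(loci, phasirnas = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = loci$contig,
    ranges = IRanges::IRanges(loci$start, loci$end),
    strand = "*")
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = "siRNA_locus", ID = loci$name, cycle = loci$cycle,
    pvalue = loci$pvalue, p_adjusted = loci$p_adjusted,
    phase_score = loci$max_phase_score)
  if (!is.null(phasirnas) && nrow(phasirnas)) {
    ps <- GenomicRanges::GRanges(
      seqnames = loci$contig[match(phasirnas$locus, loci$name)],
      ranges = IRanges::IRanges(phasirnas$position,
                                width = phasirnas$length),
      strand = phasirnas$strand)
    S4Vectors::mcols(ps) <- S4Vectors::DataFrame(
      type = "siRNA", ID = phasirnas$name, Parent = phasirnas$locus,
      cycle = phasirnas$length, pvalue = NA_real_, p_adjusted = NA_real_,
      phase_score = NA_real_)
    gr <- c(gr, ps)
  }
  gr
}

#' Export called loci (and optionally their phasiRNAs) as GFF3
#'
#' Loci are written as `siRNA_locus` features with `siRNA` children;
#' coordinates stay 1-based as GFF3 requires.
#'
#' @param loci called-locus data frame.
#' @param path output file.
#' @param phasirnas optional phasiRNA data frame.
#' @export
export_loci_gff3 <- function(loci, path, phasirnas = NULL) {
  gr <- loci_granges(loci, phasirnas)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Export called loci as BED6 (0-based half-open, as BED requires)
#'
#' @param loci called-locus data frame.
#' @param path output file.
#' @export
export_loci_bed <- function(loci, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = loci$contig,
    ranges = IRanges::IRanges(loci$start, loci$end), strand = "*")
  score <- pmin(1000, round(loci$max_phase_score * 100))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(name = loci$name,
                                               score = score)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write phasiRNAs as FASTA
#'
#' @param phasirnas phasiRNA data frame.
#' @param path output file.
#' @export
write_phasirna_fasta <- function(phasirnas, path) {
  x <- Biostrings::DNAStringSet(phasirnas$sequence)
  names(x) <- phasirnas$name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
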