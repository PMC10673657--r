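# internal helpers shared across modules

#' Reverse complement of character sequences
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Uppercase and normalise U -> T. Returns NA for sequences containing
# characters outside A/C/G/T/U/N so callers can warn and drop them.
normalize_seq <- function(x) {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGTN]", x)
  x[bad] <- NA_character_
  x
}

# substring of a named character genome, 1-based inclusive
genome_substr <- function(genome, contig, start, end) {
  substr(genome[[contig]], start, end)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rbind a list of data frames, dropping NULLs; NULL when nothing remains
rbind_all <- function(lst) {
  lst <- Filter(Negate(is.null), lst)
  if (length(lst) == 0L) return(NULL)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}

# deterministic row order for data frames written to disk
sort_df <- function(df, cols) {
  if (nrow(df) == 0L) return(df)
  df[do.call(order, unname(df[cols])), , drop = FALSE]
}

as_chr_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    stats::setNames(as.character(genome), names(genome))
  } else if (is.character(genome)) {
    genome
  } else {
    stop("genome must be a DNAStringSet or a named character vector")
  }
}
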