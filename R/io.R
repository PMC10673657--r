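# Readers/writers and read-level preprocessing: collapsing, length
# selection, repeat filtering, collapsed-FASTA and degradome-table I/O,
# and SAM/BAM alignment import.

#' Collapse raw reads into unique sequences with per-library counts
#'
#' Each distinct sequence becomes one row; per-library counts are summed.
#' Sequences are uppercased and U is normalised to T. Reads containing
#' characters outside A/C/G/T/U/N are dropped with a warning.
#'
#' @param libraries named list; each element is either a character vector of
#'   raw read sequences (one entry per read) or a data frame with columns
#'   `sequence` and `count` (already-collapsed input).
#' @return data frame with columns `sequence`, `length`, one count column
#'   per library (named as in `libraries`), and `total_count`; rows sorted
#'   by sequence so the result is order-independent. The library names are
#'   kept in `attr(, "libraries")`.
#' @examples
#' collapse_reads(list(lib1 = c("ACGTACGTACGTACGTACGTA", "ACGTACGTACGTACGTACGTA")))
#' @export
collapse_reads <- function(libraries) {
  stopifnot(is.list(libraries), !is.null(names(libraries)))
  libs <- names(libraries)
  tabs <- lapply(libs, function(lib) {
    x <- libraries[[lib]]
    if (is.data.frame(x)) {
      seqs <- normalize_seq(x$sequence); cnt <- as.numeric(x$count)
    } else {
      seqs <- normalize_seq(x); cnt <- rep(1, length(x))
    }
    bad <- is.na(seqs)
    if (any(bad)) {
      warning(sum(bad), " read(s) with non-ACGTUN characters dropped from ",
              lib, call. = FALSE)
      seqs <- seqs[!bad]; cnt <- cnt[!bad]
    }
    if (length(seqs) == 0L) return(NULL)
    agg <- rowsum(cnt, seqs)
    data.frame(sequence = rownames(agg), lib = lib, count = agg[, 1L])
  })
  tabs <- rbind_all(tabs)
  all_seq <- sort(unique(tabs$sequence))
  counts <- matrix(0, nrow = length(all_seq), ncol = length(libs),
                   dimnames = list(NULL, libs))
  if (!is.null(tabs) && nrow(tabs)) {
    counts[cbind(match(tabs$sequence, all_seq), match(tabs$lib, libs))] <-
      tabs$count
  }
  out <- data.frame(sequence = all_seq, length = nchar(all_seq))
  for (lib in libs) out[[lib]] <- counts[, lib]
  out$total_count <- rowSums(counts)
  attr(out, "libraries") <- libs
  out
}

#' Keep reads of selected lengths
#'
#' @param reads a collapsed-read data frame from [collapse_reads()].
#' @param lengths integer vector of lengths to keep (within 15..35).
#' @return the subset of `reads` with `length %in% lengths`.
#' @export
select_lengths <- function(reads, lengths = c(21L, 24L)) {
  stopifnot(all(lengths >= 15L), all(lengths <= 35L))
  out <- reads[reads$length %in% as.integer(lengths), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "libraries") <- attr(reads, "libraries")
  out
}

#' Remove reads matching a repeat database
#'
#' Drops every read whose sequence, or its reverse complement, occurs as an
#' exact full-length substring of any repeat sequence. Matching is exact and
#' strand-symmetric; survivors are returned unchanged.
#'
#' @param reads collapsed-read data frame.
#' @param repeats repeat sequences: a `DNAStringSet`, named character vector,
#'   or path to a FASTA file.
#' @return the retained subset of `reads`.
#' @export
filter_repeat_reads <- function(reads, repeats) {
  if (is.character(repeats) && length(repeats) == 1L && file.exists(repeats))
    repeats <- Biostrings::readDNAStringSet(repeats)
  if (!methods::is(repeats, "DNAStringSet"))
    repeats <- Biostrings::DNAStringSet(as.character(repeats))
  if (length(repeats) == 0L || nrow(reads) == 0L) {
    if (length(repeats) == 0L)
      warning("empty repeat set: no reads filtered", call. = FALSE)
    return(reads)
  }
  subj <- c(repeats, Biostrings::reverseComplement(repeats))
  hit <- logical(nrow(reads))
  for (len in unique(reads$length)) {
    sel <- which(reads$length == len)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(reads$sequence[sel]))
    counts <- Biostrings::vcountPDict(pd, subj)   # reads x repeats
    hit[sel] <- rowSums(counts) > 0L
  }
  out <- reads[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "libraries") <- attr(reads, "libraries")
  out
}

#' Map reads to a genome by exact full-length matching
#'
#' Reports every exact, ungapped, full-length placement of each read on both
#' strands. Minus-strand placements (the reverse complement matches the plus
#' strand) are recorded by their leftmost plus-strand coordinate, the
#' convention used throughout the package.
#'
#' @param reads collapsed-read data frame (see [collapse_reads()]).
#' @param genome a `DNAStringSet` or named character vector of contigs.
#' @return placement data frame: `sequence`, `contig`, `start`, `end`,
#'   `strand`, `length`, `count` (the read's pooled total count).
#' @export
map_reads <- function(reads, genome) {
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(as_chr_genome(genome))
  stopifnot(length(genome) > 0L)
  empty <- data.frame(sequence = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), length = integer(0),
                      count = numeric(0))
  if (nrow(reads) == 0L) return(empty)
  out <- list()
  for (len in sort(unique(reads$length))) {
    sub <- reads[reads$length == len, , drop = FALSE]
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(sub$sequence))
    for (ci in seq_along(genome)) {
      ctg <- names(genome)[ci]
      clen <- Biostrings::width(genome)[ci]
      for (str in c("+", "-")) {
        subj <- if (str == "+") genome[[ci]] else
          Biostrings::reverseComplement(genome[[ci]])
        m <- Biostrings::matchPDict(pd, subj)
        starts <- BiocGenerics::start(m)
        nhits <- S4Vectors::elementNROWS(starts)
        if (sum(nhits) == 0L) next
        idx <- rep(seq_along(nhits), nhits)
        st <- unlist(starts, use.names = FALSE)
        if (str == "-") st <- clen - (st + len - 1L) + 1L
        out[[length(out) + 1L]] <- data.frame(
          sequence = sub$sequence[idx], contig = ctg, start = as.integer(st),
          end = as.integer(st + len - 1L), strand = str, length = len,
          count = sub$total_count[idx])
      }
    }
  }
  out <- rbind_all(out)
  if (is.null(out)) return(empty)
  sort_df(out, c("contig", "start", "strand", "sequence"))
}

#' Import read placements from a SAM or BAM file
#'
#' Keeps only ungapped, full-length, mismatch-free placements (CIGAR
#' `<len>M` and, when present, `NM:i:0`); everything else is dropped and
#' counted in a message. Reads collapsed-FASTA style query names
#' (`<id>_x<count>`) to recover abundances; a query without the `_x` suffix
#' gets count 1. BAM files require the Rsamtools package.
#'
#' @param path SAM (plain text) or BAM file.
#' @return placement data frame as from [map_reads()].
#' @export
read_alignments <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
      stop("Rsamtools is required to read BAM files")
    b <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
      tag = "NM"))[[1L]]
    df <- data.frame(qname = b$qname, flag = b$flag,
                     rname = as.character(b$rname), pos = b$pos,
                     cigar = b$cigar, seq = as.character(b$seq),
                     nm = b$tag$NM %||% rep(NA_integer_, length(b$qname)))
  } else {
    lines <- readLines(path)
    lineno <- which(!startsWith(lines, "@"))
    lines <- lines[lineno]
    if (length(lines) == 0L) {
      return(data.frame(sequence = character(0), contig = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), length = integer(0),
                        count = numeric(0)))
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 11L))
      stop("malformed SAM record at line ", lineno[which(nf < 11L)[1L]])
    nm <- vapply(fields, function(f) {
      tag <- grep("^NM:i:", f[-(1:11)], value = TRUE)
      if (length(tag)) as.integer(sub("^NM:i:", "", tag[1L])) else NA_integer_
    }, integer(1L))
    df <- data.frame(
      qname = vapply(fields, `[`, "", 1L),
      flag = as.integer(vapply(fields, `[`, "", 2L)),
      rname = vapply(fields, `[`, "", 3L),
      pos = as.integer(vapply(fields, `[`, "", 4L)),
      cigar = vapply(fields, `[`, "", 6L),
      seq = vapply(fields, `[`, "", 10L),
      nm = nm)
  }
  df <- df[!bitwAnd(df$flag, 4L), , drop = FALSE]    # mapped only
  len <- nchar(df$seq)
  ok <- df$cigar == paste0(len, "M") & (is.na(df$nm) | df$nm == 0L)
  if (any(!ok))
    message(sum(!ok), " placement(s) dropped (gapped, clipped or mismatched)")
  df <- df[ok, , drop = FALSE]; len <- len[ok]
  minus <- bitwAnd(df$flag, 16L) > 0L
  seqs <- ifelse(minus, revcomp(df$seq), df$seq)   # read as sequenced
  count <- ifelse(grepl("_x\\d+$", df$qname),
                  as.numeric(sub(".*_x(\\d+)$", "\\1", df$qname)), 1)
  out <- data.frame(sequence = seqs, contig = df$rname,
                    start = df$pos, end = df$pos + len - 1L,
                    strand = ifelse(minus, "-", "+"),
                    length = len, count = count)
  sort_df(out, c("contig", "start", "strand", "sequence"))
}

#' Write collapsed reads as FASTA
#'
#' Headers follow the de-facto sRNA convention `><id>_x<count>` with the
#' pooled total count. One file per call; per-library counts can be written
#' by passing `library` to select a single column.
#'
#' @param reads collapsed-read data frame.
#' @param path output FASTA path.
#' @param library optional library id; its column is used as the count
#'   (rows with zero count are skipped). Default: pooled `total_count`.
#' @export
write_collapsed_fasta <- function(reads, path, library = NULL) {
  cnt <- if (is.null(library)) reads$total_count else reads[[library]]
  keep <- cnt > 0
  seqs <- reads$sequence[keep]; cnt <- cnt[keep]
  ids <- sprintf("r%06d_x%d", seq_along(seqs), as.integer(cnt))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a collapsed FASTA (`><id>_x<count>` headers)
#'
#' @param path collapsed FASTA file.
#' @param library library id to assign the counts to (default: file name).
#' @return collapsed-read data frame as from [collapse_reads()].
#' @export
read_collapsed_fasta <- function(path, library = NULL) {
  lib <- library %||% sub("\\.(fa|fasta)$", "", basename(path))
  x <- Biostrings::readDNAStringSet(path)
  cnt <- suppressWarnings(as.numeric(sub(".*_x(\\d+)\\s*$", "\\1", names(x))))
  if (anyNA(cnt))
    stop("header(s) without _x<count> suffix in ", path)
  df <- data.frame(sequence = as.character(x), count = cnt)
  collapse_reads(stats::setNames(list(df), lib))
}

#' Read a degradome 5'-end table
#'
#' The table has columns `library`, `transcript`, `pos` (1-based 5' end of
#' the degradome read on the transcript) and `count`.
#'
#' @param path TSV file.
#' @return named list of per-library profiles, each a data frame
#'   `transcript`, `pos`, `count`.
#' @export
read_degradome <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("library", "transcript", "pos", "count")
  if (!all(need %in% names(df)))
    stop("degradome table must have columns: ", paste(need, collapse = ", "))
  lapply(split(df[c("transcript", "pos", "count")], df$library), function(x) {
    rownames(x) <- NULL; x
  })
}

#' @rdname read_degradome
#' @param profiles named list of per-library profiles.
#' @export
write_degradome <- function(profiles, path) {
  df <- rbind_all(lapply(names(profiles), function(lib) {
    cbind(library = lib, profiles[[lib]])
  }))
  df <- sort_df(df, c("library", "transcript", "pos"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
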