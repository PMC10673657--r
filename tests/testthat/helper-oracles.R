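# Independent oracles and fixture builders used across the suite.

# Combinatorial enumeration of the hypergeometric upper tail: among all
# C(N, n) equally likely occupancy patterns of n slots, the fraction with
# at least k of the K in-register slots occupied.
oracle_hyper_tail <- function(n, k, N, K) {
  if (k <= 0) return(1)
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Literal pattern enumeration for tiny n: every subset of n slots out of N.
oracle_hyper_enum <- function(n, k, N, K) {
  if (k <= 0) return(1)
  if (n == 0) return(0)
  pats <- utils::combn(N, n)
  mean(colSums(pats <= K) >= k)   # slots 1..K are the in-register ones
}

# Sliding-window exact mapper: all full-length exact placements of each
# read on both strands of a character genome.
naive_map <- function(reads, genome) {
  out <- list()
  for (s in reads$sequence) {
    L <- nchar(s)
    rc <- revcomp(s)
    for (ctg in names(genome)) {
      g <- genome[[ctg]]
      for (st in seq_len(max(0L, nchar(g) - L + 1L))) {
        sub <- substr(g, st, st + L - 1L)
        if (sub == s)
          out[[length(out) + 1L]] <- data.frame(
            sequence = s, contig = ctg, start = st, strand = "+")
        if (sub == rc)
          out[[length(out) + 1L]] <- data.frame(
            sequence = s, contig = ctg, start = st, strand = "-")
      }
    }
  }
  df <- do.call(rbind, out)
  if (is.null(df)) {
    return(data.frame(sequence = character(0), contig = character(0),
                      start = integer(0), strand = character(0)))
  }
  df[order(df$contig, df$start, df$strand, df$sequence), , drop = FALSE]
}

# All-offsets ungapped antiparallel site search (Hamming on the reverse
# complement), the brute-force counterpart of find_binding_sites.
naive_sites <- function(srna, transcript, max_mm) {
  pat <- strsplit(revcomp(srna), "")[[1L]]
  L <- length(pat)
  out <- list()
  for (st in seq_len(max(0L, nchar(transcript) - L + 1L))) {
    sub <- strsplit(substr(transcript, st, st + L - 1L), "")[[1L]]
    mm <- sum(pat != sub)
    if (mm <= max_mm)
      out[[length(out) + 1L]] <- data.frame(t_start = st,
                                            t_end = st + L - 1L,
                                            mismatches = mm)
  }
  df <- do.call(rbind, out)
  if (is.null(df)) {
    return(data.frame(t_start = integer(0), t_end = integer(0),
                      mismatches = numeric(0)))
  }
  df
}

# brute-force mismatch scan at every offset and strand
naive_tasiarf <- function(tseq, genome, max_mm) {
  out <- list()
  L <- nchar(tseq)
  for (ctg in names(genome)) {
    g <- genome[[ctg]]
    for (str in c("+", "-")) {
      pat <- strsplit(if (str == "+") tseq else revcomp(tseq), "")[[1L]]
      for (st in seq_len(max(0L, nchar(g) - L + 1L))) {
        mm <- sum(pat != strsplit(substr(g, st, st + L - 1L), "")[[1L]])
        if (mm <= max_mm)
          out[[length(out) + 1L]] <- data.frame(
            contig = ctg, match_start = st, strand = str, mismatches = mm)
      }
    }
  }
  df <- do.call(rbind, out)
  if (is.null(df)) {
    return(data.frame(contig = character(0), match_start = integer(0),
                      strand = character(0), mismatches = numeric(0)))
  }
  df[order(df$contig, df$match_start, df$strand), , drop = FALSE]
}

# placements data frame for a perfectly phased plus-strand locus
phased_placements <- function(anchor = 1001L, cycle = 21L, n_cycles = 10L,
                              contig = "chr1", count = 5,
                              duplex = FALSE) {
  pos <- anchor + cycle * (seq_len(n_cycles) - 1L)
  plus <- data.frame(sequence = sprintf("P%03d", seq_along(pos)),
                     contig = contig, start = pos,
                     end = pos + cycle - 1L, strand = "+",
                     length = cycle, count = count)
  if (!duplex) return(plus)
  minus <- data.frame(sequence = sprintf("M%03d", seq_along(pos)),
                      contig = contig, start = pos - 2L,
                      end = pos + cycle - 3L, strand = "-",
                      length = cycle, count = count)
  rbind(plus, minus)
}

# uniform random single-count placements on one contig
uniform_placements <- function(n, contig_len, cycle = 21L,
                               contig = "chr1") {
  st <- sample.int(contig_len - cycle + 1L, n, replace = TRUE)
  data.frame(sequence = sprintf("U%05d", seq_len(n)), contig = contig,
             start = st, end = st + cycle - 1L,
             strand = sample(c("+", "-"), n, replace = TRUE),
             length = cycle, count = 1)
}

rand_dna_test <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
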