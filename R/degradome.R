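# SeqTar-style binding-site search and degradome (PARE) validation,
# used both for miRNA triggers of PHAS loci and for phasiRNA targets.

# Weighted mismatch count of an sRNA against transcript[t_start..t_end].
# Pairing is antiparallel: sRNA position i pairs transcript position
# t_end - i + 1, so a perfect site equals reverseComplement(srna).
# With gu_half, G:U wobbles (sRNA G vs target T, or sRNA U vs target G;
# i.e. pattern C/subject T and pattern A/subject G after complementing)
# weigh 0.5 instead of 1.
site_mismatches <- function(pattern_chars, subject_chars, gu_half = FALSE) {
  diff <- pattern_chars != subject_chars
  if (!gu_half) return(sum(diff))
  wob <- (pattern_chars == "C" & subject_chars == "T") |
    (pattern_chars == "A" & subject_chars == "G")
  sum(diff & !wob) + 0.5 * sum(diff & wob)
}

#' Find sRNA binding sites on transcripts
#'
#' Exhaustive ungapped antiparallel alignment of an sRNA against every
#' offset of each transcript; sites with at most `max_mismatches`
#' mismatches are reported. The inferred cleavage position is the
#' transcript nucleotide opposite sRNA position 10, i.e. `t_end - 9`.
#' G:U wobbles count as full mismatches by default; `gu_half = TRUE`
#' down-weights them to 0.5 (exploratory mode).
#'
#' @param srna named character vector of sRNA sequences (DNA or RNA
#'   alphabet), typically length-1; names label the output.
#' @param transcripts `DNAStringSet` or named character vector.
#' @param max_mismatches maximum (weighted) mismatch count (default 4).
#' @param gu_half logical; half-weight G:U wobbles (default FALSE).
#' @return data frame: `srna`, `transcript`, `t_start`, `t_end`,
#'   `mismatches`, `cleavage_pos`.
#' @export
find_binding_sites <- function(srna, transcripts, max_mismatches = 4,
                               gu_half = FALSE) {
  tx <- if (methods::is(transcripts, "DNAStringSet"))
    stats::setNames(as.character(transcripts), names(transcripts))
  else as_chr_genome(transcripts)
  if (is.null(names(srna))) names(srna) <- paste0("srna", seq_along(srna))
  empty <- data.frame(srna = character(0), transcript = character(0),
                      t_start = integer(0), t_end = integer(0),
                      mismatches = numeric(0), cleavage_pos = integer(0))
  out <- list()
  for (sn in names(srna)) {
    s <- normalize_seq(srna[[sn]])
    L <- nchar(s)
    pat <- revcomp(s)
    pat_chars <- strsplit(pat, "")[[1L]]
    # full mismatches can reach 2x the weighted bound in wobble mode
    search_mm <- if (gu_half) ceiling(2 * max_mismatches) else max_mismatches
    for (tn in names(tx)) {
      tseq <- tx[[tn]]
      if (nchar(tseq) < L) next
      if (search_mm >= L) {          # every offset is a candidate
        st <- seq_len(nchar(tseq) - L + 1L)
      } else {
        m <- Biostrings::matchPattern(pat, Biostrings::DNAString(tseq),
                                      max.mismatch = search_mm)
        if (length(m) == 0L) next
        st <- BiocGenerics::start(m)
        st <- st[st >= 1L & st + L - 1L <= nchar(tseq)]
      }
      if (length(st) == 0L) next
      mm <- vapply(st, function(p) {
        site_mismatches(pat_chars,
                        strsplit(substr(tseq, p, p + L - 1L), "")[[1L]],
                        gu_half)
      }, numeric(1L))
      keep <- mm <= max_mismatches
      if (!any(keep)) next
      out[[length(out) + 1L]] <- data.frame(
        srna = sn, transcript = tn, t_start = st[keep],
        t_end = st[keep] + L - 1L, mismatches = mm[keep],
        cleavage_pos = st[keep] + L - 1L - 9L)
    }
  }
  res <- rbind_all(out)
  if (is.null(res)) return(empty)
  sort_df(res, c("srna", "transcript", "t_start"))
}

#' Count degradome valid reads at binding sites
#'
#' A valid read has its 5' end at one of the three transcript positions
#' opposite sRNA positions 9-11 of the site, i.e.
#' `{t_end - 10, t_end - 9, t_end - 8}`. Adds one `valid_<library>` column
#' per degradome profile, their sum `valid_reads`, and
#' `total_reads_at_site` (reads with 5' end anywhere inside the site).
#'
#' @param sites binding-site data frame from [find_binding_sites()].
#' @param profiles named list of degradome profiles (see
#'   [read_degradome()]).
#' @return `sites` with valid-read columns and a `category` column:
#'   `valid_read_supported`, `low_mismatch_only` (< 4 mismatches), `both`,
#'   or `none`.
#' @export
count_valid_reads <- function(sites, profiles) {
  if (nrow(sites) == 0L) {
    for (lib in names(profiles)) sites[[paste0("valid_", lib)]] <- numeric(0)
    sites$valid_reads <- numeric(0)
    sites$total_reads_at_site <- numeric(0)
    sites$category <- character(0)
    return(sites)
  }
  for (lib in names(profiles)) {
    pr <- profiles[[lib]]
    sites[[paste0("valid_", lib)]] <- vapply(seq_len(nrow(sites)),
      function(i) {
        e <- sites$t_end[i]
        sum(pr$count[pr$transcript == sites$transcript[i] &
                       pr$pos >= e - 10L & pr$pos <= e - 8L])
      }, numeric(1L))
  }
  vcols <- paste0("valid_", names(profiles))
  sites$valid_reads <- if (length(vcols))
    rowSums(sites[, vcols, drop = FALSE]) else 0
  allpr <- rbind_all(unname(profiles))
  sites$total_reads_at_site <- vapply(seq_len(nrow(sites)), function(i) {
    if (is.null(allpr)) return(0)
    sum(allpr$count[allpr$transcript == sites$transcript[i] &
                      allpr$pos >= sites$t_start[i] &
                      allpr$pos <= sites$t_end[i]])
  }, numeric(1L))
  vr <- sites$valid_reads >= 1
  lm <- sites$mismatches < 4
  sites$category <- ifelse(vr & lm, "both",
                           ifelse(vr, "valid_read_supported",
                                  ifelse(lm, "low_mismatch_only", "none")))
  sites
}

#' Retention policies for degradome-supported sites
#'
#' Two rules are used in PHAS analyses and differ deliberately:
#' * `trigger_rule`: >= 1 valid read in any profile OR fewer than 4
#'   mismatches (miRNA triggers of PHAS loci);
#' * `target_rule`: (>= 1 valid read in any profile AND <= 4 mismatches)
#'   OR 0 mismatches (phasiRNA targets).
#'
#' @param valid_reads numeric vector of summed valid reads across profiles.
#' @param mismatches numeric vector of site mismatch counts.
#' @return logical vector of retained sites.
#' @export
trigger_rule <- function(valid_reads, mismatches) {
  valid_reads >= 1 | mismatches < 4
}

#' @rdname trigger_rule
#' @export
target_rule <- function(valid_reads, mismatches) {
  (valid_reads >= 1 & mismatches <= 4) | mismatches == 0
}

#' Identify candidate miRNA triggers of PHAS loci
#'
#' Searches every miRNA against the precursor transcripts overlapping each
#' called locus, scores sites with degradome valid reads, and measures how
#' the inferred cleavage position relates to the locus phase register: the
#' distance to the nearest occupied in-register effective position, and the
#' register offset (`0` means the cleavage sets the phase). Sites are
#' retained under the trigger rule (>= 1 valid read OR < 4 mismatches);
#' the best site per (miRNA, locus) is reported (fewest mismatches, then
#' most valid reads).
#'
#' @param mirnas named character vector of miRNA sequences.
#' @param loci called-locus data frame (see [call_loci()]).
#' @param transcripts transcript sequences (`DNAStringSet` or named
#'   character).
#' @param transcript_map data frame mapping transcripts to the genome:
#'   columns `transcript`, `contig`, `g_start`, `g_end` (plus strand).
#' @param placements placement data frame (for occupied register
#'   positions).
#' @param profiles named list of degradome profiles.
#' @param params [phase_params()] of the locus cycle class.
#' @param max_mismatches search ceiling (default 5, so that
#'   valid-read-supported sites beyond the mismatch rule remain visible).
#' @return trigger table: site columns plus `locus`, `cleavage_genomic`,
#'   `dist_to_register`, `register_offset`, `retained`.
#' @export
select_trigger_candidates <- function(mirnas, loci, transcripts,
                                      transcript_map, placements, profiles,
                                      params, max_mismatches = 5) {
  empty <- data.frame(srna = character(0), transcript = character(0),
                      locus = character(0), t_start = integer(0),
                      t_end = integer(0), mismatches = numeric(0),
                      cleavage_pos = integer(0),
                      cleavage_genomic = integer(0),
                      dist_to_register = integer(0),
                      register_offset = integer(0),
                      valid_reads = numeric(0), retained = logical(0))
  if (nrow(loci) == 0L || length(mirnas) == 0L) return(empty)
  tx <- if (methods::is(transcripts, "DNAStringSet"))
    stats::setNames(as.character(transcripts), names(transcripts))
  else as_chr_genome(transcripts)
  pl <- placements[placements$length == params$cycle, , drop = FALSE]
  eff_all <- effective_position(pl$start, pl$strand)
  out <- list()
  for (li in seq_len(nrow(loci))) {
    loc <- loci[li, , drop = FALSE]
    tm <- transcript_map[transcript_map$contig == loc$contig &
                           transcript_map$g_start <= loc$end &
                           transcript_map$g_end >= loc$start, , drop = FALSE]
    if (nrow(tm) == 0L) next
    # loci are unstranded genomic intervals: search both orientations of
    # each precursor; degradome profiles are sense-only, so antisense
    # sites can only be retained through the mismatch clause
    tx_fwd <- tx[tm$transcript]
    tx_rev <- stats::setNames(revcomp(tx_fwd),
                              paste0(tm$transcript, "|-"))
    sites <- find_binding_sites(mirnas, c(tx_fwd, tx_rev),
                                max_mismatches = max_mismatches)
    if (nrow(sites) == 0L) next
    sites <- count_valid_reads(sites, profiles)
    antis <- grepl("\\|-$", sites$transcript)
    base_tx <- sub("\\|-$", "", sites$transcript)
    mi <- match(base_tx, tm$transcript)
    g0 <- tm$g_start[mi]
    txlen <- nchar(tx[base_tx])
    sense_pos <- ifelse(antis, txlen - sites$cleavage_pos + 1L,
                        sites$cleavage_pos)
    sites$site_strand <- ifelse(antis, "-", "+")
    sites$cleavage_genomic <- as.integer(g0 + sense_pos - 1L)
    reg_pos <- sort(unique(eff_all[pl$contig == loc$contig &
                                     eff_all >= loc$start &
                                     eff_all <= loc$end &
                                     (eff_all - loc$anchor) %% params$cycle == 0L]))
    sites$dist_to_register <- if (length(reg_pos))
      vapply(sites$cleavage_genomic,
             function(g) min(abs(g - reg_pos)), numeric(1L))
    else NA_real_
    sites$register_offset <- (sites$cleavage_genomic - loc$anchor) %%
      params$cycle
    sites$locus <- loc$name
    # best site per miRNA: fewest mismatches, then most valid reads
    sites <- sites[order(sites$srna, sites$mismatches, -sites$valid_reads,
                         sites$t_start), , drop = FALSE]
    sites <- sites[!duplicated(sites$srna), , drop = FALSE]
    sites$retained <- trigger_rule(sites$valid_reads, sites$mismatches)
    out[[length(out) + 1L]] <- sites
  }
  res <- rbind_all(out)
  if (is.null(res)) return(empty)
  res <- res[res$retained, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Identify degradome-supported phasiRNA targets
#'
#' Searches every phasiRNA against the transcriptome and keeps sites that
#' satisfy the target rule ((>= 1 valid read in any profile AND <= 4
#' mismatches) OR 0 mismatches). Both the trigger-style and target-style
#' retention flags are reported, since the two rules differ.
#'
#' @param phasirnas phasiRNA data frame (needs `name`, `sequence`) or a
#'   named character vector of sequences.
#' @param transcripts transcript sequences.
#' @param profiles named list of degradome profiles.
#' @param max_mismatches search ceiling (default 5).
#' @return target table with site, valid-read, `pass_trigger_rule`,
#'   `pass_target_rule` and `retained` columns.
#' @export
select_phasirna_targets <- function(phasirnas, transcripts, profiles,
                                    max_mismatches = 5) {
  srna <- if (is.data.frame(phasirnas))
    stats::setNames(phasirnas$sequence, phasirnas$name)
  else phasirnas
  srna <- srna[!duplicated(names(srna))]
  sites <- find_binding_sites(srna, transcripts,
                              max_mismatches = max_mismatches)
  sites <- count_valid_reads(sites, profiles)
  if (nrow(sites) == 0L) {
    sites$pass_trigger_rule <- logical(0)
    sites$pass_target_rule <- logical(0)
    sites$retained <- logical(0)
    return(sites)
  }
  sites$pass_trigger_rule <- trigger_rule(sites$valid_reads,
                                          sites$mismatches)
  sites$pass_target_rule <- target_rule(sites$valid_reads, sites$mismatches)
  sites$retained <- sites$pass_target_rule
  out <- sites[sites$retained, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Data for a degradome T-plot
#'
#' Per-position degradome read counts along one transcript with the binding
#' site and inferred cleavage position annotated; ready for plotting.
#'
#' @param site one row of a binding-site table.
#' @param profile one degradome profile data frame.
#' @param transcript_length length of the transcript in nt.
#' @return data frame `pos`, `count`, `in_site` (logical), `is_cleavage`
#'   (logical), covering every transcript position.
#' @export
tplot_data <- function(site, profile, transcript_length) {
  counts <- numeric(transcript_length)
  pr <- profile[profile$transcript == site$transcript, , drop = FALSE]
  if (nrow(pr)) counts[pr$pos] <- counts[pr$pos] + pr$count
  pos <- seq_len(transcript_length)
  data.frame(pos = pos, count = counts,
             in_site = pos >= site$t_start & pos <= site$t_end,
             is_cleavage = pos == site$cleavage_pos)
}
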