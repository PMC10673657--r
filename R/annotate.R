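# TAS3-style annotation via conserved tasiARFs, cis/trans target
# classification, shared-phasiRNA reporting and network export.

#' Find conserved tasiARF matches in a genome
#'
#' Aligns each tasiARF (20-22 nt) to both strands of the genome allowing at
#' most `max_mismatches` substitutions (no gaps), and extracts a flank of
#' `flank_bp` nt on each side, clamped to the contig.
#'
#' @param tasiarfs named character vector, `DNAStringSet`, or FASTA path.
#' @param genome `DNAStringSet` or named character vector.
#' @param max_mismatches default 2.
#' @param flank_bp default 250.
#' @return data frame: `tasiarf`, `contig`, `match_start`, `match_end`,
#'   `strand`, `mismatches`, `flank_start`, `flank_end`.
#' @export
find_tasiarf_matches <- function(tasiarfs, genome, max_mismatches = 2L,
                                 flank_bp = 250L) {
  if (is.character(tasiarfs) && length(tasiarfs) == 1L &&
      file.exists(tasiarfs))
    tasiarfs <- Biostrings::readDNAStringSet(tasiarfs)
  ta <- if (methods::is(tasiarfs, "DNAStringSet"))
    stats::setNames(as.character(tasiarfs), names(tasiarfs))
  else tasiarfs
  g <- as_chr_genome(genome)
  out <- list()
  for (tn in names(ta)) {
    tseq <- normalize_seq(ta[[tn]])
    L <- nchar(tseq)
    for (ctg in names(g)) {
      clen <- nchar(g[[ctg]])
      subj <- Biostrings::DNAString(g[[ctg]])
      for (str in c("+", "-")) {
        pat <- if (str == "+") tseq else revcomp(tseq)
        m <- Biostrings::matchPattern(pat, subj,
                                      max.mismatch = max_mismatches)
        if (length(m) == 0L) next
        st <- BiocGenerics::start(m)
        mm <- vapply(st, function(p) {
          sum(strsplit(pat, "")[[1L]] !=
                strsplit(substr(g[[ctg]], p, p + L - 1L), "")[[1L]])
        }, numeric(1L))
        out[[length(out) + 1L]] <- data.frame(
          tasiarf = tn, contig = ctg, match_start = st,
          match_end = st + L - 1L, strand = str, mismatches = mm,
          flank_start = pmax(1L, st - as.integer(flank_bp)),
          flank_end = pmin(clen, st + L - 1L + as.integer(flank_bp)))
      }
    }
  }
  res <- rbind_all(out)
  if (is.null(res)) {
    res <- data.frame(tasiarf = character(0), contig = character(0),
                      match_start = integer(0), match_end = integer(0),
                      strand = character(0), mismatches = numeric(0),
                      flank_start = integer(0), flank_end = integer(0))
  }
  sort_df(res, c("contig", "match_start", "strand", "tasiarf"))
}

#' Classify tasiARF matches by miR390 site architecture
#'
#' Predicts miR390 complementary sites on the flank of each tasiARF match
#' (on the strand of the match) and labels matches with one site on each
#' side of the tasiARF as `TAS3-like` (the canonical dual-site
#' architecture), one site as `single-site`, none as `unclassified`.
#' 5' and 3' are defined on the strand of the tasiARF match. When degradome
#' profiles and a transcript map are supplied, valid-read support of each
#' site is recorded.
#'
#' @param matches data frame from [find_tasiarf_matches()].
#' @param mir390 named character vector of miR390(-family) sequences.
#' @param genome genome sequences.
#' @param max_mismatches site search ceiling (default 4).
#' @param profiles optional named list of degradome profiles.
#' @param transcript_map optional transcript-to-genome map (see
#'   [select_trigger_candidates()]).
#' @return list with `matches` (the input plus `n_sites_5p`, `n_sites_3p`,
#'   `tas3_class`) and `sites` (per-match miR390 sites in genomic
#'   coordinates, with valid reads when profiles are given).
#' @export
classify_tas3 <- function(matches, mir390, genome, max_mismatches = 4,
                          profiles = NULL, transcript_map = NULL) {
  g <- as_chr_genome(genome)
  n5 <- n3 <- integer(nrow(matches))
  site_rows <- list()
  for (i in seq_len(nrow(matches))) {
    mt <- matches[i, , drop = FALSE]
    flank <- substr(g[[mt$contig]], mt$flank_start, mt$flank_end)
    str <- mt$strand
    flank_oriented <- if (str == "+") flank else revcomp(flank)
    tx <- stats::setNames(flank_oriented, "flank")
    sites <- find_binding_sites(mir390, tx, max_mismatches = max_mismatches)
    if (nrow(sites) == 0L) next
    flen <- nchar(flank)
    # back to genomic (plus-strand) coordinates
    if (str == "+") {
      gs <- mt$flank_start + sites$t_start - 1L
      ge <- mt$flank_start + sites$t_end - 1L
      gcl <- mt$flank_start + sites$cleavage_pos - 1L
    } else {
      gs <- mt$flank_start + (flen - sites$t_end)
      ge <- mt$flank_start + (flen - sites$t_start)
      gcl <- mt$flank_start + (flen - sites$cleavage_pos)
    }
    # side of the tasiARF, on the strand of the match
    upstream <- ge < mt$match_start
    downstream <- gs > mt$match_end
    side <- rep("overlapping", nrow(sites))
    if (str == "+") {
      side[upstream] <- "5p"; side[downstream] <- "3p"
    } else {
      side[upstream] <- "3p"; side[downstream] <- "5p"
    }
    n5[i] <- sum(side == "5p"); n3[i] <- sum(side == "3p")
    sdf <- data.frame(match_row = i, tasiarf = mt$tasiarf,
                      contig = mt$contig, mir390 = sites$srna,
                      g_start = gs, g_end = ge, strand = str,
                      mismatches = sites$mismatches,
                      cleavage_genomic = gcl, side = side)
    if (!is.null(profiles) && !is.null(transcript_map)) {
      sdf$valid_reads <- vapply(seq_len(nrow(sdf)), function(j) {
        tm <- transcript_map[transcript_map$contig == sdf$contig[j] &
                               transcript_map$g_start <= sdf$cleavage_genomic[j] &
                               transcript_map$g_end >= sdf$cleavage_genomic[j], ,
                             drop = FALSE]
        if (nrow(tm) == 0L) return(0)
        tp <- sdf$cleavage_genomic[j] - tm$g_start[1L] + 1L
        sum(vapply(profiles, function(pr) {
          sum(pr$count[pr$transcript == tm$transcript[1L] &
                         pr$pos >= tp - 1L & pr$pos <= tp + 1L])
        }, numeric(1L)))
      }, numeric(1L))
    }
    site_rows[[length(site_rows) + 1L]] <- sdf
  }
  matches$n_sites_5p <- n5
  matches$n_sites_3p <- n3
  matches$tas3_class <- ifelse(n5 >= 1L & n3 >= 1L, "TAS3-like",
                               ifelse(n5 + n3 == 1L, "single-site",
                                      ifelse(n5 + n3 == 0L, "unclassified",
                                             "multi-site")))
  sites <- rbind_all(site_rows)
  if (is.null(sites)) {
    sites <- data.frame(match_row = integer(0), tasiarf = character(0),
                        contig = character(0), mir390 = character(0),
                        g_start = integer(0), g_end = integer(0),
                        strand = character(0), mismatches = numeric(0),
                        cleavage_genomic = integer(0), side = character(0))
  }
  list(matches = matches, sites = sites)
}

#' Classify phasiRNA targets as cis, same-family or other
#'
#' A target is `cis` when the targeted transcript overlaps the phasiRNA's
#' generating locus on the genome; `same_family` when transcript and locus
#' host gene share a family label; otherwise `other`. `cis` takes
#' precedence over `same_family`.
#'
#' @param targets target table (needs `srna`, `transcript`); phasiRNA
#'   names must carry their locus in a `locus` column or be resolvable via
#'   `phasirnas`.
#' @param loci called-locus data frame.
#' @param transcript_map transcript-to-genome map (`transcript`, `contig`,
#'   `g_start`, `g_end`); targets on unmapped transcripts are non-cis.
#' @param phasirnas optional phasiRNA data frame (`name`, `locus`) to
#'   resolve the generating locus of each sRNA.
#' @param families optional data frame with columns `id`, `family` covering
#'   transcripts and/or loci; without it all non-cis targets are `other`
#'   (with a warning).
#' @return `targets` with `locus` and `target_class` columns.
#' @export
classify_cis_trans <- function(targets, loci, transcript_map,
                               phasirnas = NULL, families = NULL) {
  if (nrow(targets) == 0L) {
    targets$locus <- character(0)
    targets$target_class <- character(0)
    return(targets)
  }
  if (is.null(targets$locus)) {
    if (is.null(phasirnas))
      stop("need a `locus` column or a `phasirnas` table to resolve loci")
    targets$locus <- phasirnas$locus[match(targets$srna, phasirnas$name)]
  }
  li <- match(targets$locus, loci$name)
  ti <- match(targets$transcript, transcript_map$transcript)
  cis <- !is.na(li) & !is.na(ti) &
    transcript_map$contig[ti] == loci$contig[li] &
    transcript_map$g_start[ti] <= loci$end[li] &
    transcript_map$g_end[ti] >= loci$start[li]
  cls <- rep("other", nrow(targets))
  if (!is.null(families)) {
    fam_of <- function(id) families$family[match(id, families$id)]
    same <- !is.na(fam_of(targets$transcript)) &
      !is.na(fam_of(targets$locus)) &
      fam_of(targets$transcript) == fam_of(targets$locus)
    cls[same] <- "same_family"
  } else {
    warning("no family annotation supplied: non-cis targets labeled 'other'",
            call. = FALSE)
  }
  cls[cis] <- "cis"     # precedence: cis beats same_family
  targets$target_class <- cls
  targets
}

#' Report phasiRNA sequences generated by more than one locus
#'
#' @param phasirnas phasiRNA data frame (concatenated over loci).
#' @return data frame `sequence`, `n_loci`, `loci` (comma-separated),
#'   one row per sequence produced by >= 2 distinct loci.
#' @export
shared_phasirna_report <- function(phasirnas) {
  if (nrow(phasirnas) == 0L) {
    return(data.frame(sequence = character(0), n_loci = integer(0),
                      loci = character(0)))
  }
  sp <- split(phasirnas$locus, phasirnas$sequence)
  n <- vapply(sp, function(x) length(unique(x)), integer(1L))
  keep <- n >= 2L
  out <- data.frame(
    sequence = names(sp)[keep], n_loci = n[keep],
    loci = vapply(sp[keep], function(x)
      paste(sort(unique(x)), collapse = ","), character(1L)))
  rownames(out) <- NULL
  sort_df(out, "sequence")
}

#' Export the PHAS -> phasiRNA -| target network
#'
#' Two edge types: `generates` (locus -> phasiRNA) and `targets`
#' (phasiRNA -> transcript, carrying the cis/trans class). Rows are
#' deterministically ordered; the TSV loads directly into network tools.
#'
#' @param phasirnas phasiRNA data frame.
#' @param targets classified target table (see [classify_cis_trans()]).
#' @param path optional output TSV path.
#' @return edge data frame: `source`, `interaction`, `sink`,
#'   `target_class`.
#' @export
export_network <- function(phasirnas, targets, path = NULL) {
  gen <- if (nrow(phasirnas)) {
    data.frame(source = phasirnas$locus, interaction = "generates",
               sink = phasirnas$name, target_class = NA_character_)
  } else {
    data.frame(source = character(0), interaction = character(0),
               sink = character(0), target_class = character(0))
  }
  tgt <- if (nrow(targets)) {
    data.frame(source = targets$srna, interaction = "targets",
               sink = targets$transcript,
               target_class = targets$target_class %||% NA_character_)
  } else {
    data.frame(source = character(0), interaction = character(0),
               sink = character(0), target_class = character(0))
  }
  edges <- rbind(gen, tgt)
  edges <- unique(sort_df(edges, c("interaction", "source", "sink")))
  rownames(edges) <- NULL
  if (!is.null(path)) {
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  edges
}

#' Join loci with a user-supplied annotation table
#'
#' Interval-overlap join: a locus inherits the label/family of every
#' annotation interval it overlaps on its contig. Multi-hit loci are
#' flagged and labels concatenated with `;`; unmatched loci are labeled
#' `unannotated`.
#'
#' @param loci called-locus data frame.
#' @param annotation data frame with columns `contig`, `start`, `end`,
#'   `label`, `family`.
#' @return `loci` with `label`, `family`, `multi_hit` columns.
#' @export
annotate_loci <- function(loci, annotation) {
  need <- c("contig", "start", "end", "label", "family")
  if (!is.data.frame(annotation) || !all(need %in% names(annotation)))
    stop("annotation table must have columns: ",
         paste(need, collapse = ", "))
  lab <- fam <- character(nrow(loci))
  multi <- logical(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    hit <- annotation$contig == loci$contig[i] &
      annotation$start <= loci$end[i] & annotation$end >= loci$start[i]
    h <- which(hit)
    if (length(h) == 0L) {
      lab[i] <- "unannotated"; fam[i] <- NA_character_
    } else {
      lab[i] <- paste(annotation$label[h], collapse = ";")
      fam[i] <- paste(unique(annotation$family[h]), collapse = ";")
      multi[i] <- length(h) > 1L
    }
  }
  loci$label <- lab
  loci$family <- fam
  loci$multi_hit <- multi
  loci
}
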