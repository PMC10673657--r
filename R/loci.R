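# From significant windows to named PHAS loci: extension, overlap merging,
# BH correction, permutation FPR, locus calling and phasiRNA extraction.

#' Extend significant windows
#'
#' Windows with `pvalue < p_max` are widened by `extend_bp` nt on both
#' sides, clamped to `[1, contig length]`. Windows failing the gate are not
#' passed on.
#'
#' @param windows window data frame from [scan_genome()].
#' @param contig_lengths named integer vector.
#' @param p_max significance gate (default 0.05).
#' @param extend_bp extension on each side (default 100).
#' @return extended window data frame (same columns, new bounds in
#'   `start`/`end`; the original window is kept in `win_start`/`win_end`).
#' @export
extend_windows <- function(windows, contig_lengths, p_max = 0.05,
                           extend_bp = 100L) {
  w <- windows[windows$pvalue < p_max, , drop = FALSE]
  if (nrow(w) == 0L) {
    w$win_start <- integer(0); w$win_end <- integer(0)
    return(w)
  }
  w$win_start <- w$start; w$win_end <- w$end
  clen <- as.integer(contig_lengths[w$contig])
  w$start <- pmax(1L, w$start - as.integer(extend_bp))
  w$end <- pmin(clen, w$end + as.integer(extend_bp))
  rownames(w) <- NULL
  w
}

#' Merge overlapping extended windows
#'
#' Transitively merges windows of the same contig and cycle that share at
#' least 1 nt. The representative P-value of a merged interval is the
#' minimum over its members; the locus register is the anchor of the
#' minimum-P member (ties broken by smaller coordinate); the phase score is
#' the maximum over members. Idempotent.
#'
#' @param extended extended window data frame from [extend_windows()].
#' @return merged interval data frame: `contig`, `start`, `end`, `cycle`,
#'   `pvalue`, `anchor`, `max_phase_score`, `n_windows`.
#' @export
merge_windows <- function(extended) {
  empty <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), cycle = integer(0),
                      pvalue = numeric(0), anchor = integer(0),
                      max_phase_score = numeric(0), n_windows = integer(0))
  if (nrow(extended) == 0L) return(empty)
  if (is.null(extended$anchor)) extended$anchor <- extended$start
  if (is.null(extended$max_phase_score)) extended$max_phase_score <- NA_real_
  groups <- split(extended, list(extended$contig, extended$cycle),
                  drop = TRUE)
  out <- lapply(groups, function(g) {
    g <- g[order(g$start, g$end), , drop = FALSE]
    merged <- list()
    cur <- g[1L, , drop = FALSE]
    members <- list(cur)
    flush <- function(members) {
      m <- do.call(rbind, members)
      best <- which(m$pvalue == min(m$pvalue))
      best <- best[which.min(m$anchor[best])]
      data.frame(contig = m$contig[1L], start = min(m$start),
                 end = max(m$end), cycle = m$cycle[1L],
                 pvalue = min(m$pvalue), anchor = m$anchor[best],
                 max_phase_score = max(m$max_phase_score),
                 n_windows = nrow(m))
    }
    cur_end <- g$end[1L]; cur_start <- g$start[1L]
    for (i in seq_len(nrow(g))[-1L]) {
      if (g$start[i] <= cur_end) {          # >= 1 nt shared
        members[[length(members) + 1L]] <- g[i, , drop = FALSE]
        cur_end <- max(cur_end, g$end[i])
      } else {
        merged[[length(merged) + 1L]] <- flush(members)
        members <- list(g[i, , drop = FALSE])
        cur_end <- g$end[i]
      }
    }
    merged[[length(merged) + 1L]] <- flush(members)
    do.call(rbind, merged)
  })
  out <- rbind_all(out)
  sort_df(out, c("contig", "cycle", "start"))
}

#' Benjamini-Hochberg adjustment of merged-interval P-values
#'
#' Applied separately within each cycle class (21 nt and 24 nt scans are
#' independent families of tests).
#'
#' @param merged merged interval data frame.
#' @return `merged` with a `p_adjusted` column.
#' @export
adjust_pvalues <- function(merged) {
  if (nrow(merged) == 0L) {
    merged$p_adjusted <- numeric(0)
    return(merged)
  }
  merged$p_adjusted <- NA_real_
  for (cyc in unique(merged$cycle)) {
    sel <- merged$cycle == cyc
    merged$p_adjusted[sel] <- stats::p.adjust(merged$pvalue[sel],
                                              method = "BH")
  }
  merged
}

#' Permutation false-positive rate of a merged interval
#'
#' Re-draws the effective position of every read placement inside the
#' interval uniformly (multiplicities preserved, strands kept), rescans the
#' permuted interval with windows anchored at occupied positions, and
#' reports the fraction of permutations whose best window P-value is <= the
#' observed interval P-value. Report-only: not used as a call filter.
#'
#' @param interval one row of the merged interval data frame.
#' @param placements placement data frame (see [map_reads()]).
#' @param params [phase_params()] for the interval's cycle.
#' @param n_permutations number of permutations (>= 100; default 1000).
#' @param seed RNG seed for reproducibility.
#' @return estimated FPR in \[0, 1\].
#' @export
estimate_fpr <- function(interval, placements, params,
                         n_permutations = 1000L, seed = 1L) {
  if (n_permutations < 100L)
    stop("n_permutations must be >= 100")
  pl <- placements[placements$contig == interval$contig &
                     placements$length == params$cycle, , drop = FALSE]
  eff <- effective_position(pl$start, pl$strand)
  sel <- eff >= interval$start & eff <= interval$end
  pl <- pl[sel, , drop = FALSE]
  if (nrow(pl) == 0L) return(NA_real_)
  n_reads <- nrow(pl)
  span <- interval$end - interval$start + 1L
  obs <- interval$pvalue
  best_p_of <- function(pos, strand, count) {
    o <- order(pos)
    pos <- pos[o]; count <- count[o]
    anchors <- unique(pos)
    best <- 1
    for (a in anchors) {
      i1 <- findInterval(a - 1L, pos) + 1L
      i2 <- findInterval(a + params$window - 1L, pos)
      s <- i1:i2
      k <- sum((pos[s] - a) %% params$cycle == 0L)
      p <- anchored_window_pvalue(length(s), k, params)
      if (p < best) best <- p
    }
    best
  }
  set.seed(seed)
  hit <- 0L
  for (b in seq_len(n_permutations)) {
    newpos <- interval$start + sample.int(span, n_reads, replace = TRUE) - 1L
    if (best_p_of(newpos, pl$strand, pl$count) <= obs) hit <- hit + 1L
  }
  hit / n_permutations
}

#' Call PHAS loci from merged intervals
#'
#' Keeps intervals with `max_phase_score > score_min` and
#' `p_adjusted < fdr` (both strict in the score, strict in the FDR bound),
#' and names them `PHAS_<contig>_<serial>` with serials consecutive per
#' contig in coordinate order.
#'
#' @param merged merged interval data frame with `p_adjusted` (see
#'   [adjust_pvalues()]).
#' @param score_min phase-score threshold; loci must exceed it (default 5).
#' @param fdr adjusted-P threshold; loci must be below it (default 0.05).
#' @return locus data frame: `name`, `contig`, `start`, `end`, `cycle`,
#'   `anchor`, `pvalue`, `p_adjusted`, `max_phase_score`.
#' @export
call_loci <- function(merged, score_min = 5, fdr = 0.05) {
  keep <- merged$max_phase_score > score_min & merged$p_adjusted < fdr
  loci <- merged[keep & !is.na(keep), , drop = FALSE]
  loci <- sort_df(loci, c("contig", "start"))
  if (nrow(loci)) {
    serial <- stats::ave(seq_len(nrow(loci)), loci$contig,
                         FUN = seq_along)
    loci <- cbind(name = sprintf("PHAS_%s_%d", loci$contig, serial), loci)
  } else {
    loci <- cbind(name = character(0), loci)
  }
  rownames(loci) <- NULL
  loci
}

#' Extract the phasiRNAs of a called locus
#'
#' One phasiRNA per occupied in-register (effective position, strand) slot
#' inside the locus, with the register taken from the locus anchor.
#' Serials `siR1...` are dense over occupied slots in 5'->3' coordinate
#' order; a register-indexed D-notation column (`D<cycle index>(<strand>)`)
#' is also emitted.
#'
#' @param locus one row of the called-locus data frame.
#' @param placements placement data frame carrying `sequence`.
#' @param reads collapsed-read data frame (for per-library counts).
#' @param params [phase_params()] of the locus cycle.
#' @return data frame: `name`, `d_name`, `locus`, `sequence`, `position`
#'   (effective), `strand`, `length`, one count column per library,
#'   `total_count`. Zero rows (with a warning) if the register is empty.
#' @export
extract_phasirnas <- function(locus, placements, reads, params) {
  libs <- attr(reads, "libraries") %||% character(0)
  pl <- placements[placements$contig == locus$contig &
                     placements$length == params$cycle, , drop = FALSE]
  eff <- effective_position(pl$start, pl$strand)
  reg <- locus$anchor %% params$cycle
  sel <- eff >= locus$start & eff <= locus$end &
    (eff - locus$anchor) %% params$cycle == 0L
  pl <- pl[sel, , drop = FALSE]; eff <- eff[sel]
  if (nrow(pl) == 0L) {
    warning("locus ", locus$name, " has an empty phase register",
            call. = FALSE)
    out <- data.frame(name = character(0), d_name = character(0),
                      locus = character(0), sequence = character(0),
                      position = integer(0), strand = character(0),
                      length = integer(0))
    for (lib in libs) out[[lib]] <- numeric(0)
    out$total_count <- numeric(0)
    return(out)
  }
  o <- order(eff, pl$strand, pl$sequence)
  pl <- pl[o, , drop = FALSE]; eff <- eff[o]
  dup <- duplicated(paste(eff, pl$strand, pl$sequence))
  pl <- pl[!dup, , drop = FALSE]; eff <- eff[!dup]
  # phase position 1 = first occupied in-register position (the cycle
  # set off by the trigger cleavage)
  p1 <- min(eff)
  d_idx <- (eff - p1) %/% params$cycle + 1L
  idx <- match(pl$sequence, reads$sequence)
  out <- data.frame(
    name = sprintf("%s_siR%d", locus$name, seq_len(nrow(pl))),
    d_name = sprintf("%s_D%d(%s)", locus$name, d_idx, pl$strand),
    locus = locus$name, sequence = pl$sequence, position = eff,
    strand = pl$strand, length = params$cycle)
  for (lib in libs) {
    v <- reads[[lib]][idx]
    out[[lib]] <- ifelse(is.na(v), 0, v)
  }
  tc <- reads$total_count[idx]
  out$total_count <- ifelse(is.na(tc), pl$count, tc)
  out
}

#' phasiRNA x library count matrix
#'
#' The abundance table consumed by downstream differential-expression or
#' ordination analyses.
#'
#' @param phasirnas phasiRNA data frame (rows from [extract_phasirnas()],
#'   possibly concatenated over loci).
#' @param libraries library ids; default: the count columns present.
#' @return numeric matrix, one row per phasiRNA (rownames = names).
#' @export
phasirna_count_matrix <- function(phasirnas, libraries = NULL) {
  fixed <- c("name", "d_name", "locus", "sequence", "position", "strand",
             "length", "total_count")
  libs <- libraries %||% setdiff(names(phasirnas), fixed)
  m <- as.matrix(phasirnas[, libs, drop = FALSE])
  rownames(m) <- phasirnas$name
  m
}
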