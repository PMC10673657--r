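# Phase-register statistics: effective positions, window occupancy,
# the hypergeometric window test, and the per-position phase score.

#' Parameters for a phase scan
#'
#' A PHAS scan of cycle length `c` examines windows of `window_cycles`
#' phase cycles (default 10, i.e. 210 nt for 21-nt phasiRNAs and 240 nt for
#' 24-nt phasiRNAs). The window population counts one slot per position and
#' strand (`N = 2W`), of which `K = 2 * window_cycles` fall in the anchor
#' register once antisense reads are shifted by the +2-nt duplex offset.
#'
#' @param cycle phase cycle length in nt, 21 or 24.
#' @param window_cycles number of cycles per scan window (default 10).
#' @param min_k minimum number of distinct in-register occupied positions
#'   required for a non-zero phase score (default 3).
#' @return a `phase_params` list with elements `cycle`, `window`, `m`
#'   (cycles per window), `K` (in-register slots), `N` (total slots) and
#'   `min_k`.
#' @examples
#' phase_params(21)   # window 210, N = 420, K = 20
#' phase_params(24)   # window 240, N = 480, K = 20
#' @export
phase_params <- function(cycle = 21L, window_cycles = 10L, min_k = 3L) {
  cycle <- as.integer(cycle)
  window_cycles <- as.integer(window_cycles)
  stopifnot(cycle >= 2L, window_cycles >= 1L, min_k >= 0L)
  W <- cycle * window_cycles
  structure(
    list(cycle = cycle, window = W, m = window_cycles,
         K = 2L * window_cycles, N = 2L * W, min_k = as.integer(min_k)),
    class = "phase_params"
  )
}

#' @export
print.phase_params <- function(x, ...) {
  cat(sprintf(
    "phase scan parameters: cycle %d nt, window %d nt (%d cycles), N=%d slots, K=%d in-register\n",
    x$cycle, x$window, x$m, x$N, x$K))
  invisible(x)
}

#' Effective phase coordinate of a read placement
#'
#' Plus-strand reads phase at their 5' (leftmost) coordinate. Because
#' phasiRNA duplexes carry 2-nt 3' overhangs, an antisense read is in the
#' same register as its sense partner when its leftmost coordinate is
#' shifted by +2: the exact duplex partner of a plus read starting at `p`
#' spans `[p-2, p+c-3]` on the minus strand and therefore maps back to
#' effective position `p`.
#'
#' @param start leftmost 1-based genomic coordinate(s).
#' @param strand `"+"` or `"-"`, recycled.
#' @return integer vector of effective phase coordinates.
#' @examples
#' effective_position(101, "+")  # 101
#' effective_position(99, "-")   # 101
#' @export
effective_position <- function(start, strand) {
  start <- as.integer(start)
  as.integer(start + 2L * (strand == "-"))
}

#' Upper-tail hypergeometric P-value for window phasing
#'
#' Tests whether `k` of the `n` occupied position/strand slots in a window
#' falling in the anchor register is surprising under random occupancy:
#' the upper tail `P(X >= k)` for `X ~ Hypergeometric(N, K, n)` with `N`
#' total slots and `K` in-register slots. Computed exactly in log space
#' (no normal approximation).
#'
#' @param n occupied slots in the window (draws).
#' @param k occupied slots in the anchor register.
#' @param params a [phase_params()] object.
#' @return P-value in \[0, 1\]; vectorised over `n`, `k`.
#' @examples
#' p <- phase_params(21)
#' hypergeometric_pvalue(1, 1, p)  # = K/N = 20/420
#' hypergeometric_pvalue(5, 0, p)  # = 1
#' @export
hypergeometric_pvalue <- function(n, k, params) {
  n <- as.integer(n); k <- as.integer(k)
  if (any(k < 0L) || any(n < 0L) || any(k > n) || any(n > params$N) ||
      any(k > pmin(n, params$K)))
    stop("invalid (n, k): need 0 <= k <= min(n, K) and n <= N")
  stats::phyper(k - 1L, m = params$K, n = params$N - params$K, k = n,
                lower.tail = FALSE)
}

#' Window P-value conditional on an occupied anchor
#'
#' Candidate windows are anchored at occupied effective positions, so the
#' anchor slot is occupied and in-register by construction. Testing such a
#' window with the unconditional hypergeometric tail would be
#' anti-conservative; the calibrated test conditions on the anchor:
#' `P(X >= k - 1)` for `X ~ Hypergeometric(N - 1, K - 1, n - 1)` over the
#' remaining slots. For `n = 1` (the anchor alone) the P-value is 1.
#'
#' @inheritParams hypergeometric_pvalue
#' @return P-value in \[0, 1\]; vectorised.
#' @seealso [hypergeometric_pvalue()] for the unconditional tail.
#' @export
anchored_window_pvalue <- function(n, k, params) {
  n <- as.integer(n); k <- as.integer(k)
  if (any(k < 1L) || any(n < 1L) || any(k > n) || any(n > params$N))
    stop("invalid (n, k): anchored windows have k >= 1 and n >= 1")
  stats::phyper(k - 2L, m = params$K - 1L,
                n = params$N - params$K, k = n - 1L, lower.tail = FALSE)
}

#' Phase score at a position
#'
#' `score = (k - 2) * ln(1 + 10 P / (1 + U))` when at least `min_k`
#' distinct in-register positions are occupied, else 0. `P` is the summed
#' read abundance at in-register effective positions in the scoring window,
#' `U` the abundance out of register, and `k` the number of distinct
#' occupied in-register position/strand slots.
#'
#' @param P in-register abundance (>= 0), vectorised.
#' @param U out-of-register abundance (>= 0).
#' @param k distinct occupied in-register slots.
#' @param min_k support threshold below which the score is 0 (default 3).
#' @return numeric score(s), >= 0.
#' @examples
#' phase_score(10, 0, 3)  # log(101)
#' phase_score(10, 0, 2)  # 0: below support threshold
#' @export
phase_score <- function(P, U, k, min_k = 3L) {
  stopifnot(all(P >= 0), all(U >= 0), all(k >= 0))
  out <- (k - 2) * log1p(10 * P / (1 + U))
  out[k < min_k] <- 0
  out
}

# Build the occupancy table used by every window computation: one row per
# (contig, effective position, strand) slot, with summed read abundance.
# `placements` must have columns contig, start, strand, length, count;
# rows with length != params$cycle are excluded from the scan of that cycle.
occupancy_slots <- function(placements, params) {
  pl <- placements[placements$length == params$cycle, , drop = FALSE]
  if (nrow(pl) == 0L) {
    return(data.frame(contig = character(0), pos = integer(0),
                      strand = character(0), count = numeric(0)))
  }
  eff <- effective_position(pl$start, pl$strand)
  key <- paste(pl$contig, eff, pl$strand)
  agg <- rowsum(as.numeric(pl$count), key)
  parts <- strsplit(rownames(agg), " ", fixed = TRUE)
  out <- data.frame(
    contig = vapply(parts, `[`, "", 1L),
    pos = as.integer(vapply(parts, `[`, "", 2L)),
    strand = vapply(parts, `[`, "", 3L),
    count = as.numeric(agg[, 1L])
  )
  sort_df(out, c("contig", "pos", "strand"))
}

#' Occupancy and abundance of one phase window
#'
#' Counts, for the window `[anchor, anchor + W - 1]`, the distinct occupied
#' position/strand slots `n`, the in-register subset `k`
#' (`(pos - anchor) %% cycle == 0`), and the in-/out-of-register abundance
#' sums `P` and `U`. Antisense placements enter via their +2 effective
#' position.
#'
#' @param placements data frame with columns `contig`, `start`, `strand`,
#'   `length`, `count` (pooled abundance per placement).
#' @param anchor 1-based window start defining the register.
#' @param params a [phase_params()] object.
#' @param contig restrict to this contig (default: the only contig present).
#' @return list with elements `n`, `k`, `P`, `U`.
#' @export
window_counts <- function(placements, anchor, params, contig = NULL) {
  slots <- occupancy_slots(placements, params)
  if (!is.null(contig)) slots <- slots[slots$contig == contig, , drop = FALSE]
  anchor <- as.integer(anchor)
  inwin <- slots$pos >= anchor & slots$pos <= anchor + params$window - 1L
  s <- slots[inwin, , drop = FALSE]
  inreg <- (s$pos - anchor) %% params$cycle == 0L
  list(n = nrow(s), k = sum(inreg),
       P = sum(s$count[inreg]), U = sum(s$count[!inreg]))
}

# Phase score for each distinct occupied effective position on one contig.
# The scoring window is params$window nt centred at the scored position,
# truncated at the contig edges; the register is that of the scored position.
position_scores_contig <- function(pos, strand, count, params, contig_len) {
  upos <- sort(unique(pos))
  half <- params$window %/% 2L
  n_pos <- length(upos)
  P <- U <- numeric(n_pos); kk <- integer(n_pos)
  ord <- order(pos)
  pos <- pos[ord]; count <- count[ord]
  for (i in seq_len(n_pos)) {
    p0 <- upos[i]
    ws <- max(1L, p0 - half)
    we <- min(contig_len, ws + params$window - 1L)
    i1 <- findInterval(ws - 1L, pos) + 1L
    i2 <- findInterval(we, pos)
    if (i2 < i1) next
    sel <- i1:i2
    inreg <- (pos[sel] - p0) %% params$cycle == 0L
    P[i] <- sum(count[sel][inreg])
    U[i] <- sum(count[sel][!inreg])
    kk[i] <- sum(inreg)
  }
  data.frame(position = upos, P = P, U = U, k = kk,
             score = phase_score(P, U, kk, params$min_k))
}

#' Per-position phase scores
#'
#' Computes the phase score at every occupied effective position, using a
#' window of one scan width centred on the scored position (truncated at
#' contig edges) and the register defined by that position.
#'
#' @inheritParams window_counts
#' @param contig_lengths named integer vector of contig lengths.
#' @return data frame with columns `contig`, `position`, `P`, `U`, `k`,
#'   `score`.
#' @export
position_scores <- function(placements, params, contig_lengths) {
  slots <- occupancy_slots(placements, params)
  out <- lapply(split(slots, slots$contig), function(s) {
    cl <- contig_lengths[[s$contig[1L]]]
    cbind(contig = s$contig[1L],
          position_scores_contig(s$pos, s$strand, s$count, params, cl))
  })
  res <- rbind_all(out)
  if (is.null(res)) {
    res <- data.frame(contig = character(0), position = integer(0),
                      P = numeric(0), U = numeric(0), k = integer(0),
                      score = numeric(0))
  }
  res
}

#' Scan a genome for phased windows
#'
#' Slides a candidate window anchored at every occupied effective position
#' (a significant register must contain a read at its anchor). Each window
#' spans `[anchor, anchor + W - 1]`; windows running past the contig end are
#' dropped. For each window the occupancy counts, the anchor-conditional
#' hypergeometric P-value (see [anchored_window_pvalue()]), and the maximum
#' per-position phase score among occupied positions inside the window are
#' recorded.
#'
#' @inheritParams position_scores
#' @return data frame of windows: `contig`, `start`, `end`, `cycle`,
#'   `anchor`, `n`, `k`, `P`, `U`, `pvalue`, `max_phase_score`.
#' @export
scan_genome <- function(placements, params, contig_lengths) {
  slots <- occupancy_slots(placements, params)
  empty <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), cycle = integer(0),
                      anchor = integer(0), n = integer(0), k = integer(0),
                      P = numeric(0), U = numeric(0), pvalue = numeric(0),
                      max_phase_score = numeric(0))
  if (nrow(slots) == 0L) return(empty)
  res <- lapply(split(slots, slots$contig), function(s) {
    ctg <- s$contig[1L]
    clen <- contig_lengths[[ctg]]
    if (is.null(clen) || is.na(clen)) stop("missing length for contig ", ctg)
    pos <- s$pos; count <- s$count        # sorted by occupancy_slots
    scores <- position_scores_contig(pos, s$strand, count, params, clen)
    anchors <- unique(pos)
    anchors <- anchors[anchors + params$window - 1L <= clen]
    if (length(anchors) == 0L) return(NULL)
    n <- k <- integer(length(anchors))
    P <- U <- smax <- numeric(length(anchors))
    for (i in seq_along(anchors)) {
      a <- anchors[i]
      i1 <- findInterval(a - 1L, pos) + 1L
      i2 <- findInterval(a + params$window - 1L, pos)
      sel <- i1:i2
      inreg <- (pos[sel] - a) %% params$cycle == 0L
      n[i] <- length(sel); k[i] <- sum(inreg)
      P[i] <- sum(count[sel][inreg]); U[i] <- sum(count[sel][!inreg])
      sp <- scores$position >= a & scores$position <= a + params$window - 1L
      smax[i] <- max(scores$score[sp])
    }
    data.frame(contig = ctg, start = anchors,
               end = anchors + params$window - 1L,
               cycle = params$cycle, anchor = anchors, n = n, k = k,
               P = P, U = U,
               pvalue = anchored_window_pvalue(n, k, params),
               max_phase_score = smax)
  })
  res <- rbind_all(res)
  if (is.null(res)) return(empty)
  sort_df(res, c("contig", "start"))
}
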