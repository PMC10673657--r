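mk_windows <- function(start, end, pvalue, contig = "chr1", cycle = 21L,
                       score = 10) {
  data.frame(contig = contig, start = start, end = end, cycle = cycle,
             anchor = start, n = 10L, k = 10L, P = 50, U = 0,
             pvalue = pvalue, max_phase_score = score)
}

test_that("window extension clamps to the contig and gates on P", {
  clen <- c(chr1 = 10000L)
  w <- mk_windows(1000L, 1209L, 0.01)
  e <- extend_windows(w, clen)
  expect_equal(c(e$start, e$end), c(900L, 1309L))
  expect_equal(c(e$win_start, e$win_end), c(1000L, 1209L))

  e2 <- extend_windows(mk_windows(50L, 259L, 0.01), clen)
  expect_equal(c(e2$start, e2$end), c(1L, 359L))

  e3 <- extend_windows(mk_windows(9950L, 10159L, 0.01),
                       c(chr1 = 10100L))
  expect_equal(e3$end, 10100L)

  expect_equal(nrow(extend_windows(mk_windows(1000L, 1209L, 0.2), clen)),
               0L)
})

test_that("overlap merging keeps the minimum P and is idempotent", {
  e <- rbind(mk_windows(900L, 1310L, 0.01),
             mk_windows(1050L, 1460L, 0.001))
  m <- merge_windows(e)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(900L, 1460L))
  expect_equal(m$pvalue, 0.001)
  expect_equal(m$anchor, 1050L)        # anchor of the min-P member

  # disjoint intervals unchanged
  d <- rbind(mk_windows(100L, 500L, 0.01), mk_windows(700L, 900L, 0.02))
  md <- merge_windows(d)
  expect_equal(nrow(md), 2L)
  expect_equal(md$start, c(100L, 700L))

  # idempotence
  m2 <- merge_windows(md)
  expect_equal(md[c("contig", "start", "end", "pvalue")],
               m2[c("contig", "start", "end", "pvalue")])

  # different cycles never merge
  mixed <- rbind(mk_windows(100L, 500L, 0.01),
                 mk_windows(300L, 700L, 0.01, cycle = 24L))
  expect_equal(nrow(merge_windows(mixed)), 2L)

  # abutting-by-1 intervals share a nucleotide
  ab <- rbind(mk_windows(100L, 200L, 0.03), mk_windows(200L, 300L, 0.01))
  expect_equal(nrow(merge_windows(ab)), 1L)
})

test_that("BH adjustment matches the hand-computed step-up", {
  m <- rbind(mk_windows(100L, 300L, 0.01), mk_windows(400L, 600L, 0.02),
             mk_windows(700L, 900L, 0.03), mk_windows(1000L, 1200L, 0.04))
  m <- merge_windows(m)
  a <- adjust_pvalues(m)
  expect_equal(a$p_adjusted, rep(0.04, 4))

  one <- adjust_pvalues(merge_windows(mk_windows(100L, 300L, 0.012)))
  expect_equal(one$p_adjusted, one$pvalue)

  eq <- adjust_pvalues(merge_windows(
    rbind(mk_windows(100L, 300L, 0.02), mk_windows(500L, 700L, 0.02))))
  expect_equal(eq$p_adjusted, rep(0.02, 2))

  # correction is per cycle class
  mix <- adjust_pvalues(merge_windows(
    rbind(mk_windows(100L, 300L, 0.03),
          mk_windows(500L, 700L, 0.03, cycle = 24L))))
  expect_equal(mix$p_adjusted, rep(0.03, 2))
})

test_that("locus calling applies strict score and FDR thresholds", {
  m <- merge_windows(rbind(
    mk_windows(100L, 400L, 1e-6, score = 6.1),
    mk_windows(1000L, 1300L, 1e-6, score = 5.0),
    mk_windows(2000L, 2300L, 1e-6, score = 8)))
  m$p_adjusted <- c(0.01, 0.01, 0.06)
  called <- call_loci(m)
  expect_equal(nrow(called), 1L)
  expect_equal(called$max_phase_score, 6.1)
  expect_equal(called$name, "PHAS_chr1_1")
})

test_that("locus names are serial per contig in coordinate order", {
  m <- merge_windows(rbind(
    mk_windows(5000L, 5300L, 1e-6), mk_windows(100L, 400L, 1e-6),
    mk_windows(900L, 1200L, 1e-6, contig = "chr2")))
  m$p_adjusted <- 1e-4
  called <- call_loci(m)
  expect_equal(called$name[called$contig == "chr1"],
               c("PHAS_chr1_1", "PHAS_chr1_2"))
  expect_equal(called$start[called$name == "PHAS_chr1_1"], 100L)
  expect_equal(called$name[called$contig == "chr2"], "PHAS_chr2_1")
  # naming is a pure function of coordinates: identical on re-run
  expect_equal(call_loci(m)$name, called$name)
})

locus_row <- function(anchor = 1001L, cycle = 21L, span = 400L,
                      contig = "chr1") {
  data.frame(name = "PHAS_chr1_1", contig = contig,
             start = anchor - 100L, end = anchor - 100L + span, cycle = cycle,
             pvalue = 1e-8, anchor = anchor, max_phase_score = 20,
             p_adjusted = 1e-6, n_windows = 1L)
}

test_that("phasiRNA extraction is register-faithful and densely numbered", {
  reads <- collapse_reads(list(l1 = character(0)))
  p <- phase_params(21)
  loc <- locus_row()

  plus <- phased_placements(anchor = 1001L, count = 5)
  ph <- extract_phasirnas(loc, plus, reads, p)
  expect_equal(nrow(ph), 10L)
  expect_equal(ph$name, sprintf("PHAS_chr1_1_siR%d", 1:10))
  expect_equal(ph$d_name, sprintf("PHAS_chr1_1_D%d(+)", 1:10))

  dup <- phased_placements(anchor = 1001L, count = 5, duplex = TRUE)
  ph2 <- extract_phasirnas(loc, dup, reads, p)
  expect_equal(nrow(ph2), 20L)

  # a gap in the register: serials stay dense, D-index keeps the position
  gap <- plus[-3, ]
  ph3 <- extract_phasirnas(loc, gap, reads, p)
  expect_equal(nrow(ph3), 9L)
  expect_equal(ph3$name, sprintf("PHAS_chr1_1_siR%d", 1:9))
  expect_equal(ph3$d_name[3], "PHAS_chr1_1_D4(+)")

  # off-register reads are not phasiRNAs
  off <- plus; off$start <- off$start + 3L
  expect_warning(ph4 <- extract_phasirnas(loc, off[0, ], reads, p),
                 "empty phase register")
  expect_equal(nrow(ph4), 0L)
})

test_that("count matrix carries per-library abundances", {
  s <- vapply(1:3, function(i) rand_dna_test(21), "")
  reads <- collapse_reads(list(l1 = rep(s, c(2, 3, 4)), l2 = s[1]))
  pl <- data.frame(sequence = s, contig = "chr1",
                   start = 1001L + 21L * (0:2), end = 1021L + 21L * (0:2),
                   strand = "+", length = 21L,
                   count = reads$total_count[match(s, reads$sequence)])
  ph <- extract_phasirnas(locus_row(), pl, reads, phase_params(21))
  m <- phasirna_count_matrix(ph)
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(unname(rowSums(m)), ph$total_count)
  expect_equal(unname(m[1, "l2"]), 1)
})

test_that("permutation FPR separates phased from uniform intervals", {
  p <- phase_params(21)
  itv <- data.frame(contig = "chr1", start = 900L, end = 1350L,
                    pvalue = NA_real_)

  phased <- phased_placements(anchor = 1001L, count = 5, duplex = TRUE)
  itv$pvalue <- anchored_window_pvalue(20, 20, p)
  expect_lte(estimate_fpr(itv, phased, p, 1000, seed = 3), 0.01)

  expect_error(estimate_fpr(itv, phased, p, 0), ">= 100")

  # uniform placements: observed min-P replayed under its own null
  set.seed(99)
  unif <- uniform_placements(25, 430L)
  unif$start <- unif$start + 899L
  unif$end <- unif$start + 20L
  w <- scan_genome(unif, p, c(chr1 = 2000L))
  itv2 <- data.frame(contig = "chr1", start = 900L, end = 1350L,
                     pvalue = min(w$pvalue))
  fprs <- vapply(1:11, function(s) estimate_fpr(itv2, unif, p, 100, seed = s),
                 numeric(1))
  expect_gte(stats::median(fprs), 0.2)
  expect_lte(stats::median(fprs), 0.8)
})
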