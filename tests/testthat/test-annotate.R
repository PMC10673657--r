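mutate_at <- function(s, pos) {
  for (p in pos) {
    old <- substr(s, p, p)
    substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  s
}

test_that("tasiARF scan finds copies up to two mismatches on both strands", {
  set.seed(31)
  ta <- c(arf = rand_dna_test(21))
  g <- rand_dna_test(8000)
  substr(g, 1001, 1021) <- ta[["arf"]]                     # exact
  substr(g, 2001, 2021) <- mutate_at(ta[["arf"]], 5)       # 1 mm
  substr(g, 3001, 3021) <- mutate_at(ta[["arf"]], c(3, 17)) # 2 mm
  substr(g, 4001, 4021) <- mutate_at(ta[["arf"]], c(2, 9, 20)) # 3 mm
  substr(g, 5001, 5021) <- revcomp(ta[["arf"]])            # minus strand
  genome <- c(chrA = g)
  m <- find_tasiarf_matches(ta, genome, max_mismatches = 2)
  expect_setequal(m$match_start, c(1001L, 2001L, 3001L, 5001L))
  expect_equal(m$mismatches[m$match_start == 1001], 0)
  expect_equal(m$mismatches[m$match_start == 2001], 1)
  expect_equal(m$mismatches[m$match_start == 3001], 2)
  expect_equal(m$strand[m$match_start == 5001], "-")
  # flank bounds: match +/- 250 clamped to the contig
  expect_equal(m$flank_start[m$match_start == 1001], 751L)
  expect_equal(m$flank_end[m$match_start == 1001], 1271L)
  near_edge <- find_tasiarf_matches(
    ta, c(s = paste0(ta[["arf"]], rand_dna_test(50))), max_mismatches = 0)
  expect_equal(near_edge$flank_start, 1L)
  expect_equal(near_edge$flank_end, 71L)
})

test_that("tasiARF scan equals the brute-force oracle", {
  set.seed(13)
  ta <- c(arf = rand_dna_test(21))
  g <- c(c1 = rand_dna_test(6000))
  substr(g[["c1"]], 501, 521) <- mutate_at(ta[["arf"]], c(4, 12))
  substr(g[["c1"]], 901, 921) <- revcomp(mutate_at(ta[["arf"]], 7))
  got <- find_tasiarf_matches(ta, g, max_mismatches = 2)
  want <- naive_tasiarf(ta[["arf"]], g, 2)
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got[c("contig", "match_start", "strand", "mismatches")],
               want, ignore_attr = TRUE)
})

test_that("dual miR390 sites flanking a tasiARF classify as TAS3-like", {
  b <- simulate_dataset(sim_config(seed = 9, n_phas_21 = 0, n_phas_24 = 0,
                                   n_tas3_like = 1,
                                   background_read_density = 0))
  m <- find_tasiarf_matches(b$tasiarfs, b$genome, max_mismatches = 2)
  expect_gte(nrow(m), 2L)     # two payload copies implanted
  cl <- classify_tas3(m, b$mirnas["mir390_syn"], b$genome,
                      profiles = b$degradome,
                      transcript_map = b$transcript_map)
  expect_true(all(cl$matches$tas3_class == "TAS3-like"))
  expect_true(all(cl$matches$n_sites_5p >= 1))
  expect_true(all(cl$matches$n_sites_3p >= 1))
  # the 3' site carries the implanted cleavage signal
  s3 <- cl$sites[cl$sites$side == "3p", ]
  expect_true(all(s3$valid_reads > 0))

  # single-site and zero-site flanks
  set.seed(2)
  ta <- c(arf = rand_dna_test(21))
  mir <- c(mir390 = rand_dna_test(21))
  g1 <- rand_dna_test(1200)
  substr(g1, 601, 621) <- ta[["arf"]]
  substr(g1, 501, 521) <- revcomp(mir[["mir390"]])   # one 5' site only
  m1 <- find_tasiarf_matches(ta, c(c1 = g1), max_mismatches = 0)
  c1 <- classify_tas3(m1, mir, c(c1 = g1))
  expect_equal(c1$matches$tas3_class, "single-site")
  g0 <- rand_dna_test(1200)
  substr(g0, 601, 621) <- ta[["arf"]]
  m0 <- find_tasiarf_matches(ta, c(c0 = g0), max_mismatches = 0)
  c0 <- classify_tas3(m0, mir, c(c0 = g0))
  expect_equal(c0$matches$tas3_class, "unclassified")
})

test_that("cis/trans classification gives cis precedence and is order-stable", {
  loci <- data.frame(name = "PHAS_c1_1", contig = "c1", start = 1000L,
                     end = 1400L, cycle = 21L)
  tmap <- data.frame(transcript = c("tx_self", "tx_other"),
                     contig = c("c1", "c1"),
                     g_start = c(950L, 5000L), g_end = c(1450L, 5800L))
  fam <- data.frame(id = c("tx_self", "tx_other", "PHAS_c1_1"),
                    family = c("F", "F", "F"))
  tg <- data.frame(srna = c("PHAS_c1_1_siR1", "PHAS_c1_1_siR2",
                            "PHAS_c1_1_siR3"),
                   transcript = c("tx_self", "tx_other", "tx_unknown"),
                   locus = "PHAS_c1_1")
  out <- classify_cis_trans(tg, loci, tmap, families = fam)
  expect_equal(out$target_class,
               c("cis", "same_family", "other"))
  # cis wins even though tx_self shares the family label
  expect_equal(out$target_class[1], "cis")
  # permuting rows permutes labels identically
  perm <- c(3, 1, 2)
  out2 <- classify_cis_trans(tg[perm, ], loci, tmap, families = fam)
  expect_equal(out2$target_class, out$target_class[perm])
  # no family table: non-cis collapse to other
  expect_warning(out3 <- classify_cis_trans(tg, loci, tmap),
                 "no family annotation")
  expect_equal(out3$target_class, c("cis", "other", "other"))
})

test_that("shared phasiRNA report groups identical sequences across loci", {
  ph <- data.frame(
    name = c("A_siR1", "A_siR2", "B_siR1", "C_siR1"),
    locus = c("A", "A", "B", "C"),
    sequence = c("ACGT", "GGGG", "ACGT", "TTTT"))
  sh <- shared_phasirna_report(ph)
  expect_equal(nrow(sh), 1L)
  expect_equal(sh$sequence, "ACGT")
  expect_equal(sh$n_loci, 2L)
  expect_equal(sh$loci, "A,B")
  expect_equal(nrow(shared_phasirna_report(ph[ph$locus == "A", ])), 0L)
  expect_equal(nrow(shared_phasirna_report(ph[c(2, 4), ])), 0L)
})

test_that("network export emits typed edges in deterministic order", {
  ph <- data.frame(name = c("L1_siR1", "L1_siR2"), locus = "L1",
                   sequence = c("AA", "CC"))
  tg <- data.frame(srna = "L1_siR1", transcript = "tx9",
                   target_class = "cis")
  tf <- withr::local_tempfile(fileext = ".tsv")
  net <- export_network(ph, tg, path = tf)
  expect_equal(sum(net$interaction == "generates"), 2L)
  expect_equal(sum(net$interaction == "targets"), 1L)
  gen <- net[net$interaction == "generates", ]
  expect_true(all(gen$source == "L1"))
  tgt <- net[net$interaction == "targets", ]
  expect_equal(tgt$source, "L1_siR1")
  expect_equal(tgt$target_class, "cis")
  # deterministic: identical on re-run, file round-trips
  expect_equal(export_network(ph, tg), net)
  back <- read.table(tf, header = TRUE, sep = "\t", na.strings = "NA")
  expect_equal(nrow(back), 3L)
})

test_that("annotation join labels overlaps and flags multi-hits", {
  loci <- data.frame(name = c("PHAS_c1_1", "PHAS_c1_2", "PHAS_c2_1"),
                     contig = c("c1", "c1", "c2"),
                     start = c(100L, 5000L, 10L), end = c(500L, 5400L, 50L))
  ann <- data.frame(contig = c("c1", "c1", "c1"),
                    start = c(50L, 400L, 4000L),
                    end = c(450L, 600L, 4600L),
                    label = c("geneA", "geneB", "geneC"),
                    family = c("NB-LRR", "NB-LRR", "PPR"))
  out <- annotate_loci(loci, ann)
  expect_equal(out$label[1], "geneA;geneB")
  expect_true(out$multi_hit[1])
  expect_equal(out$family[1], "NB-LRR")
  expect_equal(out$label[2], "unannotated")
  expect_equal(out$label[3], "unannotated")
  expect_error(annotate_loci(loci, data.frame(x = 1)), "columns")
})
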