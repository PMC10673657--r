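test_that("effective positions implement the 2-nt antisense offset", {
  expect_identical(effective_position(101L, "+"), 101L)
  # duplex partner of a plus read at 101 starts at 99 on the minus strand
  expect_identical(effective_position(99L, "-"), 101L)
  # a minus read at 100 lands at 102, out of the 101 register mod 21
  expect_identical(effective_position(100L, "-"), 102L)
  expect_false((effective_position(100L, "-") - 101L) %% 21L == 0L)
  expect_identical(effective_position(c(10L, 10L), c("+", "-")),
                   c(10L, 12L))
})

test_that("window occupancy counts distinct slots and splits by register", {
  p <- phase_params(21)
  pl <- phased_placements(anchor = 1001L, count = 5)
  wc <- window_counts(pl, 1001L, p)
  expect_equal(wc[c("n", "k")], list(n = 10L, k = 10L))
  expect_equal(wc$P, 50); expect_equal(wc$U, 0)

  # one extra off-register read
  extra <- pl[1, ]; extra$start <- 1006L; extra$end <- 1026L
  extra$sequence <- "X001"
  wc2 <- window_counts(rbind(pl, extra), 1001L, p)
  expect_equal(wc2[c("n", "k")], list(n = 11L, k = 10L))

  # full duplex: both strands occupy distinct slots, all in register
  wc3 <- window_counts(phased_placements(duplex = TRUE), 1001L, p)
  expect_equal(wc3[c("n", "k")], list(n = 20L, k = 20L))
})

test_that("hypergeometric tail equals combinatorial enumeration (N = 42)", {
  mini <- phase_params(21, window_cycles = 1)   # W = 21, N = 42, K = 2
  expect_equal(mini$N, 42L); expect_equal(mini$K, 2L)
  for (n in 0:42) {
    for (k in 0:min(n, 2L)) {
      expect_equal(hypergeometric_pvalue(n, k, mini),
                   oracle_hyper_tail(n, k, 42, 2), tolerance = 1e-12,
                   info = sprintf("n=%d k=%d", n, k))
    }
  }
  # literal pattern enumeration for small n
  for (n in 1:4) {
    for (k in 0:min(n, 2L)) {
      expect_equal(hypergeometric_pvalue(n, k, mini),
                   oracle_hyper_enum(n, k, 42, 2), tolerance = 1e-12)
    }
  }
})

test_that("hypergeometric closed forms hold", {
  p21 <- phase_params(21)
  expect_equal(hypergeometric_pvalue(1, 1, p21), 20 / 420,
               tolerance = 1e-14)
  expect_equal(hypergeometric_pvalue(7, 0, p21), 1)
  # all K in-register slots drawn: single-term tail
  expect_equal(hypergeometric_pvalue(20, 20, p21),
               exp(lchoose(20, 20) + lchoose(400, 0) - lchoose(420, 20)),
               tolerance = 1e-12)
  p24 <- phase_params(24)
  expect_equal(hypergeometric_pvalue(1, 1, p24), 20 / 480,
               tolerance = 1e-14)
  expect_error(hypergeometric_pvalue(5, 6, p21), "invalid")
  expect_error(hypergeometric_pvalue(421, 3, p21), "invalid")
})

test_that("p-value is non-increasing in k at fixed n", {
  p <- phase_params(21)
  for (n in c(3, 8, 15, 20)) {
    pv <- hypergeometric_pvalue(rep(n, min(n, 20) + 1), 0:min(n, 20), p)
    expect_true(all(diff(pv) <= 1e-15))
    pa <- anchored_window_pvalue(rep(n, min(n, 20)), 1:min(n, 20), p)
    expect_true(all(diff(pa) <= 1e-15))
  }
})

test_that("anchored window test matches enumeration given the anchor", {
  mini <- phase_params(21, window_cycles = 1)   # N = 42, K = 2
  # condition on one occupied in-register slot; remaining n-1 draws from 41
  for (n in 2:10) {
    for (k in 1:min(n, 2L)) {
      expect_equal(anchored_window_pvalue(n, k, mini),
                   oracle_hyper_tail(n - 1, k - 1, 41, 1),
                   tolerance = 1e-12)
    }
  }
  expect_equal(anchored_window_pvalue(1, 1, mini), 1)
})

test_that("phase score matches its formula and monotonicity", {
  expect_equal(phase_score(10, 0, 3), log(101), tolerance = 1e-12)
  expect_equal(phase_score(5, 5, 2), 0)     # below support threshold
  expect_equal(phase_score(0, 0, 3), 0)     # log(1)
  expect_equal(phase_score(100, 7, 1), 0)
  # strict monotonicity on a grid, k >= 3
  Pg <- c(1, 5, 20, 100); Ug <- c(0, 2, 10); kg <- 3:6
  for (U in Ug) for (k in kg) {
    expect_true(all(diff(phase_score(Pg, U, k)) > 0))
  }
  for (P in Pg) for (U in Ug) {
    expect_true(all(diff(phase_score(P, U, kg)) > 0))
  }
  for (P in Pg) for (k in kg) {
    expect_true(all(diff(phase_score(P, Ug, k)) < 0))
  }
})

test_that("duplex conversion leaves all window statistics unchanged", {
  set.seed(42)
  p <- phase_params(21)
  clen <- c(chr1 = 5000L)
  pl <- rbind(phased_placements(anchor = 2001L, count = 7),
              uniform_placements(40, 4900L))
  pl$count <- sample(1:20, nrow(pl), replace = TRUE)
  # exact duplex partner: leftmost coordinate -2, opposite strand
  dp <- pl
  dp$start <- ifelse(pl$strand == "+", pl$start - 2L, pl$start + 2L)
  dp$end <- dp$start + dp$length - 1L
  dp$strand <- ifelse(pl$strand == "+", "-", "+")
  w1 <- scan_genome(pl, p, clen)
  w2 <- scan_genome(dp, p, clen)
  expect_equal(w1[c("contig", "start", "n", "k", "P", "U", "pvalue",
                    "max_phase_score")],
               w2[c("contig", "start", "n", "k", "P", "U", "pvalue",
                    "max_phase_score")])
})

test_that("genome scan anchors at occupied positions and finds implants", {
  p <- phase_params(21)
  clen <- c(chr1 = 5000L)
  pl <- phased_placements(anchor = 1001L, count = 5)
  w <- scan_genome(pl, p, clen)
  at <- w[w$start == 1001L, ]
  expect_equal(nrow(at), 1L)
  expect_equal(at$n, 10L); expect_equal(at$k, 10L)
  expect_equal(min(w$pvalue), at$pvalue)

  expect_equal(nrow(scan_genome(pl[0, ], p, clen)), 0L)

  single <- pl[1, ]
  w1 <- scan_genome(single, p, clen)
  expect_equal(nrow(w1), 1L)
  expect_equal(w1$n, 1L); expect_equal(w1$k, 1L)
  # anchored windows are tested conditionally on the anchor slot:
  # a lone read carries no evidence beyond itself
  expect_equal(w1$pvalue, 1)

  # windows overlapping the contig end are dropped
  tail_read <- pl[1, ]; tail_read$start <- 4900L; tail_read$end <- 4920L
  expect_equal(nrow(scan_genome(tail_read, p, clen)), 0L)
})

test_that("reads of other lengths are excluded from a scan", {
  p <- phase_params(21)
  pl <- phased_placements(anchor = 101L, count = 5)
  off <- pl[1, ]; off$length <- 24L; off$sequence <- "L24"
  wc <- window_counts(rbind(pl, off), 101L, p)
  expect_equal(wc$n, 10L)
})

test_that("candidate windows are null-calibrated on uniform placements", {
  set.seed(7)
  p <- phase_params(21)
  clen <- c(chr1 = 30000L)
  pl <- uniform_placements(1500, 29000L)
  w <- scan_genome(pl, p, clen)
  expect_gt(nrow(w), 500)
  for (alpha in c(0.05)) {
    frac <- mean(w$pvalue < alpha)
    se <- sqrt(alpha * (1 - alpha) / nrow(w))
    expect_lte(frac, alpha + 3 * se)
  }
})
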