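# Synthetic-data generator: random genomes with implanted phased loci,
# duplex-partner reads, miRNA trigger sites with degradome cleavage
# signatures, TAS3-like dual-site architectures, repeat-derived and
# uniform background reads, and a truth table for every implanted feature.

#' Simulation configuration
#'
#' The defaults define the study conditions exercised by the test-suite:
#' a 100-kb two-contig genome, five 21-nt and two 24-nt implanted PHAS
#' loci of ten cycles each, nine libraries grouped as three tissues,
#' log-normal phased abundances around 20 reads per position per library,
#' 50 background reads/kb and one TAS3-like locus.
#'
#' @param seed integer RNG seed; identical configs reproduce identical
#'   output byte-for-byte.
#' @param genome_length total genome size in nt.
#' @param n_contigs number of contigs (genome split evenly).
#' @param gc_content GC fraction in (0, 1).
#' @param n_phas_21,n_phas_24 implanted PHAS loci per cycle class.
#' @param cycles_per_locus phase cycles per implanted locus (>= 4).
#' @param phased_read_abundance mean read count per phased position per
#'   library (log-normal, sdlog 0.5).
#' @param n_libraries sRNA libraries; 9 yields root/leaf/flower x 3.
#' @param background_read_density unphased reads per kb of genome.
#' @param background_abundance Poisson mean of background read counts.
#' @param repeat_fraction fraction of background reads copied from the
#'   repeat set instead of the genome.
#' @param trigger_mirna_length trigger miRNA length (default 22).
#' @param degradome_signal degradome read count at true cleavage positions.
#' @param degradome_noise_density degradome noise reads per kb of
#'   transcript.
#' @param n_tas3_like implanted loci with two miR390-style sites flanking
#'   tasiARF payloads.
#' @param tasiarfs tasiARF payload sequences (named character); default:
#'   the synthetic stand-in set shipped with the package.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L, genome_length = 100000L, n_contigs = 2L,
                       gc_content = 0.42, n_phas_21 = 5L, n_phas_24 = 2L,
                       cycles_per_locus = 10L, phased_read_abundance = 20,
                       n_libraries = 9L, background_read_density = 50,
                       background_abundance = 2,
                       repeat_fraction = 0.1, trigger_mirna_length = 22L,
                       degradome_signal = 10, degradome_noise_density = 5,
                       n_tas3_like = 1L, tasiarfs = NULL) {
  cfg <- list(seed = as.integer(seed),
              genome_length = as.integer(genome_length),
              n_contigs = as.integer(n_contigs), gc_content = gc_content,
              n_phas_21 = as.integer(n_phas_21),
              n_phas_24 = as.integer(n_phas_24),
              cycles_per_locus = as.integer(cycles_per_locus),
              phased_read_abundance = phased_read_abundance,
              n_libraries = as.integer(n_libraries),
              background_read_density = background_read_density,
              background_abundance = background_abundance,
              repeat_fraction = repeat_fraction,
              trigger_mirna_length = as.integer(trigger_mirna_length),
              degradome_signal = degradome_signal,
              degradome_noise_density = degradome_noise_density,
              n_tas3_like = as.integer(n_tas3_like),
              tasiarfs = tasiarfs)
  counts <- cfg[c("genome_length", "n_contigs", "n_phas_21", "n_phas_24",
                  "cycles_per_locus", "n_libraries", "n_tas3_like",
                  "trigger_mirna_length")]
  if (any(unlist(counts) < 0L)) stop("all counts must be >= 0")
  if (cfg$gc_content <= 0 || cfg$gc_content >= 1)
    stop("gc_content must lie in (0, 1)")
  if (cfg$cycles_per_locus < 4L)
    stop("cycles_per_locus must be >= 4 (phase score needs k >= 3)")
  if (cfg$n_libraries < 1L) stop("need at least one library")
  structure(cfg, class = "sim_config")
}

sim_library_names <- function(n) {
  if (n == 9L) {
    paste0(rep(c("root", "leaf", "flower"), each = 3L), 1:3)
  } else {
    sprintf("lib%02d", seq_len(n))
  }
}

#' The tasiARF stand-in set shipped with the package
#'
#' Synthetic 21-nt payload sequences used as default tasiARF payloads by
#' the simulator (see `inst/extdata/tasiarf_synthetic.fa`). These are
#' stand-ins, not the conserved Arabidopsis/rice tasiARFs; supply your own
#' FASTA for real analyses.
#'
#' @return named character vector.
#' @export
default_tasiarfs <- function() {
  path <- system.file("extdata", "tasiarf_synthetic.fa",
                      package = "phasikit")
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

rand_dna <- function(n, gc) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

str_write <- function(s, at, what) {
  # overwrite s[at .. at+nchar(what)-1] with `what`
  substr(s, at, at + nchar(what) - 1L) <- what
  s
}

# non-overlapping placement of `widths` intervals inside [lo, hi] per
# contig, with `pad` nt of clearance; errors when no room is found
place_intervals <- function(widths, contig_lengths, pad = 300L,
                            margin = 260L, tries = 500L) {
  taken <- lapply(contig_lengths, function(...) {
    data.frame(s = integer(0), e = integer(0))
  })
  ctgs <- names(contig_lengths)
  out <- data.frame(contig = character(0), start = integer(0))
  for (i in seq_along(widths)) {
    w <- widths[i]
    placed <- FALSE
    for (t in seq_len(tries)) {
      ctg <- ctgs[((i - 1L) + (t - 1L)) %% length(ctgs) + 1L]
      hi <- contig_lengths[[ctg]] - w - margin
      if (hi <= margin) next
      st <- sample.int(hi - margin, 1L) + margin
      tk <- taken[[ctg]]
      if (any(st <= tk$e + pad & st + w - 1L >= tk$s - pad)) next
      taken[[ctg]] <- rbind(tk, data.frame(s = st, e = st + w - 1L))
      out <- rbind(out, data.frame(contig = ctg, start = st))
      placed <- TRUE
      break
    }
    if (!placed)
      stop("genome too short to place requested loci without overlap")
  }
  out
}

#' Simulate a complete phasiRNA study bundle
#'
#' Generates a genome with implanted PHAS and TAS3-like loci, collapsed
#' sRNA libraries (phased reads on the plus strand plus their exact duplex
#' partners at leftmost coordinate `p - 2` on the minus strand, unphased
#' background, repeat-derived reads), precursor transcripts, trigger
#' miRNAs whose complementary sites cleave exactly at phased position 1,
#' degradome profiles with signal `degradome_signal` at every true
#' cleavage position, and a truth table.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, all files of the bundle
#'   are written there (genome.fa, reads_<lib>.fa, degradome.tsv,
#'   transcripts.fa, mirnas.fa, repeats.fa, tasiarfs.fa, truth.gff3,
#'   truth.json).
#' @return a `sim_bundle` list: `config`, `genome` (named character),
#'   `contig_lengths`, `libraries`, `reads` (collapsed data frame),
#'   `mirnas`, `repeats`, `tasiarfs`, `transcripts`, `transcript_map`,
#'   `degradome` (list of profiles), `truth` (data frame with
#'   comma-separated `phased_positions`).
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  libs <- sim_library_names(config$n_libraries)
  deg_libs <- c("deg_leaf", "deg_root")

  # --- genome -------------------------------------------------------------
  clen <- rep(config$genome_length %/% config$n_contigs, config$n_contigs)
  clen[1L] <- clen[1L] + config$genome_length %% config$n_contigs
  names(clen) <- sprintf("ctg%02d", seq_len(config$n_contigs))
  genome <- vapply(clen, rand_dna, "", gc = config$gc_content)

  # --- repeats and tasiARF payloads --------------------------------------
  repeats <- stats::setNames(
    vapply(1:5, function(i) rand_dna(500L, config$gc_content), ""),
    sprintf("repeat%02d", 1:5))
  tasiarfs <- config$tasiarfs %||% default_tasiarfs()

  # --- plan implants ------------------------------------------------------
  Ltrig <- config$trigger_mirna_length
  cyc <- config$cycles_per_locus
  n21 <- config$n_phas_21; n24 <- config$n_phas_24
  ntas <- config$n_tas3_like
  phas_cycles <- c(rep(21L, n21), rep(24L, n24))
  # footprint: trigger-site overhang (L-10 nt upstream of position 1)
  # plus cycles_per_locus full cycles
  widths <- c((Ltrig - 10L) + cyc * phas_cycles,
              rep(21L + cyc * 21L + 21L, ntas))
  places <- if (length(widths))
    place_intervals(widths, clen) else
      data.frame(contig = character(0), start = integer(0))

  mirnas <- character(0)
  truth <- list()
  phased_list <- list()
  mir390 <- rand_dna(21L, 0.5)
  mirnas["mir390_syn"] <- mir390

  n_phas <- n21 + n24
  for (i in seq_len(n_phas)) {
    cycle <- phas_cycles[i]
    ctg <- places$contig[i]
    st <- places$start[i]
    p0 <- st + (Ltrig - 10L)                  # phased position 1
    trig_name <- sprintf("mir_trig_%02d", i)
    trig <- rand_dna(Ltrig, 0.5)
    mirnas[trig_name] <- trig
    # complementary site: t_end opposite sRNA pos 10 is p0 + 9
    genome[[ctg]] <- str_write(genome[[ctg]], p0 - (Ltrig - 10L),
                               revcomp(trig))
    pp <- p0 + cycle * (seq_len(cyc) - 1L)
    truth[[length(truth) + 1L]] <- data.frame(
      locus_id = sprintf("sim_PHAS%d_%02d", cycle, i), contig = ctg,
      start = st, end = p0 + cyc * cycle - 1L, cycle = cycle,
      strand_of_trigger_site = "+", trigger_name = trig_name,
      class = "PHAS", phased_positions = paste(pp, collapse = ","))
    phased_list[[length(phased_list) + 1L]] <- pp
  }
  for (j in seq_len(ntas)) {
    i <- n_phas + j
    ctg <- places$contig[i]
    L0 <- places$start[i]
    p0 <- L0 + 21L
    c3 <- p0 + 21L * cyc                       # 3' site cleavage position
    genome[[ctg]] <- str_write(genome[[ctg]], L0, revcomp(mir390))
    # tasiARF payloads at two in-register phased positions
    pay <- tasiarfs[((2L * j - 2L):(2L * j - 1L)) %% length(tasiarfs) + 1L]
    genome[[ctg]] <- str_write(genome[[ctg]], p0 + 21L * (cyc - 4L),
                               substr(pay[[1L]], 1L, 21L))
    genome[[ctg]] <- str_write(genome[[ctg]], p0 + 21L * (cyc - 3L),
                               substr(pay[[2L]], 1L, 21L))
    genome[[ctg]] <- str_write(genome[[ctg]], c3 - 11L, revcomp(mir390))
    pp <- p0 + 21L * (seq_len(cyc) - 1L)
    truth[[length(truth) + 1L]] <- data.frame(
      locus_id = sprintf("sim_TAS3like_%02d", j), contig = ctg,
      start = L0, end = c3 + 9L, cycle = 21L,
      strand_of_trigger_site = "+", trigger_name = "mir390_syn",
      class = "TAS3-like", phased_positions = paste(pp, collapse = ","))
    phased_list[[length(phased_list) + 1L]] <- pp
  }
  truth <- rbind_all(truth)
  if (is.null(truth)) {
    truth <- data.frame(locus_id = character(0), contig = character(0),
                        start = integer(0), end = integer(0),
                        cycle = integer(0),
                        strand_of_trigger_site = character(0),
                        trigger_name = character(0), class = character(0),
                        phased_positions = character(0))
  }

  # --- sRNA reads (sequences extracted after all genome writes) ----------
  lib_reads <- stats::setNames(
    lapply(libs, function(...) list()), libs)
  add_read <- function(lib, seqs, counts) {
    lib_reads[[lib]][[length(lib_reads[[lib]]) + 1L]] <<-
      data.frame(sequence = seqs, count = counts)
  }
  for (r in seq_len(nrow(truth))) {
    ctg <- truth$contig[r]; cycle <- truth$cycle[r]
    pp <- as.integer(strsplit(truth$phased_positions[r], ",")[[1L]])
    plus_seq <- vapply(pp, function(p)
      genome_substr(genome, ctg, p, p + cycle - 1L), "")
    minus_seq <- revcomp(vapply(pp, function(p)
      genome_substr(genome, ctg, p - 2L, p + cycle - 3L), ""))
    for (lib in libs) {
      cnt_p <- pmax(1, round(stats::rlnorm(
        length(pp), log(config$phased_read_abundance), 0.5)))
      cnt_m <- pmax(1, round(stats::rlnorm(
        length(pp), log(config$phased_read_abundance), 0.5)))
      add_read(lib, c(plus_seq, minus_seq), c(cnt_p, cnt_m))
    }
  }

  n_bg <- round(config$background_read_density *
                  config$genome_length / 1000)
  if (n_bg > 0L) {
    bg_len <- sample(20:24, n_bg, replace = TRUE,
                     prob = c(.1, .35, .1, .1, .35))
    from_repeat <- stats::runif(n_bg) < config$repeat_fraction
    rc_flag <- stats::runif(n_bg) < 0.5
    src_rep <- sample.int(length(repeats), n_bg, replace = TRUE)
    src_ctg <- sample.int(length(clen), n_bg, replace = TRUE)
    bg_seq <- character(n_bg)
    for (b in seq_len(n_bg)) {
      if (from_repeat[b]) {
        rp <- repeats[[src_rep[b]]]
        st <- sample.int(nchar(rp) - bg_len[b] + 1L, 1L)
        bg_seq[b] <- substr(rp, st, st + bg_len[b] - 1L)
      } else {
        ctg <- names(clen)[src_ctg[b]]
        st <- sample.int(clen[[ctg]] - bg_len[b] + 1L, 1L)
        bg_seq[b] <- genome_substr(genome, ctg, st, st + bg_len[b] - 1L)
      }
    }
    flip <- !from_repeat & rc_flag
    bg_seq[flip] <- revcomp(bg_seq[flip])
    bg_lib <- libs[sample.int(length(libs), n_bg, replace = TRUE)]
    bg_cnt <- stats::rpois(n_bg, config$background_abundance)
    keep <- bg_cnt > 0
    for (lib in unique(bg_lib[keep])) {
      sel <- keep & bg_lib == lib
      add_read(lib, bg_seq[sel], bg_cnt[sel])
    }
  }
  reads <- collapse_reads(lapply(lib_reads, function(x) {
    if (length(x)) do.call(rbind, x) else
      data.frame(sequence = character(0), count = numeric(0))
  }))

  # --- transcripts and degradome -----------------------------------------
  transcripts <- character(0)
  tmap <- list()
  degr <- stats::setNames(lapply(deg_libs, function(...) list()), deg_libs)
  add_deg <- function(lib, txid, pos, count) {
    degr[[lib]][[length(degr[[lib]]) + 1L]] <<-
      data.frame(transcript = txid, pos = as.integer(pos), count = count)
  }
  for (r in seq_len(nrow(truth))) {
    ctg <- truth$contig[r]
    gs <- max(1L, truth$start[r] - 40L)
    ge <- min(clen[[ctg]], truth$end[r] + 40L)
    txid <- paste0("TX_", truth$locus_id[r])
    transcripts[txid] <- genome_substr(genome, ctg, gs, ge)
    tmap[[length(tmap) + 1L]] <- data.frame(
      transcript = txid, contig = ctg, g_start = gs, g_end = ge)
    # cleavage signature at phased position 1 (PHAS) or the 3' site (TAS3)
    pp <- as.integer(strsplit(truth$phased_positions[r], ",")[[1L]])
    cleave_g <- if (truth$class[r] == "TAS3-like")
      pp[length(pp)] + 21L else pp[1L]
    for (lib in deg_libs)
      add_deg(lib, txid, cleave_g - gs + 1L, config$degradome_signal)
  }
  # background transcripts; the first carries an implanted phasiRNA target
  for (b in 1:3) {
    txid <- sprintf("TX_bg_%02d", b)
    transcripts[txid] <- rand_dna(800L, config$gc_content)
  }
  if (n_phas >= 1L) {
    tgt_read <- genome_substr(genome, truth$contig[1L],
                              as.integer(strsplit(truth$phased_positions[1L],
                                                  ",")[[1L]])[1L],
                              as.integer(strsplit(truth$phased_positions[1L],
                                                  ",")[[1L]])[1L] +
                                truth$cycle[1L] - 1L)
    transcripts[["TX_bg_01"]] <- str_write(transcripts[["TX_bg_01"]], 100L,
                                           revcomp(tgt_read))
    t_end <- 100L + truth$cycle[1L] - 1L
    for (lib in deg_libs)
      add_deg(lib, "TX_bg_01", t_end - 9L, config$degradome_signal)
  }
  # degradome noise
  for (txid in names(transcripts)) {
    tl <- nchar(transcripts[[txid]])
    for (lib in deg_libs) {
      nn <- stats::rpois(1L, config$degradome_noise_density * tl / 1000)
      if (nn > 0L)
        add_deg(lib, txid, sample.int(tl, nn, replace = TRUE),
                sample(1:3, nn, replace = TRUE))
    }
  }
  degradome <- lapply(degr, function(x) {
    if (!length(x)) {
      return(data.frame(transcript = character(0), pos = integer(0),
                        count = numeric(0)))
    }
    df <- do.call(rbind, x)
    df <- stats::aggregate(count ~ transcript + pos, df, sum)
    sort_df(df[c("transcript", "pos", "count")], c("transcript", "pos"))
  })
  transcript_map <- rbind_all(tmap)
  if (is.null(transcript_map)) {
    transcript_map <- data.frame(transcript = character(0),
                                 contig = character(0),
                                 g_start = integer(0), g_end = integer(0))
  }

  families <- data.frame(
    id = names(transcripts),
    family = ifelse(grepl("^TX_bg_", names(transcripts)),
                    "background", "simulated_precursor"))

  bundle <- structure(list(
    config = config, genome = genome, contig_lengths = clen,
    libraries = libs, reads = reads, mirnas = mirnas, repeats = repeats,
    tasiarfs = tasiarfs, transcripts = transcripts,
    transcript_map = transcript_map, degradome = degradome,
    families = families, truth = truth), class = "sim_bundle")
  if (!is.null(out_dir)) write_sim_bundle(bundle, out_dir)
  bundle
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf(
    "phasikit sim bundle: %d contig(s) (%d nt), %d unique reads, %d implanted loci\n",
    length(x$genome), sum(x$contig_lengths), nrow(x$reads), nrow(x$truth)))
  invisible(x)
}

write_fasta_chr <- function(x, path) {
  s <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' Write every file of a simulation bundle
#'
#' @param bundle a `sim_bundle` from [simulate_dataset()].
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_sim_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  write_fasta_chr(bundle$genome, fp("genome.fa"))
  for (lib in bundle$libraries)
    write_collapsed_fasta(bundle$reads, fp(sprintf("reads_%s.fa", lib)),
                          library = lib)
  write_degradome(bundle$degradome, fp("degradome.tsv"))
  write_fasta_chr(bundle$transcripts, fp("transcripts.fa"))
  write_fasta_chr(bundle$mirnas, fp("mirnas.fa"))
  write_fasta_chr(bundle$repeats, fp("repeats.fa"))
  write_fasta_chr(bundle$tasiarfs, fp("tasiarfs.fa"))
  utils::write.table(bundle$transcript_map, fp("transcript_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth_gff3(bundle$truth, fp("truth.gff3"))
  jsonlite::write_json(
    list(config = unclass(bundle$config)[setdiff(names(bundle$config),
                                                 "tasiarfs")],
         truth = bundle$truth),
    fp("truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

truth_gff3 <- function(truth, path) {
  lines <- "##gff-version 3"
  if (nrow(truth)) {
    lines <- c(lines, sprintf(
      "%s\tphasikit_sim\tsiRNA_locus\t%d\t%d\t.\t%s\t.\tID=%s;class=%s;cycle=%d;trigger=%s",
      truth$contig, truth$start, truth$end, truth$strand_of_trigger_site,
      truth$locus_id, truth$class, truth$cycle, truth$trigger_name))
  }
  writeLines(lines, path)
  invisible(path)
}
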