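# End-to-end orchestration: filter -> map -> scan(21) -> scan(24) ->
# call -> extract -> triggers -> targets -> tas3 -> network, with a run
# manifest and structured per-stage logging.

#' Pipeline configuration
#'
#' Bundles the thresholds of the full analysis. Defaults follow the
#' standard PHAS-calling criteria: 10-cycle windows, 100-bp extension,
#' phase score strictly above 5 and BH-adjusted P below 0.05.
#'
#' @param cycles cycle classes to scan (default `c(21, 24)`).
#' @param window_cycles cycles per scan window (default 10).
#' @param score_min phase-score call threshold (exclusive; default 5).
#' @param fdr adjusted-P call threshold (exclusive; default 0.05).
#' @param extend_bp window extension (default 100).
#' @param p_extend significance gate for extension (default 0.05).
#' @param tasiarf_max_mm tasiARF alignment mismatch cap (default 2).
#' @param site_max_mm binding-site search ceiling (default 5).
#' @param n_permutations FPR permutations per called locus (default 1000;
#'   set to 0 to skip the FPR column).
#' @param seed seed for the FPR permutations.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cycles = c(21L, 24L), window_cycles = 10L,
                            score_min = 5, fdr = 0.05, extend_bp = 100L,
                            p_extend = 0.05, tasiarf_max_mm = 2L,
                            site_max_mm = 5, n_permutations = 1000L,
                            seed = 1L) {
  stopifnot(score_min > 0, fdr > 0, extend_bp > 0, p_extend > 0,
            tasiarf_max_mm >= 0, site_max_mm >= 0)
  structure(list(cycles = as.integer(cycles),
                 window_cycles = as.integer(window_cycles),
                 score_min = score_min, fdr = fdr,
                 extend_bp = as.integer(extend_bp), p_extend = p_extend,
                 tasiarf_max_mm = as.integer(tasiarf_max_mm),
                 site_max_mm = site_max_mm,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

stage_log <- function(stage, ...) {
  message(sprintf("[phasikit] %-10s %s", stage, sprintf(...)))
}

#' Run the full phasiRNA discovery pipeline
#'
#' Takes a simulation bundle (or an equivalent list assembled from real
#' inputs: `genome`, `contig_lengths`, `reads`, `repeats`, `mirnas`,
#' `transcripts`, `transcript_map`, `degradome`, `tasiarfs`) and runs
#' every stage, returning all result tables. Identical inputs and config
#' produce identical outputs.
#'
#' @param bundle input bundle (see [simulate_dataset()]).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for the exported files (loci GFF3 and
#'   BED, tables as TSV, phasiRNA FASTA, count matrix, run manifest JSON).
#' @return a `phasikit_result` list with elements `windows`, `merged`,
#'   `loci`, `phasirnas`, `count_matrix`, `triggers`, `targets`, `tas3`,
#'   `shared`, `network`, `placements`, and `manifest`.
#' @export
run_pipeline <- function(bundle, config = pipeline_config(),
                         out_dir = NULL) {
  t0 <- Sys.time()

  stage_log("filter", "%d unique reads in", nrow(bundle$reads))
  reads <- select_lengths(bundle$reads, config$cycles)
  stage_log("filter", "%d reads of length %s", nrow(reads),
            paste(config$cycles, collapse = "/"))
  reads <- filter_repeat_reads(reads, bundle$repeats)
  stage_log("filter", "%d reads after repeat filtering", nrow(reads))

  placements <- map_reads(reads, bundle$genome)
  stage_log("map", "%d exact placements", nrow(placements))

  all_windows <- list(); all_merged <- list()
  for (cyc in config$cycles) {
    params <- phase_params(cyc, config$window_cycles)
    win <- scan_genome(placements, params, bundle$contig_lengths)
    stage_log(sprintf("scan(%d)", cyc), "%d candidate windows", nrow(win))
    ext <- extend_windows(win, bundle$contig_lengths,
                          p_max = config$p_extend,
                          extend_bp = config$extend_bp)
    mrg <- merge_windows(ext)
    stage_log(sprintf("scan(%d)", cyc), "%d merged intervals", nrow(mrg))
    all_windows[[as.character(cyc)]] <- win
    all_merged[[as.character(cyc)]] <- mrg
  }
  windows <- rbind_all(unname(all_windows))
  merged <- adjust_pvalues(
    rbind_all(unname(all_merged)))

  loci <- call_loci(merged, score_min = config$score_min, fdr = config$fdr)
  stage_log("call", "%d PHAS loci", nrow(loci))
  if (nrow(loci) && config$n_permutations >= 100L) {
    loci$fpr <- vapply(seq_len(nrow(loci)), function(i) {
      estimate_fpr(loci[i, ], placements,
                   phase_params(loci$cycle[i], config$window_cycles),
                   n_permutations = config$n_permutations,
                   seed = config$seed + i)
    }, numeric(1L))
  } else {
    loci$fpr <- rep(NA_real_, nrow(loci))
  }

  phasirnas <- rbind_all(lapply(seq_len(nrow(loci)), function(i) {
    extract_phasirnas(loci[i, ], placements, reads,
                      phase_params(loci$cycle[i], config$window_cycles))
  }))
  if (is.null(phasirnas)) {
    phasirnas <- data.frame(name = character(0), d_name = character(0),
                            locus = character(0), sequence = character(0),
                            position = integer(0), strand = character(0),
                            length = integer(0))
    for (lib in attr(reads, "libraries") %||% character(0))
      phasirnas[[lib]] <- numeric(0)
    phasirnas$total_count <- numeric(0)
  }
  stage_log("extract", "%d phasiRNAs", nrow(phasirnas))
  count_matrix <- phasirna_count_matrix(phasirnas)

  have_deg <- !is.null(bundle$degradome) && length(bundle$degradome) > 0L
  triggers <- targets <- NULL
  if (have_deg) {
    triggers <- rbind_all(lapply(config$cycles, function(cyc) {
      select_trigger_candidates(
        bundle$mirnas, loci[loci$cycle == cyc, , drop = FALSE],
        bundle$transcripts, bundle$transcript_map, placements,
        bundle$degradome, phase_params(cyc, config$window_cycles),
        max_mismatches = config$site_max_mm)
    }))
    stage_log("triggers", "%d candidate triggers",
              if (is.null(triggers)) 0L else nrow(triggers))
    targets <- select_phasirna_targets(phasirnas, bundle$transcripts,
                                       bundle$degradome,
                                       max_mismatches = config$site_max_mm)
    targets <- classify_cis_trans(targets, loci, bundle$transcript_map,
                                  phasirnas = phasirnas,
                                  families = bundle$families)
    stage_log("targets", "%d degradome-supported targets", nrow(targets))
  } else {
    warning("no degradome profiles: trigger/target stages skipped",
            call. = FALSE)
  }

  tas3 <- NULL
  if (!is.null(bundle$tasiarfs) && length(bundle$tasiarfs)) {
    ta <- find_tasiarf_matches(bundle$tasiarfs, bundle$genome,
                               max_mismatches = config$tasiarf_max_mm)
    mir390 <- bundle$mirnas[grepl("390", names(bundle$mirnas))]
    if (length(mir390) == 0L) mir390 <- bundle$mirnas
    tas3 <- classify_tas3(ta, mir390, bundle$genome,
                          profiles = if (have_deg) bundle$degradome,
                          transcript_map = bundle$transcript_map)
    stage_log("tas3", "%d tasiARF matches, %d TAS3-like", nrow(ta),
              sum(tas3$matches$tas3_class == "TAS3-like"))
  }

  shared <- shared_phasirna_report(phasirnas)
  network <- if (!is.null(targets))
    export_network(phasirnas, targets) else
      export_network(phasirnas, data.frame(srna = character(0),
                                           transcript = character(0),
                                           target_class = character(0)))

  manifest <- list(
    package = "phasikit",
    version = as.character(utils::packageVersion("phasikit")),
    config = unclass(config),
    seed = config$seed,
    n_reads_in = nrow(bundle$reads), n_placements = nrow(placements),
    n_loci = nrow(loci), n_phasirnas = nrow(phasirnas),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  res <- structure(list(windows = windows, merged = merged, loci = loci,
                        phasirnas = phasirnas, count_matrix = count_matrix,
                        triggers = triggers, targets = targets,
                        tas3 = tas3, shared = shared, network = network,
                        placements = placements, manifest = manifest),
                   class = "phasikit_result")
  if (!is.null(out_dir)) write_pipeline_results(res, out_dir)
  res
}

#' @export
print.phasikit_result <- function(x, ...) {
  cat("phasikit pipeline result\n")
  cat(sprintf("  loci called:      %d\n", nrow(x$loci)))
  cat(sprintf("  phasiRNAs:        %d\n", nrow(x$phasirnas)))
  if (!is.null(x$triggers))
    cat(sprintf("  trigger sites:    %d\n", nrow(x$triggers)))
  if (!is.null(x$targets))
    cat(sprintf("  targets retained: %d\n", nrow(x$targets)))
  invisible(x)
}

#' Write every pipeline result table to a directory
#'
#' @param res a `phasikit_result`.
#' @param out_dir output directory.
#' @export
write_pipeline_results <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  wt <- function(df, f) {
    utils::write.table(df, fp(f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(res$windows, "windows.tsv")
  wt(res$merged, "merged_windows.tsv")
  wt(res$loci, "loci.tsv")
  wt(res$phasirnas[, setdiff(names(res$phasirnas), "sequence"),
                   drop = FALSE], "phasirna_table.tsv")
  utils::write.table(cbind(phasiRNA = rownames(res$count_matrix),
                           as.data.frame(res$count_matrix)),
                     fp("phasirna_counts.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (nrow(res$loci)) {
    export_loci_gff3(res$loci, fp("loci.gff3"), res$phasirnas)
    export_loci_bed(res$loci, fp("loci.bed"))
  }
  if (nrow(res$phasirnas))
    write_phasirna_fasta(res$phasirnas, fp("phasirnas.fa"))
  if (!is.null(res$triggers)) wt(res$triggers, "triggers.tsv")
  if (!is.null(res$targets)) wt(res$targets, "targets.tsv")
  if (!is.null(res$tas3)) {
    wt(res$tas3$matches, "tas3_matches.tsv")
    wt(res$tas3$sites, "tas3_mir390_sites.tsv")
  }
  wt(res$shared, "shared_phasirnas.tsv")
  wt(res$network, "network.tsv")
  manifest <- res$manifest
  manifest$file_md5 <- as.list(tools::md5sum(
    list.files(out_dir, full.names = TRUE)))
  names(manifest$file_md5) <- basename(names(manifest$file_md5))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}
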