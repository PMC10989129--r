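# End-to-end orchestration of the evolution-screening workflow:
# simulate a loxPsym-partitioned genome -> SCRaMbLE it -> sequence ->
# QC-filter -> map -> split-read call -> compare calls against ground truth.
# A single global seed derives per-stage seeds so every run is reproducible
# from one integer.

#' Default pipeline configuration
#'
#' One key-value document holding every stage parameter; unknown keys are
#' rejected. Defaults encode the published thresholds (min flank 15 bp,
#' min support 5, Phred 10, mining triple 1000/75/1000, 1.5-fold screen) and
#' the desk-scale study conditions (a ~20 kb toy chromosome with 10 loxPsym
#' sites, 30x PE100 reads at 0.1% substitution error).
#'
#' @param ... Named overrides of the defaults.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    # genome
    segment_lengths = c(1800L, 2100L, 1500L, 2400L, 1700L, 2000L, 1600L,
                        2300L, 1900L, 1500L, 1700L),
    loxpsym = loxpsym_sequence(),
    chrom_id = "chrSCR",
    # scramble
    n_events = 1L,
    type_probabilities = c(deletion = 0.5, inversion = 0.3,
                           tandem_duplication = 0.2),
    # sequencing
    coverage = 30,
    read_length = 100L,
    insert_mean = 350,
    insert_sd = 35,
    error_rate = 0.001,
    # qc
    min_mean_phred = 10,
    drop_if_any_n = TRUE,
    # mapping
    k = 21L,
    max_mismatch = 4L,
    # junction calling
    min_flank = 15L,
    max_site_mismatch = 2L,
    min_support = 5L,
    snap_tolerance = 2L,
    deletion_max_ratio = 0.25,
    duplication_min_ratio = 1.6,
    inversion_ratio_range = c(0.75, 1.25),
    # screening / mining defaults carried for reference
    fold_threshold = 1.5,
    min_bit_score = 1000,
    min_identity = 75,
    min_alignment_length = 1000,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown pipeline_config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, over)
  class(cfg) <- "pipeline_config"
  cfg
}

# Derive a per-stage seed from the global seed (kept below 2^31).
stage_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 1009 + stage * 7919) %% 2147483647)
}

#' Match event calls against ground truth
#'
#' A call matches a truth event when type and exact segment span agree.
#' Truth site coordinates are interpreted on the parental reference, so the
#' comparison is meaningful for independent (non-overlapping) events.
#'
#' @param events Event-call `data.frame` from [classify_events()].
#' @param truth Truth `data.frame` from [truth_events()].
#' @param reference The parental `lox_chromosome` (or list).
#' @return List with `n_truth`, `n_calls`, `n_matched`, `precision`,
#'   `recall`, and the annotated `truth` table.
#' @export
compare_calls_to_truth <- function(events, truth, reference) {
  chroms <- if (inherits(reference, "lox_chromosome")) list(reference) else reference
  names(chroms) <- vapply(chroms, `[[`, "", "id")
  if (nrow(truth)) {
    idx <- mapply(function(chr, s) match(s, chroms[[chr]]$loxpsym_starts) - 1L,
                  truth$chrom, truth$site_a)
    idx_b <- mapply(function(chr, s) match(s, chroms[[chr]]$loxpsym_starts) - 1L,
                    truth$chrom, truth$site_b)
    truth$seg_first <- idx + 1L
    truth$seg_last <- idx_b
  } else {
    truth$seg_first <- integer(0)
    truth$seg_last <- integer(0)
  }
  truth$matched <- logical(nrow(truth))
  used <- rep(FALSE, nrow(events))
  for (i in seq_len(nrow(truth))) {
    m <- which(!used & events$chrom == truth$chrom[i] &
               events$type == truth$type[i] &
               events$seg_first == truth$seg_first[i] &
               events$seg_last == truth$seg_last[i])
    if (length(m)) {
      used[m[1L]] <- TRUE
      truth$matched[i] <- TRUE
    }
  }
  n_truth <- nrow(truth); n_calls <- nrow(events); n_matched <- sum(used)
  list(n_truth = n_truth, n_calls = n_calls, n_matched = n_matched,
       precision = if (n_calls == 0L) ifelse(n_truth == 0L, 1, NA_real_)
                   else n_matched / n_calls,
       recall = if (n_truth == 0L) 1 else n_matched / n_truth,
       truth = truth)
}

#' Run the simulate-sequence-QC-map-call pipeline end to end
#'
#' Executes the full workflow on a seeded toy genome and reports the
#' truth-versus-called comparison. With `events` supplied, those exact events
#' are applied instead of random SCRaMbLE draws. All outputs are standard
#' formats (FASTA, BED, FASTQ, TSV) when `out_dir` is given.
#'
#' @param config A [pipeline_config()].
#' @param events Optional list of [scramble_event()]s to apply verbatim.
#' @param out_dir Optional output directory for the intermediate files, the
#'   events table and the report.
#' @return List with `reference`, `rearranged`, `truth`, `calls` (the events
#'   table), `comparison`, `depth`, `filter_stats`, `diagnostics`, `report`
#'   (character vector), and `files` (paths written, if any).
#' @export
run_end_to_end <- function(config = pipeline_config(), events = NULL,
                           out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  reference <- build_toy_genome(config$segment_lengths,
                                loxpsym = config$loxpsym,
                                id = config$chrom_id,
                                seed = stage_seed(config$seed, 1L))
  if (is.null(events)) {
    rearranged <- random_scramble(reference, config$n_events,
                                  type_probabilities = config$type_probabilities,
                                  seed = stage_seed(config$seed, 2L))
  } else {
    rearranged <- as_rearranged(reference)
    for (e in events) rearranged <- apply_event(rearranged, e)
  }
  truth <- truth_events(rearranged)
  pairs <- simulate_read_pairs(rearranged, coverage = config$coverage,
                               read_length = config$read_length,
                               insert_mean = config$insert_mean,
                               insert_sd = config$insert_sd,
                               error_rate = config$error_rate,
                               seed = stage_seed(config$seed, 3L))
  res <- call_events(pairs, reference,
                     min_mean_phred = config$min_mean_phred,
                     drop_if_any_n = config$drop_if_any_n,
                     k = config$k, max_mismatch = config$max_mismatch,
                     min_flank = config$min_flank,
                     max_site_mismatch = config$max_site_mismatch,
                     min_support = config$min_support,
                     snap_tolerance = config$snap_tolerance,
                     thresholds = list(
                       deletion_max_ratio = config$deletion_max_ratio,
                       duplication_min_ratio = config$duplication_min_ratio,
                       inversion_ratio_range = config$inversion_ratio_range))
  cmp <- compare_calls_to_truth(res$events, truth, reference)
  report <- c(
    sprintf("reference: %s, %d bp, %d loxPsym sites", reference$id,
            nchar(reference$sequence), length(reference$loxpsym_starts)),
    sprintf("simulated events: %d; rearranged length: %d bp", nrow(truth),
            nchar(rearranged_sequence(rearranged))),
    sprintf("read pairs simulated: %d; removed by QC: %d (%.2f%%)",
            res$filter_stats$pairs_in,
            res$filter_stats$pairs_removed_quality + res$filter_stats$pairs_removed_n,
            100 * res$filter_stats$fraction_removed),
    sprintf("supported junctions: %d; event calls: %d", nrow(res$junctions),
            nrow(res$events)),
    sprintf("truth events matched: %d / %d (recall %.2f, precision %.2f)",
            cmp$n_matched, cmp$n_truth, cmp$recall,
            ifelse(is.na(cmp$precision), 1, cmp$precision)),
    if (nrow(res$events)) {
      sprintf("  call: %s segments %d-%d support %d copy-ratio %.2f %s",
              res$events$type, res$events$seg_first, res$events$seg_last,
              res$events$support, res$events$mean_copy_ratio, res$events$notes)
    } else "  (no calls)"
  )
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      ref = write_genome_fasta(reference, file.path(out_dir, "reference.fa")),
      sites = write_sites_bed(reference, file.path(out_dir, "sites.bed")),
      donor = write_genome_fasta(rearranged, file.path(out_dir, "rearranged.fa")),
      truth = write_truth_events(truth, file.path(out_dir, "truth_events.tsv")),
      events = write_tsv(res$events, file.path(out_dir, "events.tsv")),
      junctions = write_tsv(res$junctions, file.path(out_dir, "junctions.tsv")),
      depth = write_tsv(res$depth, file.path(out_dir, "depth.tsv")),
      report = {
        p <- file.path(out_dir, "report.txt")
        writeLines(report, p)
        p
      }
    )
    fq <- write_read_pairs_fastq(pairs, file.path(out_dir, "reads_1.fastq"),
                                 file.path(out_dir, "reads_2.fastq"))
    files <- c(files, r1 = fq[1], r2 = fq[2])
  }
  list(reference = reference, rearranged = rearranged, truth = truth,
       calls = res$events, comparison = cmp, depth = res$depth,
       junctions = res$junctions, filter_stats = res$filter_stats,
       diagnostics = res$diagnostics, report = report, files = files)
}
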