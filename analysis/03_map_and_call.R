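#!/usr/bin/env Rscript
# Stage 3: map the QC-passed reads against the parental reference, profile
# per-segment depth, call junctions from loxPsym split reads, classify the
# SCRaMbLE events, and compare them with the ground truth from stage 1.

suppressMessages({library(scramblesv); library(Biostrings)})
seed <- 20231226

# rebuild the parental chromosome object (stage 1 is deterministic in `seed`)
# and recover its gene annotation from the BED written alongside it
cfg <- pipeline_config(seed = seed)
bed <- read.table("results/parental_sites.bed", sep = "\t",
                  col.names = c("chrom", "start", "end", "name"))
genes <- bed[!grepl("^loxPsym_", bed$name), ]
genes <- data.frame(name = genes$name, start = genes$start, end = genes$end,
                    strand = "+")
ref <- build_toy_genome(cfg$segment_lengths, genes = genes, seed = seed)
stopifnot(identical(
  as.character(readDNAStringSet("results/parental.fa")[[1]]), ref$sequence))

pairs <- read_read_pairs_fastq("results/reads_1.fastq", "results/reads_2.fastq")
res <- call_events(pairs, ref)

cat("alignment diagnostics (split-read stage):\n")
print(res$diagnostics)
cat("\nper-segment copy ratios:\n")
print(res$depth[, c("segment", "mean_depth", "copy_ratio")], digits = 3)
cat("\nsupported junctions:\n")
print(res$junctions)
cat("\nevent calls:\n")
print(res$events)

truth <- read.table("results/truth_events.tsv", sep = "\t", header = TRUE)
cmp <- compare_calls_to_truth(res$events, truth, ref)
cat(sprintf("\ntruth events: %d, calls: %d, matched: %d (precision %.2f, recall %.2f)\n",
            cmp$n_truth, cmp$n_calls, cmp$n_matched, cmp$precision, cmp$recall))

tsv <- function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                         row.names = FALSE)
tsv(res$events, "results/events.tsv")
tsv(res$junctions, "results/junctions.tsv")
tsv(res$depth, "results/depth_profile.tsv")
cat("wrote results/events.tsv, junctions.tsv, depth_profile.tsv\n")
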