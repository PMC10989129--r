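#!/usr/bin/env Rscript
# Stage 2: simulate PE100 sequencing of the rearranged molecule (30x, 0.1%
# substitution error, with a slice of deliberately contaminated reads) and
# apply the QC rule: pairs with a mate of mean Phred < 10 or any N are
# dropped. Writes paired FASTQ and the filter statistics.

suppressMessages({library(scramblesv); library(Biostrings)})
seed <- 20231226

donor <- local({
  x <- readDNAStringSet("results/rearranged.fa")
  setNames(as.character(x), names(x))
})
pairs <- simulate_read_pairs(donor, coverage = 30, error_rate = 0.001,
                             seed = seed + 2,
                             low_quality_fraction = 0.05,
                             n_base_fraction = 0.02)
cat(sprintf("simulated %d read pairs (%d bp genome at 30x)\n",
            nrow(pairs), nchar(donor[[1]])))

flt <- filter_read_pairs(pairs, min_mean_phred = 10, drop_if_any_n = TRUE)
print(flt$stats)
stopifnot(flt$stats$fraction_removed < 0.15)  # the preprocessing sanity bound

write_read_pairs_fastq(flt$pairs, "results/reads_1.fastq",
                       "results/reads_2.fastq",
                       truth_path = "results/read_truth.tsv")
write_filter_stats(flt$stats, "results/filter_stats.tsv")
cat("wrote results/reads_[12].fastq, read_truth.tsv, filter_stats.tsv\n")
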