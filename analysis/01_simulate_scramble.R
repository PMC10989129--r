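#!/usr/bin/env Rscript
# Stage 1: build the parental toy chromosome (~20 kb, 10 loxPsym sites, one
# annotated gene per segment) and SCRaMbLE it. Writes the parental FASTA +
# BED, the rearranged FASTA, and the ground-truth event table under results/.

suppressMessages(library(scramblesv))

dir.create("results", showWarnings = FALSE)
seed <- 20231226

cfg <- pipeline_config(seed = seed)
genes <- local({
  # one synthetic gene centered in each segment, named after the archetypal
  # SCRaMbLE targets plus fillers
  sm_lengths <- cfg$segment_lengths
  starts <- cumsum(c(0, head(sm_lengths, -1) + 34))
  data.frame(name = c("LSB3", "MIC19", "YFR010W-A", "ECM15", "CEN6",
                      sprintf("FIL%03d", 1:6)),
             start = as.integer(starts + floor(sm_lengths / 4)),
             end = as.integer(starts + floor(3 * sm_lengths / 4)),
             strand = rep(c("+", "-"), length.out = 11))
})
ref <- build_toy_genome(cfg$segment_lengths, genes = genes, seed = seed)
cat(sprintf("parental chromosome: %d bp, %d loxPsym sites, %d genes\n",
            nchar(ref$sequence), length(ref$loxpsym_starts), nrow(ref$genes)))

# the two-target archetype: delete the MIC19-bearing segment (segment 1)
# and tandem-duplicate the ECM15-bearing segment (segment 3); applied
# downstream-first so both events can be stated in parental coordinates
# (random_scramble() draws random events instead when exploring)
s <- ref$loxpsym_starts
rearranged <- apply_event(ref, scramble_event("tandem_duplication", s[3], s[4]))
rearranged <- apply_event(rearranged, scramble_event("deletion", s[1], s[2]))
truth <- truth_events(rearranged)
cat(sprintf("applied %d SCRaMbLE events:\n", nrow(truth)))
print(truth)
cat(sprintf("rearranged molecule: %d bp (parental %d bp)\n",
            nchar(rearranged_sequence(rearranged)), nchar(ref$sequence)))

write_genome_fasta(ref, "results/parental.fa")
write_sites_bed(ref, "results/parental_sites.bed")
write_genome_fasta(rearranged, "results/rearranged.fa")
write_truth_events(truth, "results/truth_events.tsv")
cat("wrote results/parental.fa, parental_sites.bed, rearranged.fa, truth_events.tsv\n")
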