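#!/usr/bin/env Rscript
# Stage 4: the enzyme-mining filter chain on a synthetic similarity-search
# table — strict 1000/75/1000 thresholds plus the MIA-family whitelist — then
# longest-ORF extraction from the surviving subject sequences, and the two
# protein-engineering operations (N-terminal chimera, RR-motif truncation)
# on ORF-derived proteins.

suppressMessages(library(scramblesv))
dir.create("results", showWarnings = FALSE)
seed <- 20231226

hits <- simulate_homolog_hits(500, seed = seed + 4)
write_homolog_hits(hits, "results/homolog_hits.tsv")
kept <- filter_homolog_hits(read_homolog_hits("results/homolog_hits.tsv"))
cat(sprintf("hits: %d in, %d pass bit>1000 & id>75 & len>1000 & MIA family\n",
            nrow(hits), nrow(kept)))

orfs <- lapply(kept$subject_seq, longest_orf)
has_orf <- !vapply(orfs, is.null, logical(1))
cat(sprintf("complete ORFs found in %d / %d passing subjects\n",
            sum(has_orf), nrow(kept)))
orf_tab <- do.call(rbind, lapply(which(has_orf), function(i) {
  o <- orfs[[i]]
  data.frame(subject = kept$subject[i], family = kept$family[i],
             strand = o$strand, start = o$start, end = o$end,
             orf_nt = o$length, protein_aa = nchar(o$protein))
}))
utils::write.table(orf_tab, "results/mined_orfs.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
proteins <- vapply(orfs[has_orf], `[[`, "", "protein")
names(proteins) <- kept$subject[has_orf]
Biostrings::writeXStringSet(Biostrings::AAStringSet(proteins),
                            "results/mined_proteins.fa")

# N-terminal swap between the two longest mined proteins (the ceCrG8H/ceTeG8H
# construction: first 29 residues exchanged)
if (sum(has_orf) >= 2) {
  top2 <- names(sort(nchar(proteins), decreasing = TRUE))[1:2]
  a <- proteins[[top2[1]]]; b <- proteins[[top2[2]]]
  ce_a <- make_chimera(b, a, 29)
  ce_b <- make_chimera(a, b, 29)
  cat(sprintf("chimeras: %s(N,1-29)+%s -> %d aa; %s(N,1-29)+%s -> %d aa\n",
              top2[2], top2[1], nchar(ce_a), top2[1], top2[2], nchar(ce_b)))
  stopifnot(nchar(ce_a) == nchar(a), nchar(ce_b) == nchar(b))
}

# RR-motif truncation of a synthetic plastid-targeted synthase (motif at 88,
# mirroring the 2-87 aa truncation span)
set.seed(seed)
aa_no_r <- strsplit("ACDEFGHIKLMNPQSTVWY", "")[[1]]
ges <- paste(c("M", sample(aa_no_r, 86, TRUE), "RR",
               sample(aa_no_r, 460, TRUE)), collapse = "")
tges <- truncate_at_rr(ges)
cat(sprintf("GES-like protein %d aa -> truncated %d aa (removed residues 2-%d)\n",
            nchar(ges), nchar(tges), nchar(ges) - nchar(tges) + 1))
cat("wrote results/homolog_hits.tsv, mined_orfs.tsv, mined_proteins.fa\n")
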