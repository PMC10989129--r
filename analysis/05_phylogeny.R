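#!/usr/bin/env Rscript
# Stage 5: family tree of the mined homologs — p-distances (pairwise
# deletion) from a protein alignment and a neighbor-joining tree written as
# Newick. The alignment is simulated along a known tree so the reconstruction
# can be judged against its generator.

suppressMessages(library(scramblesv))
dir.create("results", showWarnings = FALSE)
seed <- 20231226

sim <- simulate_protein_alignment(18, n_sites = 450, seed = seed + 5)
Biostrings::writeXStringSet(Biostrings::AAStringSet(sim$alignment),
                            "results/g8h_alignment.fa")

D <- p_distance_matrix("results/g8h_alignment.fa")
write_distance_matrix(D, "results/g8h_pdist.tsv")
cat(sprintf("p-distances over %d taxa: range %.3f-%.3f\n",
            nrow(D), min(D[upper.tri(D)]), max(D[upper.tri(D)])))

tree <- nj_tree(D)
write_newick(tree, "results/g8h_nj.nwk")
rf <- ape::dist.topo(ape::unroot(tree), ape::unroot(sim$tree))
cat(sprintf("NJ tree: %d tips; Robinson-Foulds distance to the generating tree: %d\n",
            length(tree$tip.label), rf))
cat("wrote results/g8h_alignment.fa, g8h_pdist.tsv, g8h_nj.nwk\n")
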