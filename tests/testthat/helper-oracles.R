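# Independent oracles used across the suite. Each one deliberately avoids the
# code path of the function it checks: the mapper is checked against a full
# shifted-comparison Hamming profile, the ORF finder against a position-by-
# position codon walk, NJ against path lengths on trees the matrices were
# generated from, and counting rules against plain loops.

# --- brute-force aligner oracle ---------------------------------------------

# Precompute, for a reference molecule and query length l, the l shifted
# genome slices so profiles over many same-length queries reuse them.
brute_slices <- function(G, l) {
  P <- length(G) - l + 1L
  lapply(seq_len(l), function(j) G[j:(j + P - 1L)])
}

# All placements of `query` with Hamming distance <= max_mm, over both strands
# of every reference molecule, by exhaustive scan. `slices` optionally carries
# precomputed shifted slices per molecule (same query length throughout).
brute_force_placements <- function(query, reference, max_mm, slices = NULL) {
  rows <- list()
  l <- nchar(query)
  for (nm in names(reference)) {
    G <- utf8ToInt(reference[[nm]])
    if (l > length(G)) next
    sl <- if (is.null(slices)) brute_slices(G, l) else slices[[nm]]
    for (strand in c("+", "-")) {
      q <- utf8ToInt(if (strand == "+") query else revcomp(query))
      mm <- (sl[[1L]] != q[1L])
      for (j in 2:l) {
        mm <- mm + (sl[[j]] != q[j])
      }
      hit <- which(mm <= max_mm)
      if (length(hit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = nm, start = hit - 1L, strand = strand,
          mismatches = as.integer(mm[hit]), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = integer(0),
               strand = character(0), mismatches = integer(0))
}

# Best placements + status under the same reporting convention as the mapper.
brute_force_best <- function(query, reference, max_mm, slices = NULL) {
  p <- brute_force_placements(query, reference, max_mm, slices = slices)
  if (!nrow(p)) {
    return(list(status = "unmapped", placements = p))
  }
  p <- p[p$mismatches == min(p$mismatches), , drop = FALSE]
  p <- p[order(p$chrom, p$start, match(p$strand, c("+", "-"))), , drop = FALSE]
  rownames(p) <- NULL
  list(status = if (nrow(p) == 1L) "unique" else "multi", placements = p)
}

# --- brute-force ORF oracle --------------------------------------------------

# Walk codon-by-codon from every ATG on one strand; return all complete spans.
orf_walk_one_strand <- function(s) {
  L <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  spans <- list()
  for (i in seq_len(max(L - 5L, 0L))) {          # 1-based start of a codon
    if (substr(s, i, i + 2L) != "ATG") next
    j <- i
    while (j + 2L <= L) {
      codon <- substr(s, j, j + 2L)
      if (j > i && codon %in% stops) {
        spans[[length(spans) + 1L]] <- c(start = i - 1L, end = j + 2L)
        break
      }
      j <- j + 3L
    }
  }
  if (length(spans)) as.data.frame(do.call(rbind, spans)) else
    data.frame(start = integer(0), end = integer(0))
}

# Longest ATG..stop span over 6 frames with the package's tie-break rule,
# reported in input coordinates; NULL if none.
brute_force_orf <- function(s, both = TRUE) {
  L <- nchar(s)
  f <- orf_walk_one_strand(s)
  if (nrow(f)) {
    f$strand <- "+"
    f$orig_start <- f$start
  }
  cand <- f
  if (both) {
    r <- orf_walk_one_strand(revcomp(s))
    if (nrow(r)) {
      r$strand <- "-"
      r$orig_start <- L - r$end
      cand <- rbind(cand, r)
    }
  }
  if (!nrow(cand)) return(NULL)
  cand$len <- cand$end - cand$start
  cand <- cand[cand$len == max(cand$len), , drop = FALSE]
  prot_of <- function(b) {
    region <- if (b$strand == "+") substr(s, b$start + 1L, b$end) else
      substr(revcomp(s), b$start + 1L, b$end)
    as.character(Biostrings::translate(
      Biostrings::DNAString(substr(region, 1L, nchar(region) - 3L)),
      no.init.codon = TRUE))
  }
  proteins <- vapply(seq_len(nrow(cand)), function(i) prot_of(cand[i, ]), "")
  o <- order(proteins, cand$strand != "+", cand$orig_start)
  b <- cand[o[1L], ]
  list(strand = b$strand, start = b$orig_start, end = b$orig_start + b$len,
       length = b$len, protein = proteins[o[1L]])
}

# --- phylogeny helpers -------------------------------------------------------

# Random additive distance matrix from a random tree; returns both.
random_additive_matrix <- function(n_taxa, seed) {
  set.seed(seed)
  tree <- ape::rtree(n_taxa, rooted = FALSE,
                     br = function(k) runif(k, 0.1, 1))
  D <- ape::cophenetic.phylo(tree)
  o <- sort(rownames(D))
  list(tree = tree, D = D[o, o])
}

same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

# --- misc --------------------------------------------------------------------

# A small deterministic read_pairs table built by hand.
manual_pair <- function(id, seq1, qual1, seq2, qual2) {
  p <- data.frame(id = id, seq1 = seq1, qual1 = qual1, seq2 = seq2,
                  qual2 = qual2, chrom = NA_character_, start1 = NA_integer_,
                  strand1 = NA_character_, start2 = NA_integer_,
                  strand2 = NA_character_, stringsAsFactors = FALSE)
  class(p) <- c("read_pairs", "data.frame")
  p
}

qual_of <- function(phred, n) strrep(intToUtf8(phred + 33L), n)
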