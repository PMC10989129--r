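# Canonical one-string-per-query serialization of placement sets, so oracle
# agreement can be asserted in bulk (one expectation per genome) instead of
# per read.
placement_string <- function(p) {
  if (!nrow(p)) return("unplaced")
  p <- p[order(p$chrom, p$start, match(p$strand, c("+", "-"))), , drop = FALSE]
  paste(sprintf("%s:%d%s/%d", p$chrom, p$start, p$strand, p$mismatches),
        collapse = ";")
}

# Per-query placement strings for a mapper result (align_sequences output).
mapper_placement_strings <- function(aln) {
  pl <- attr(aln, "placements")
  by_q <- split(pl, factor(pl$query, levels = aln$query))
  vapply(by_q, placement_string, "")
}

# Per-query placement strings and statuses from the brute-force oracle, for a
# batch of equal-length reads. The scan is a full Hamming profile of every
# read against every genome position on both strands, computed as a
# position-by-read mismatch matrix: for each read offset j the genome slice
# is compared once per distinct base and added into the columns carrying that
# base, so the enumeration stays exhaustive while the inner work is vectorized.
brute_placement_strings <- function(reads, ref, max_mm) {
  l <- nchar(reads[[1L]])
  stopifnot(all(nchar(reads) == l))
  fwd <- unname(reads)
  rcs <- revcomp(fwd)
  n <- length(reads)
  hit_q <- integer(0); hit_chrom <- character(0)
  hit_start <- integer(0); hit_strand <- character(0); hit_mm <- integer(0)
  for (nm in names(ref)) {
    G <- utf8ToInt(ref[[nm]])
    if (l > length(G)) next
    P <- length(G) - l + 1L
    GS <- brute_slices(G, l)
    chunk <- max(1L, min(n, as.integer(4e6 %/% P)))
    for (st in c("+", "-")) {
      M <- matrix(utf8ToInt(paste(if (st == "+") fwd else rcs, collapse = "")),
                  nrow = l)
      for (cs in split(seq_len(n), ceiling(seq_len(n) / chunk))) {
        MM <- matrix(0L, P, length(cs))
        for (j in seq_len(l)) {
          row <- M[j, cs]
          for (b in unique(row)) {
            cols <- which(row == b)
            MM[, cols] <- MM[, cols] + (GS[[j]] != b)
          }
        }
        h <- which(MM <= max_mm, arr.ind = TRUE)
        if (nrow(h)) {
          hit_q <- c(hit_q, cs[h[, 2L]])
          hit_chrom <- c(hit_chrom, rep(nm, nrow(h)))
          hit_start <- c(hit_start, h[, 1L] - 1L)
          hit_strand <- c(hit_strand, rep(st, nrow(h)))
          hit_mm <- c(hit_mm, MM[h])
        }
      }
    }
  }
  status <- rep("unmapped", n)
  pstr <- rep("unplaced", n)
  for (qi in unique(hit_q)) {
    sel <- hit_q == qi
    mmv <- hit_mm[sel]; keep <- mmv == min(mmv)
    chrom <- hit_chrom[sel][keep]; start <- hit_start[sel][keep]
    strand <- hit_strand[sel][keep]; mmv <- mmv[keep]
    o <- order(chrom, start, match(strand, c("+", "-")))
    status[qi] <- if (sum(keep) == 1L) "unique" else "multi"
    pstr[qi] <- paste(sprintf("%s:%d%s/%d", chrom[o], start[o], strand[o],
                              mmv[o]), collapse = ";")
  }
  list(status = status, placements = pstr)
}
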