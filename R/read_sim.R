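# Paired-end read simulator (PE100 by default) with a constant-Phred
# substitution error model, emulating short-insert WGS of a (rearranged)
# genome. Fragment starts are uniform (no GC bias), insert sizes are
# truncated-normal, mate 2 is sequenced from the reverse strand of the
# fragment, and per-base substitution probability equals the rate implied by
# the emitted Phred value, so quality strings are honest.

# Truncated-normal sampler on [lo, hi] by vectorized rejection.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# Substitute bases at given flat indices of a character matrix of reads
# (one column per read is NOT used; reads kept as strings, mutated in place).
inject_substitutions <- function(seqs, p) {
  n <- length(seqs)
  if (n == 0L || all(p == 0)) return(seqs)
  len <- nchar(seqs)
  n_err <- stats::rbinom(n, len, p)
  hit <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(len[i], n_err[i])
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    for (pp in pos) {
      ch[pp] <- sample(setdiff(bases, ch[pp]), 1L)
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

inject_n_bases <- function(seqs, n_per_read = 2L) {
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    pos <- sample.int(length(ch), min(n_per_read, length(ch)))
    ch[pos] <- "N"
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Simulate paired-end reads from a genome
#'
#' The pair count per molecule is `ceiling(coverage * length / (2 *
#' read_length))`. Insert sizes follow a normal distribution truncated to
#' `[2 * read_length, insert_mean + 4 * insert_sd]`; fragments are drawn
#' uniformly from both strands. The run-constant Phred value is
#' `round(-10 * log10(error_rate))` (clamped to `[2, 41]`) and substitutions
#' are injected at exactly the rate the Phred value implies; `error_rate = 0`
#' produces error-free reads at Phred 40. Optional contamination flags mark a
#' fraction of pairs as low-quality (Phred `low_quality_phred`, with the
#' matching elevated error rate) or inject N bases, for exercising QC.
#'
#' @param genome Anything [as_reference()] understands.
#' @param coverage Mean per-base depth (default 85, PE100 at ~85-fold).
#' @param read_length Read length in bp (default 100).
#' @param insert_mean,insert_sd Insert-size distribution (bp).
#' @param error_rate Per-base substitution rate before Phred rounding.
#' @param seed Optional RNG seed.
#' @param low_quality_fraction Fraction of pairs emitted at `low_quality_phred`.
#' @param n_base_fraction Fraction of pairs with N bases injected into mate 1.
#' @param low_quality_phred Phred value for contaminated pairs (default 6).
#' @return A `read_pairs` data.frame with columns `id`, `seq1`, `qual1`,
#'   `seq2`, `qual2`, `chrom`, `start1`, `strand1`, `start2`, `strand2`
#'   (truth origins: 0-based leftmost coordinate of each mate on the source
#'   molecule, and the strand the mate was read from).
#' @export
simulate_read_pairs <- function(genome, coverage = 85, read_length = 100L,
                                insert_mean = 350, insert_sd = 35,
                                error_rate = 0.001, seed = NULL,
                                low_quality_fraction = 0, n_base_fraction = 0,
                                low_quality_phred = 6L) {
  if (coverage <= 0) stop("coverage must be > 0")
  if (read_length > insert_mean) stop("read_length must be <= insert_mean")
  if (error_rate < 0 || error_rate > 0.75) stop("error_rate must be in [0, 0.75]")
  if (!is.null(seed)) set.seed(seed)
  ref <- as_reference(genome)
  hi <- insert_mean + 4 * insert_sd
  q_run <- if (error_rate > 0) {
    max(2L, min(41L, as.integer(round(-10 * log10(error_rate)))))
  } else 40L
  p_run <- if (error_rate > 0) 10^(-q_run / 10) else 0

  per_mol <- lapply(names(ref), function(nm) {
    L <- nchar(ref[[nm]])
    if (L < hi) {
      stop("molecule '", nm, "' (", L, " bp) shorter than insert_mean + 4*insert_sd")
    }
    n <- as.integer(ceiling(coverage * L / (2 * read_length)))
    ins <- as.integer(round(rtruncnorm(n, insert_mean, insert_sd,
                                       max(2 * read_length, 1), hi)))
    start <- as.integer(floor(stats::runif(n, 0, L - ins + 1)))  # 0-based
    fwd <- stats::runif(n) < 0.5
    left <- substring(ref[[nm]], start + 1L, start + read_length)
    right <- revcomp(substring(ref[[nm]], start + ins - read_length + 1L,
                               start + ins))
    data.frame(
      id = sprintf("%s_p%06d", nm, seq_len(n)),
      seq1 = ifelse(fwd, left, right),
      seq2 = ifelse(fwd, right, left),
      chrom = nm,
      start1 = ifelse(fwd, start, start + ins - read_length),
      strand1 = ifelse(fwd, "+", "-"),
      start2 = ifelse(fwd, start + ins - read_length, start),
      strand2 = ifelse(fwd, "-", "+"),
      stringsAsFactors = FALSE
    )
  })
  pairs <- do.call(rbind, per_mol)
  n <- nrow(pairs)

  # contamination assignments (disjoint sets)
  q_pair <- rep(q_run, n)
  p_pair <- rep(p_run, n)
  n_lowq <- as.integer(floor(n * low_quality_fraction))
  n_nbase <- as.integer(floor(n * n_base_fraction))
  idx <- sample.int(n, min(n, n_lowq + n_nbase))
  lowq_idx <- idx[seq_len(n_lowq)]
  nbase_idx <- setdiff(idx, lowq_idx)
  q_pair[lowq_idx] <- low_quality_phred
  p_pair[lowq_idx] <- 10^(-low_quality_phred / 10)

  pairs$seq1 <- inject_substitutions(pairs$seq1, p_pair)
  pairs$seq2 <- inject_substitutions(pairs$seq2, p_pair)
  if (length(nbase_idx)) {
    pairs$seq1[nbase_idx] <- inject_n_bases(pairs$seq1[nbase_idx])
  }
  pairs$qual1 <- constant_qual_string(q_pair, nchar(pairs$seq1))
  pairs$qual2 <- constant_qual_string(q_pair, nchar(pairs$seq2))
  pairs <- pairs[, c("id", "seq1", "qual1", "seq2", "qual2", "chrom",
                     "start1", "strand1", "start2", "strand2")]
  class(pairs) <- c("read_pairs", "data.frame")
  pairs
}

#' Write read pairs as two FASTQ files (Phred+33)
#'
#' @param pairs A `read_pairs` data.frame.
#' @param r1_path,r2_path Output FASTQ paths for mate 1 and mate 2.
#' @param truth_path Optional TSV sidecar recording the truth origins.
#' @return Invisibly, `c(r1_path, r2_path)`.
#' @export
write_read_pairs_fastq <- function(pairs, r1_path, r2_path, truth_path = NULL) {
  for (m in 1:2) {
    x <- Biostrings::DNAStringSet(pairs[[paste0("seq", m)]])
    names(x) <- paste0(pairs$id, "/", m)
    Biostrings::writeXStringSet(
      x, if (m == 1) r1_path else r2_path, format = "fastq",
      qualities = Biostrings::BStringSet(pairs[[paste0("qual", m)]])
    )
  }
  if (!is.null(truth_path)) {
    write_tsv(pairs[, c("id", "chrom", "start1", "strand1", "start2", "strand2")],
              truth_path)
  }
  invisible(c(r1_path, r2_path))
}

#' Read paired FASTQ files into a `read_pairs` table
#'
#' Truth-origin columns are `NA` (unknown for external data).
#'
#' @param r1_path,r2_path FASTQ paths for mate 1 and mate 2.
#' @return A `read_pairs` data.frame.
#' @export
read_read_pairs_fastq <- function(r1_path, r2_path) {
  r1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq", with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq", with.qualities = TRUE)
  if (length(r1) != length(r2)) stop("mate FASTQ files differ in read count")
  id <- sub("/1$", "", names(r1))
  pairs <- data.frame(
    id = id,
    seq1 = as.character(r1), qual1 = as.character(S4Vectors::mcols(r1)$qualities),
    seq2 = as.character(r2), qual2 = as.character(S4Vectors::mcols(r2)$qualities),
    chrom = NA_character_, start1 = NA_integer_, strand1 = NA_character_,
    start2 = NA_integer_, strand2 = NA_character_, stringsAsFactors = FALSE
  )
  class(pairs) <- c("read_pairs", "data.frame")
  pairs
}
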