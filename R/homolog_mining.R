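# Genome-mining filter chain for G8H homologs plus the protein-engineering
# sequence operations: strict-threshold filtering of BLAST-style hit tables,
# six-frame longest-ORF extraction, N-terminal chimera construction, and
# truncation of plastid targeting sequences at the conserved RR motif.

#' Plant families known to accumulate monoterpenoid indole alkaloids
#'
#' Default whitelist for [filter_homolog_hits()]: the MIA-producing families
#' from which active geraniol 8-hydroxylases have been mined.
#'
#' @return Character vector of family names.
#' @export
mia_families <- function() {
  c("Apocynaceae", "Rubiaceae", "Gentianaceae", "Loganiaceae")
}

#' Filter homolog hits on bit score, identity, alignment length and taxonomy
#'
#' All three numeric thresholds are strict inequalities (a hit at exactly the
#' threshold fails). Family matching is case-insensitive; an empty whitelist
#' disables the taxonomy filter. The filter is a pure row predicate: output
#' rows are a subset of the input in their original order, and filtering is
#' idempotent.
#'
#' @param hits `data.frame` with at least `bit_score`, `percent_identity`,
#'   `alignment_length`, and (when a whitelist is used) `family`.
#' @param min_bit_score,min_identity,min_alignment_length Strict lower
#'   thresholds (defaults 1000, 75, 1000).
#' @param family_whitelist Character vector of accepted families
#'   (default [mia_families()]); `character(0)` or `NULL` disables it.
#' @return The passing rows of `hits`.
#' @export
filter_homolog_hits <- function(hits, min_bit_score = 1000,
                                min_identity = 75,
                                min_alignment_length = 1000,
                                family_whitelist = mia_families()) {
  req <- c("bit_score", "percent_identity", "alignment_length")
  use_family <- !is.null(family_whitelist) && length(family_whitelist) > 0L
  if (use_family) req <- c(req, "family")
  missing_cols <- setdiff(req, names(hits))
  if (length(missing_cols)) {
    stop("hit table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(hits$percent_identity < 0 | hits$percent_identity > 100)) {
    stop("percent_identity must be within [0, 100]")
  }
  pass <- hits$bit_score > min_bit_score &
    hits$percent_identity > min_identity &
    hits$alignment_length > min_alignment_length
  if (use_family) {
    pass <- pass & tolower(hits$family) %in% tolower(family_whitelist)
  }
  out <- hits[pass, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a homolog hit table (BLAST tabular dialect + subject sequence, family)
#'
#' Expects the 12 standard tabular columns followed by the subject nucleotide
#' sequence and the source taxon family, tab-separated, no header.
#'
#' @param path Input TSV.
#' @return `data.frame` with canonical column names (`query`, `subject`,
#'   `percent_identity`, `alignment_length`, `mismatches`, `gap_opens`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `evalue`, `bit_score`,
#'   `subject_seq`, `family`).
#' @export
read_homolog_hits <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, quote = "")
  if (ncol(x) != 14L) stop("expected 14 tab-separated columns (outfmt 6 + sseq + family)")
  names(x) <- c("query", "subject", "percent_identity", "alignment_length",
                "mismatches", "gap_opens", "q_start", "q_end", "s_start",
                "s_end", "evalue", "bit_score", "subject_seq", "family")
  x
}

#' Write a homolog hit table in the dialect [read_homolog_hits()] reads
#'
#' @param hits Hit `data.frame` with the canonical columns.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_homolog_hits <- function(hits, path) {
  cols <- c("query", "subject", "percent_identity", "alignment_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start",
            "s_end", "evalue", "bit_score", "subject_seq", "family")
  utils::write.table(hits[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Simulate a homolog hit table
#'
#' Synthetic stand-in for a similarity search against plant sequence
#' databases: scores, identities and alignment lengths are drawn wide enough
#' to straddle the filtering thresholds, families are drawn from MIA and
#' non-MIA plants, and subject sequences are random DNA with a planted ORF in
#' a random frame/strand for a stated fraction of rows.
#'
#' @param n Number of hits.
#' @param seed Optional RNG seed.
#' @param orf_fraction Fraction of subject sequences with a planted long ORF.
#' @return Hit `data.frame` with the canonical columns.
#' @export
simulate_homolog_hits <- function(n, seed = NULL, orf_fraction = 0.7) {
  if (!is.null(seed)) set.seed(seed)
  families <- c(mia_families(), "Poaceae", "Brassicaceae", "Solanaceae")
  subject_len <- sample(1200:2400, n, replace = TRUE)
  subject_seq <- vapply(subject_len, random_dna, "")
  plant <- stats::runif(n) < orf_fraction
  for (i in which(plant)) {
    orf_aa <- sample(200:450, 1L)
    body <- paste(sample(setdiff(names(Biostrings::GENETIC_CODE),
                                 c("TAA", "TAG", "TGA", "ATG")),
                         orf_aa - 1L, replace = TRUE), collapse = "")
    orf <- paste0("ATG", body, sample(c("TAA", "TAG", "TGA"), 1L))
    at <- sample(0:(subject_len[i] - nchar(orf)), 1L)
    s <- subject_seq[i]
    s <- paste0(substr(s, 1, at), orf, substr(s, at + nchar(orf) + 1L, nchar(s)))
    if (stats::runif(1) < 0.5) s <- revcomp(s)
    subject_seq[i] <- s
  }
  aln_len <- sample(600:1600, n, replace = TRUE)
  data.frame(
    query = "CrG8H", subject = sprintf("hit%04d", seq_len(n)),
    percent_identity = round(stats::runif(n, 50, 100), 1),
    alignment_length = aln_len,
    mismatches = sample(0:200, n, replace = TRUE),
    gap_opens = sample(0:5, n, replace = TRUE),
    q_start = 1L, q_end = aln_len, s_start = 1L, s_end = aln_len,
    evalue = signif(10^stats::runif(n, -180, -10), 3),
    bit_score = round(stats::runif(n, 400, 1800), 1),
    subject_seq = subject_seq,
    family = sample(families, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# Translate a vector of codons; codons containing N (or shorter than 3) give X.
translate_codons <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# All complete ATG..stop spans of one strand of a sequence.
# Returns data.frame(frame, start, end) in 0-based coordinates on `s`.
orf_spans_forward <- function(s) {
  L <- nchar(s)
  rows <- list()
  for (f in 0:2) {
    n_codon <- (L - f) %/% 3L
    if (n_codon < 2L) next
    cs <- f + 3L * (seq_len(n_codon) - 1L)  # 0-based codon starts
    codons <- substring(s, cs + 1L, cs + 3L)
    starts <- which(codons == "ATG")
    stops <- which(codons %in% STOP_CODONS)
    if (!length(starts) || !length(stops)) next
    # first stop at or after each start (an ATG can't be a stop, so ">=" is safe)
    nxt <- stops[findInterval(starts, stops) + 1L]
    ok <- !is.na(nxt)
    if (!any(ok)) next
    rows[[length(rows) + 1L]] <- data.frame(
      frame = f + 1L, start = cs[starts[ok]], end = cs[nxt[ok]] + 3L)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(0), start = integer(0), end = integer(0))
}

#' Extract the longest open reading frame
#'
#' Scans all three frames of the forward strand (and of the reverse
#' complement when `search_both_strands`) for complete ATG-to-stop spans and
#' returns the longest; an explicit in-sequence stop codon is required.
#' Codons containing `N` translate to `X` and are never treated as start or
#' stop. Length ties are broken on the translated protein (lexicographically
#' smallest), then forward strand, then smallest reported start, so the
#' reported ORF is invariant under reverse-complementing the input.
#' Reverse-strand coordinates are reported on the input
#' sequence: `substr(seq, start + 1, end)` reverse-complemented is the ORF.
#'
#' @param sequence A DNA string.
#' @param search_both_strands Also scan the reverse complement (default TRUE).
#' @return An `orf_record` list with `strand`, `frame` (1-3 on the searched
#'   strand), `start`, `end` (0-based half-open span including the stop
#'   codon), `protein` (stop not translated), `length` (nt); or `NULL` when
#'   no complete ORF exists.
#' @export
longest_orf <- function(sequence, search_both_strands = TRUE) {
  stopifnot(length(sequence) == 1L)
  if (!is_dna(sequence)) stop("sequence must be DNA over A/C/G/T/N")
  L <- nchar(sequence)
  cand <- list()
  f <- orf_spans_forward(sequence)
  if (nrow(f)) {
    f$strand <- "+"
    f$orig_start <- f$start
    cand[[1L]] <- f
  }
  if (search_both_strands) {
    r <- orf_spans_forward(revcomp(sequence))
    if (nrow(r)) {
      r$strand <- "-"
      r$orig_start <- L - r$end  # map back to input coordinates
      cand[[length(cand) + 1L]] <- r
    }
  }
  if (!length(cand)) return(NULL)
  x <- do.call(rbind, cand)
  x$len <- x$end - x$start
  x <- x[x$len == max(x$len), , drop = FALSE]
  protein_of <- function(b) {
    orf_seq <- if (b$strand == "+") {
      substr(sequence, b$start + 1L, b$end)
    } else {
      substr(revcomp(sequence), b$start + 1L, b$end)
    }
    n_codon <- nchar(orf_seq) %/% 3L
    codons <- substring(orf_seq, 3L * (seq_len(n_codon) - 1L) + 1L,
                        3L * seq_len(n_codon))
    paste(translate_codons(codons[-n_codon]), collapse = "")
  }
  proteins <- vapply(seq_len(nrow(x)), function(i) protein_of(x[i, ]), "")
  o <- order(proteins, x$strand != "+", x$orig_start)
  b <- x[o[1L], ]
  structure(list(strand = b$strand, frame = b$frame,
                 start = as.integer(b$orig_start),
                 end = as.integer(b$orig_start + b$len),
                 length = as.integer(b$len), protein = proteins[o[1L]]),
            class = "orf_record")
}

#' @export
print.orf_record <- function(x, ...) {
  cat(sprintf("<orf_record> strand %s frame %d [%d, %d) %d nt, %d aa\n",
              x$strand, x$frame, x$start, x$end, x$length, nchar(x$protein)))
  invisible(x)
}

#' Swap an N-terminal segment between two proteins
#'
#' Builds the chimera `donor[1..n] + acceptor[(n+1)..end]` (1-based inclusive
#' residue numbering); with the default `n = 29` this reproduces the
#' N-terminal exchange used to dissect the role of the G8H membrane anchor.
#' The chimera length always equals the acceptor length.
#'
#' @param donor,acceptor Protein strings.
#' @param n_terminal_length Number of donor residues (default 29); 0 returns
#'   the acceptor unchanged.
#' @return The chimeric protein string.
#' @export
make_chimera <- function(donor, acceptor, n_terminal_length = 29L) {
  n <- as.integer(n_terminal_length)
  if (n < 0L) stop("n_terminal_length must be >= 0")
  if (n >= nchar(donor) || n >= nchar(acceptor)) {
    stop("n_terminal_length must be smaller than both protein lengths")
  }
  paste0(substr(donor, 1L, n), substr(acceptor, n + 1L, nchar(acceptor)))
}

#' Truncate a plastid targeting sequence at the first RR motif
#'
#' Removes residues 2..(p-1), where p is the 1-based position of the first
#' RR dipeptide, keeping the initial methionine: the standard truncation of
#' plant monoterpene synthases (e.g. geraniol synthase) for cytosolic yeast
#' expression.
#'
#' @param protein Protein string starting with `M`.
#' @return `"M"` followed by the protein from the RR motif onward.
#' @export
truncate_at_rr <- function(protein) {
  if (!startsWith(protein, "M")) stop("protein must start with methionine (M)")
  p <- as.integer(regexpr("RR", protein, fixed = TRUE))
  if (p < 0L) stop("no RR dipeptide motif found; cannot truncate")
  paste0("M", substr(protein, p, nchar(protein)))
}
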