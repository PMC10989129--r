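# Small shared helpers: DNA string utilities, Phred conversions, reference
# normalization. Coordinates are 0-based half-open throughout the package.

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences (alphabet A, C, G, T, N).
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA sequence
#'
#' Uniform base composition; used by the synthetic-data generators.
#'
#' @param n Sequence length in bp.
#' @return A single DNA string.
#' @export
random_dna <- function(n) {
  stopifnot(n >= 0)
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

is_dna <- function(x) {
  all(grepl("^[ACGTN]+$", x))
}

#' Test whether a site is a perfect reverse-complement palindrome
#'
#' loxPsym owes its orientation-independent recombination to being its own
#' reverse complement; configured site sequences are checked against this.
#'
#' @param x A DNA string.
#' @return Logical scalar.
#' @export
is_palindromic_site <- function(x) {
  identical(revcomp(x), x)
}

# Phred+33 encode a vector of integer qualities into one quality string per
# element of `n` (constant quality per read).
constant_qual_string <- function(q, n) {
  stopifnot(length(q) == length(n))
  vapply(seq_along(q), function(i) strrep(intToUtf8(q[i] + 33L), n[i]), "")
}

# Integer Phred values of a single quality string.
phred_values <- function(qual) utf8ToInt(qual) - 33L

# Per-string summary of Phred values for a character vector of qualities.
phred_stat <- function(quals, fun) {
  vapply(quals, function(q) fun(utf8ToInt(q) - 33L), numeric(1), USE.NAMES = FALSE)
}

# Normalize the many accepted genome representations into a named character
# vector of molecule sequences.
as_reference <- function(x) {
  if (is.character(x)) {
    nm <- names(x)
    if (is.null(nm)) nm <- if (length(x) == 1L) "seq1" else paste0("seq", seq_along(x))
    return(stats::setNames(as.character(x), nm))
  }
  if (inherits(x, "lox_chromosome")) {
    return(stats::setNames(x$sequence, x$id))
  }
  if (inherits(x, "rearranged_genome")) {
    return(stats::setNames(rearranged_sequence(x), x$chrom))
  }
  if (is.list(x)) {
    refs <- lapply(x, as_reference)
    out <- unlist(refs, use.names = TRUE)
    if (anyDuplicated(names(out))) stop("duplicated molecule ids in reference")
    return(out)
  }
  stop("cannot interpret object of class '", paste(class(x), collapse = "/"),
       "' as a reference genome")
}

# Thin TSV wrappers so every on-disk table uses one dialect.
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE, ...)
}
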