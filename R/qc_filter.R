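# Read quality filtering prior to mapping: pairs are removed when either mate
# is low-quality (Phred below threshold under the chosen summary) or contains
# unknown bases. Removal is pair-level so the output stays properly paired.

#' Filter low-quality and ambiguous read pairs
#'
#' A pair is removed when either mate fails the Phred rule or (if
#' `drop_if_any_n`) contains at least one `N`. The Phred rule is configurable
#' because published pipelines differ in how "Phred-score < 10" is summarized
#' per read: `"mean"` removes mates whose mean Phred is below
#' `min_mean_phred`; `"min"` removes mates with any base below it;
#' `"fraction_below"` removes mates where more than `low_fraction_limit` of
#' bases fall below it. Surviving pairs are returned unmodified and in input
#' order.
#'
#' @param pairs A `read_pairs` data.frame.
#' @param min_mean_phred Phred threshold (default 10).
#' @param drop_if_any_n Remove pairs with unknown bases (default `TRUE`).
#' @param metric Per-mate Phred summary; see Details.
#' @param low_fraction_limit Used only for `metric = "fraction_below"`.
#' @return A list with `pairs` (the survivors) and `stats`, a `filter_stats`
#'   list with fields `pairs_in`, `pairs_removed_quality`, `pairs_removed_n`,
#'   `fraction_removed`.
#' @export
filter_read_pairs <- function(pairs, min_mean_phred = 10,
                              drop_if_any_n = TRUE,
                              metric = c("mean", "min", "fraction_below"),
                              low_fraction_limit = 0.5) {
  metric <- match.arg(metric)
  stopifnot(is.data.frame(pairs))
  n <- nrow(pairs)
  if (n > 0L && (any(nchar(pairs$qual1) != nchar(pairs$seq1)) ||
                 any(nchar(pairs$qual2) != nchar(pairs$seq2)))) {
    stop("malformed quality string: length differs from sequence length")
  }
  summarize <- switch(metric,
    mean = function(q) phred_stat(q, mean),
    min = function(q) phred_stat(q, min),
    fraction_below = function(q) {
      vapply(q, function(s) mean((utf8ToInt(s) - 33L) < min_mean_phred),
             numeric(1), USE.NAMES = FALSE)
    }
  )
  if (n == 0L) {
    low <- logical(0); has_n <- logical(0)
  } else if (metric == "fraction_below") {
    low <- summarize(pairs$qual1) > low_fraction_limit |
      summarize(pairs$qual2) > low_fraction_limit
  } else {
    low <- summarize(pairs$qual1) < min_mean_phred |
      summarize(pairs$qual2) < min_mean_phred
  }
  if (drop_if_any_n && n > 0L) {
    has_n <- !low & (grepl("N", pairs$seq1, fixed = TRUE) |
                     grepl("N", pairs$seq2, fixed = TRUE))
  } else {
    has_n <- rep(FALSE, n)
  }
  keep <- !(low | has_n)
  stats <- structure(
    list(pairs_in = n,
         pairs_removed_quality = sum(low),
         pairs_removed_n = sum(has_n),
         fraction_removed = if (n == 0L) 0 else sum(!keep) / n),
    class = "filter_stats"
  )
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(pairs)
  list(pairs = out, stats = stats)
}

#' @export
print.filter_stats <- function(x, ...) {
  cat(sprintf("<filter_stats> %d pairs in; removed %d low-quality + %d with N (%.2f%%)\n",
              x$pairs_in, x$pairs_removed_quality, x$pairs_removed_n,
              100 * x$fraction_removed))
  invisible(x)
}

#' Write filter statistics as a one-row TSV
#'
#' @param stats A `filter_stats` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_filter_stats <- function(stats, path) {
  write_tsv(as.data.frame(unclass(stats)), path)
}
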