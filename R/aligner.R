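# Desk-scale ungapped read mapper: exact k-mer seeding with full Hamming
# verification. The effective seed length is capped at
# floor(length / (max_mismatch + 1)) so that, by the pigeonhole principle,
# every placement within the mismatch allowance contains at least one exact
# seed — the seeded search is therefore provably identical to a brute-force
# Hamming scan of all positions on both strands. Ties are reported as
# status "multi" so repeats (notably loxPsym itself) never fake unique
# evidence. SCRaMbLE junction signal is carried by split reads (see
# junction_caller), not by gapped alignment, so the mapper stays ungapped.

#' Align query sequences against a reference (ungapped, exact)
#'
#' Each query is assigned its best placements by mismatch count over both
#' strands of every reference molecule. A placement on strand `-` means the
#' reverse complement of the query matches the reference forward sequence at
#' `start`. Status is `unique` (single best placement), `multi` (tied best),
#' or `unmapped` (no placement within `max_mismatch`).
#'
#' @param seqs Named character vector of queries (names become query ids).
#' @param reference Anything [as_reference()] understands.
#' @param max_mismatch Mismatch allowance; scalar or per-query vector.
#' @param k Requested seed length; internally capped per query group at
#'   `floor(length / (max_mismatch + 1))` to keep the search exact.
#' @return `data.frame` with columns `query`, `chrom`, `start` (0-based),
#'   `strand`, `mismatches`, `status`, `length`; one row per query, `NA`
#'   placement fields when unmapped, lexicographically first placement when
#'   `multi`. The full set of best placements is in
#'   `attr(x, "placements")`.
#' @export
align_sequences <- function(seqs, reference, max_mismatch = 4L, k = 21L) {
  ref <- as_reference(reference)
  n <- length(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("q%06d", seq_len(n))
  res <- data.frame(query = ids, chrom = NA_character_, start = NA_integer_,
                    strand = NA_character_, mismatches = NA_integer_,
                    status = rep("unmapped", n), length = nchar(seqs),
                    stringsAsFactors = FALSE)
  if (n == 0L) {
    attr(res, "placements") <- res[0, c("query", "chrom", "start", "strand", "mismatches")]
    return(res)
  }
  len <- nchar(seqs)
  mm <- rep_len(as.integer(max_mismatch), n)
  if (k > min(len)) stop("k larger than read length")
  chunk <- len %/% (mm + 1L)
  if (any(chunk < 1L)) stop("max_mismatch too large relative to query length")
  k_eff <- min(k, chunk)

  Lc <- vapply(ref, nchar, integer(1))
  idx_envs <- lapply(names(ref), function(nm) {
    L <- Lc[[nm]]
    if (L < k_eff) return(list2env(list(), hash = TRUE, parent = emptyenv()))
    kmers <- substring(ref[[nm]], 1:(L - k_eff + 1L), k_eff:L)
    list2env(split(0:(L - k_eff), kmers), hash = TRUE, parent = emptyenv())
  })
  names(idx_envs) <- names(ref)
  G <- lapply(ref, utf8ToInt)
  rcs <- revcomp(seqs)

  placements <- list()
  for (g in split(seq_len(n), paste(len, mm))) {
    l <- len[g[1L]]
    m <- mm[g[1L]]
    ng <- length(g)
    offs <- as.integer(floor(l * (0:m) / (m + 1)))
    Q <- matrix(utf8ToInt(paste(seqs[g], collapse = "")), nrow = l)
    Qrc <- matrix(utf8ToInt(paste(rcs[g], collapse = "")), nrow = l)
    for (str in c("+", "-")) {
      ss <- if (str == "+") seqs[g] else rcs[g]
      MQ <- if (str == "+") Q else Qrc
      seed_mat <- matrix("", ng, m + 1L)
      for (j in seq_len(m + 1L)) {
        seed_mat[, j] <- substring(ss, offs[j] + 1L, offs[j] + k_eff)
      }
      for (nm in names(ref)) {
        hits <- mget(as.vector(seed_mat), envir = idx_envs[[nm]],
                     ifnotfound = list(integer(0)))
        reps <- lengths(hits)
        if (sum(reps) == 0L) next
        qrow <- rep.int(((seq_along(hits) - 1L) %% ng) + 1L, reps)
        offv <- rep.int(offs[((seq_along(hits) - 1L) %/% ng) + 1L], reps)
        pos <- unlist(hits, use.names = FALSE) - offv
        ok <- pos >= 0L & pos <= Lc[[nm]] - l
        qrow <- qrow[ok]; pos <- pos[ok]
        if (!length(pos)) next
        d <- !duplicated(qrow * (Lc[[nm]] + 1) + pos)
        qrow <- qrow[d]; pos <- pos[d]
        W <- matrix(G[[nm]][outer(seq_len(l), pos, `+`)], nrow = l)
        mmc <- colSums(W != MQ[, qrow, drop = FALSE])
        keep <- mmc <= m
        if (any(keep)) {
          placements[[length(placements) + 1L]] <- data.frame(
            qi = g[qrow[keep]], chrom = nm, start = as.integer(pos[keep]),
            strand = str, mismatches = as.integer(mmc[keep]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  if (length(placements)) {
    P <- do.call(rbind, placements)
    P$bestmm <- stats::ave(P$mismatches, P$qi, FUN = min)
    P <- P[P$mismatches == P$bestmm, , drop = FALSE]
    P <- P[order(P$qi, P$chrom, P$start, match(P$strand, c("+", "-"))), , drop = FALSE]
    cnt <- table(P$qi)
    first <- P[!duplicated(P$qi), , drop = FALSE]
    res$chrom[first$qi] <- first$chrom
    res$start[first$qi] <- first$start
    res$strand[first$qi] <- first$strand
    res$mismatches[first$qi] <- first$mismatches
    res$status[first$qi] <- ifelse(cnt[as.character(first$qi)] > 1L, "multi", "unique")
    pl <- data.frame(query = ids[P$qi], chrom = P$chrom, start = P$start,
                     strand = P$strand, mismatches = P$mismatches,
                     stringsAsFactors = FALSE)
  } else {
    pl <- res[0, c("query", "chrom", "start", "strand", "mismatches")]
  }
  attr(res, "placements") <- pl
  res
}

#' Map read pairs against a reference
#'
#' Mates are aligned independently (mate 2 is reverse-complemented by the
#' strand search, not beforehand); pairing information is not used for
#' placement.
#'
#' @param pairs A `read_pairs` data.frame.
#' @param reference Anything [as_reference()] understands.
#' @param k Seed length passed to [align_sequences()].
#' @param max_mismatch Mismatch allowance per read.
#' @return `data.frame` of class `alignments` with columns `read`, `mate`,
#'   `chrom`, `start`, `strand`, `mismatches`, `status`, `length`.
#' @export
map_reads <- function(pairs, reference, k = 21L, max_mismatch = 4L) {
  stopifnot(is.data.frame(pairs))
  seqs <- c(stats::setNames(pairs$seq1, paste0(pairs$id, "/1")),
            stats::setNames(pairs$seq2, paste0(pairs$id, "/2")))
  aln <- align_sequences(seqs, reference, max_mismatch = max_mismatch, k = k)
  out <- data.frame(read = sub("/[12]$", "", aln$query),
                    mate = as.integer(sub("^.*/", "", aln$query)),
                    chrom = aln$chrom, start = aln$start, strand = aln$strand,
                    mismatches = aln$mismatches, status = aln$status,
                    length = aln$length, stringsAsFactors = FALSE)
  class(out) <- c("alignments", "data.frame")
  out
}

#' Per-segment depth profile from unique alignments
#'
#' Builds a per-base pileup from uniquely mapped reads only (multi reads are
#' discarded so repeats contribute no depth evidence), averages it over each
#' segment of the segment map, and normalizes by the median segment depth of
#' the chromosome to give copy ratios (~1 neutral, ~0 deleted, ~2 tandem
#' duplicated).
#'
#' @param alignments An `alignments` data.frame from [map_reads()].
#' @param segment_map A segment map from [derive_segment_map()].
#' @return `data.frame` of class `depth_profile` with columns `chrom`,
#'   `segment`, `start`, `end`, `mean_depth`, `median_depth`, `copy_ratio`.
#'   `attr(x, "pileup_total")` holds the per-chromosome pileup sums (equal to
#'   the summed lengths of uniquely mapped reads).
#' @export
compute_depth <- function(alignments, segment_map) {
  uni <- alignments[alignments$status == "unique", , drop = FALSE]
  if (nrow(uni) == 0L) stop("no uniquely mapped reads; cannot compute depth")
  out <- list()
  totals <- numeric(0)
  for (nm in unique(segment_map$chrom)) {
    sm <- segment_map[segment_map$chrom == nm, , drop = FALSE]
    L <- max(sm$end)
    a <- uni[uni$chrom == nm, , drop = FALSE]
    delta <- numeric(L + 1L)
    if (nrow(a) > 0L) {
      if (any(a$start + a$length > L)) stop("alignment extends past chromosome end")
      st <- tabulate(a$start + 1L, nbins = L + 1L)
      en <- tabulate(a$start + a$length + 1L, nbins = L + 1L)
      delta <- st - en
    }
    cov <- cumsum(delta)[seq_len(L)]
    cumcov <- c(0, cumsum(cov))
    seg_sum <- cumcov[sm$end + 1L] - cumcov[sm$start + 1L]
    mean_depth <- seg_sum / (sm$end - sm$start)
    med <- stats::median(mean_depth)
    ratio <- if (med > 0) mean_depth / med else rep(NA_real_, length(mean_depth))
    if (med <= 0) warning("median segment depth is 0 on '", nm, "'; copy ratios are NA")
    out[[nm]] <- data.frame(chrom = nm, segment = sm$segment, start = sm$start,
                            end = sm$end, mean_depth = mean_depth,
                            median_depth = med, copy_ratio = ratio,
                            stringsAsFactors = FALSE)
    totals[nm] <- sum(cov)
  }
  prof <- do.call(rbind, out)
  rownames(prof) <- NULL
  class(prof) <- c("depth_profile", "data.frame")
  attr(prof, "pileup_total") <- totals
  prof
}

#' Write alignments as a minimal tab-separated table
#'
#' @param alignments An `alignments` data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(alignments, path) write_tsv(alignments, path)

#' Export mapped alignments as SAM (ungapped, M-only CIGAR)
#'
#' Minimal SAM with correct FLAG (reverse-strand and mate bits), 1-based POS,
#' and `<len>M` CIGAR; unmapped reads get FLAG 4. Intended for inspection in
#' standard viewers, not as the package's native format.
#'
#' @param alignments An `alignments` data.frame.
#' @param reference Anything [as_reference()] understands (for `@SQ` lines).
#' @param path Output SAM file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, reference, path) {
  ref <- as_reference(reference)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(ref), nchar(ref)), con)
  a <- alignments
  flag <- ifelse(a$status == "unmapped", 4L, 0L) +
    ifelse(!is.na(a$strand) & a$strand == "-", 16L, 0L) +
    ifelse(a$mate == 1L, 64L, 128L) + 1L
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
                   a$read, flag,
                   ifelse(is.na(a$chrom), "*", a$chrom),
                   ifelse(is.na(a$start), 0L, a$start + 1L),
                   ifelse(a$status == "unique", 60L, 0L),
                   ifelse(a$status == "unmapped", "*", sprintf("%dM", a$length)))
  writeLines(lines, con)
  invisible(path)
}
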