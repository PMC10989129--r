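# loxPsym split-read junction calling and event typing.
#
# Reads that fail contiguous mapping are scanned for a loxPsym occurrence;
# reads carrying the site with at least `min_flank` bp on both sides are split
# into two flank fragments, each flank is placed on the reference, fragment
# ends are snapped to segment boundaries, and the resulting novel adjacency
# (a junction) is recorded. Junctions with enough distinct supporting reads
# are classified into deletion / tandem duplication / inversion (or complex)
# from the breakpoint orientation pattern plus per-segment coverage depth.
#
# Junction geometry. Site index j separates segment j from segment j+1; a
# junction side is (site index, side, strand) where side "tail" means the
# flank abuts the site from the segment end at the site start, and "head"
# means it abuts from the segment start at the site end. Orientation
# patterns, after canonicalization (a junction read from the opposite strand
# is the same junction):
#   tail(+) -> head(+), a <  b : deletion of segments a+1..b
#   tail(+) -> head(+), a == b : the wild-type adjacency (dropped)
#   head(-) -> tail(-), a <  b : tandem duplication of segments a+1..b
#   tail(+) -> tail(-)  paired with  head(-) -> head(+), same (a, b):
#                                inversion of segments a+1..b

#' Split unmapped reads at a loxPsym occurrence
#'
#' Scans each read for the best loxPsym match (the palindromic site makes the
#' two orientations identical), allowing up to `max_site_mismatch`
#' substitutions inside the site. When a match is found and both flanks are
#' at least `min_flank` bp, the left and right flank fragments are emitted;
#' otherwise the read yields nothing.
#'
#' @param reads Named character vector of read sequences (names = read ids).
#' @param loxpsym Site sequence.
#' @param min_flank Minimum flank length on *both* sides (default 15 bp).
#' @param max_site_mismatch Mismatches tolerated inside the site (default 2).
#' @return `data.frame` with columns `read`, `side` (`left`/`right`),
#'   `sequence`, `flank_length`, `site_offset` (0-based offset of the site in
#'   the read), `site_mismatches`.
#' @export
split_read_at_loxpsym <- function(reads, loxpsym = loxpsym_sequence(),
                                  min_flank = 15L, max_site_mismatch = 2L) {
  w <- nchar(loxpsym)
  if (length(reads) && any(nchar(reads) < w)) {
    stop("loxpsym sequence is longer than at least one read")
  }
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("r%06d", seq_along(reads))
  site_int <- utf8ToInt(loxpsym)
  rows <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    r <- utf8ToInt(reads[[i]])
    l <- length(r)
    npos <- l - w + 1L
    mmv <- integer(npos)
    for (j in seq_len(w)) {
      mmv <- mmv + (r[j:(j + npos - 1L)] != site_int[j])
    }
    best <- min(mmv)
    if (best > max_site_mismatch) next
    o <- which(mmv == best)[1L] - 1L  # 0-based, leftmost on ties
    left_len <- o
    right_len <- l - o - w
    if (left_len < min_flank || right_len < min_flank) next
    rows[[i]] <- data.frame(
      read = ids[i], side = c("left", "right"),
      sequence = c(substr(reads[[i]], 1L, left_len),
                   substr(reads[[i]], o + w + 1L, l)),
      flank_length = c(left_len, right_len),
      site_offset = o, site_mismatches = best, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(read = character(0), side = character(0),
                      sequence = character(0), flank_length = integer(0),
                      site_offset = integer(0), site_mismatches = integer(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# Site boundary coordinates per chromosome, derived from a segment map:
# site j starts where segment j ends and ends where segment j+1 starts.
site_table <- function(segment_map) {
  do.call(rbind, lapply(split(segment_map, segment_map$chrom), function(sm) {
    sm <- sm[order(sm$segment), , drop = FALSE]
    n <- nrow(sm)
    if (n < 2L) {
      return(data.frame(chrom = character(0), site = integer(0),
                        start = integer(0), end = integer(0)))
    }
    data.frame(chrom = sm$chrom[1L], site = 0:(n - 2L),
               start = sm$end[-n], end = sm$start[-1L],
               stringsAsFactors = FALSE)
  }))
}

# Snap a coordinate to the nearest value in `targets` within `tol`; NA if none.
snap_to <- function(x, targets, tol) {
  if (!length(targets)) return(NA_integer_)
  d <- abs(targets - x)
  i <- which.min(d)
  if (d[i] <= tol) i else NA_integer_
}

side_tuple <- function(site, side, strand) {
  c(site, if (side == "tail") 0L else 1L, if (strand == "+") 0L else 1L)
}

flip_side <- function(s) {
  s$strand <- if (s$strand == "+") "-" else "+"
  s
}

# Canonicalize a junction: reading the junction from the opposite strand
# swaps the two sides and flips both strands; keep the lexicographically
# smaller representation.
canonical_junction <- function(L, R) {
  t1 <- c(side_tuple(L$site, L$side, L$strand), side_tuple(R$site, R$side, R$strand))
  Lf <- flip_side(R); Rf <- flip_side(L)
  t2 <- c(side_tuple(Lf$site, Lf$side, Lf$strand), side_tuple(Rf$site, Rf$side, Rf$strand))
  cmp <- sign(t1 - t2)
  first <- cmp[cmp != 0][1]
  if (!is.na(first) && first > 0) list(L = Lf, R = Rf) else list(L = L, R = R)
}

#' Locate junctions from split-read fragments
#'
#' Aligns each flank fragment (mismatch allowance `min(2, floor(len / 25))`),
#' requires both flanks of a read to map uniquely to the same chromosome,
#' snaps the fragment end abutting the loxPsym to the nearest segment
#' boundary within `snap_tolerance`, and emits the canonical junction.
#' Wild-type adjacencies (flanks rejoining across the same reference site)
#' are dropped; unplaceable reads are counted in the `diagnostics` attribute.
#'
#' @param fragments Output of [split_read_at_loxpsym()].
#' @param reference Anything [as_reference()] understands.
#' @param segment_map Segment map of the reference ([derive_segment_map()]).
#' @param snap_tolerance Max distance (bp) between a fragment end and a
#'   segment boundary (default 2, sequencing-error slack).
#' @param k Seed length for fragment alignment.
#' @return `data.frame` of junction observations, one row per read, with
#'   columns `read`, `chrom`, `site_a`, `side_a`, `strand_a`, `site_b`,
#'   `side_b`, `strand_b`, `key`; diagnostics in `attr(x, "diagnostics")`.
#' @export
locate_junctions <- function(fragments, reference, segment_map,
                             snap_tolerance = 2L, k = 21L) {
  diag <- c(reads_in = 0L, not_unique = 0L, cross_chromosome = 0L,
            no_boundary = 0L, wild_type = 0L, junctions = 0L)
  empty <- data.frame(read = character(0), chrom = character(0),
                      site_a = integer(0), side_a = character(0),
                      strand_a = character(0), site_b = integer(0),
                      side_b = character(0), strand_b = character(0),
                      key = character(0), stringsAsFactors = FALSE)
  if (nrow(fragments) == 0L) {
    attr(empty, "diagnostics") <- diag
    return(empty)
  }
  seqs <- stats::setNames(fragments$sequence,
                          paste(fragments$read, fragments$side, sep = "\r"))
  mm <- pmin(2L, nchar(fragments$sequence) %/% 25L)
  aln <- align_sequences(seqs, reference, max_mismatch = mm,
                         k = min(k, min(nchar(fragments$sequence))))
  aln$read <- sub("\r.*$", "", aln$query)
  aln$side <- sub("^.*\r", "", aln$query)
  sites <- site_table(segment_map)

  rows <- list()
  for (id in unique(aln$read)) {
    diag["reads_in"] <- diag["reads_in"] + 1L
    a <- aln[aln$read == id, , drop = FALSE]
    lft <- a[a$side == "left", , drop = FALSE]
    rgt <- a[a$side == "right", , drop = FALSE]
    if (nrow(lft) != 1L || nrow(rgt) != 1L ||
        lft$status != "unique" || rgt$status != "unique") {
      diag["not_unique"] <- diag["not_unique"] + 1L
      next
    }
    if (lft$chrom != rgt$chrom) {
      diag["cross_chromosome"] <- diag["cross_chromosome"] + 1L
      next
    }
    st <- sites[sites$chrom == lft$chrom, , drop = FALSE]
    # left flank: its right end abuts the site
    if (lft$strand == "+") {
      iL <- snap_to(lft$start + lft$length, st$start, snap_tolerance)
      L <- list(site = st$site[iL], side = "tail", strand = "+")
    } else {
      iL <- snap_to(lft$start, st$end, snap_tolerance)
      L <- list(site = st$site[iL], side = "head", strand = "-")
    }
    # right flank: its left end abuts the site
    if (rgt$strand == "+") {
      iR <- snap_to(rgt$start, st$end, snap_tolerance)
      R <- list(site = st$site[iR], side = "head", strand = "+")
    } else {
      iR <- snap_to(rgt$start + rgt$length, st$start, snap_tolerance)
      R <- list(site = st$site[iR], side = "tail", strand = "-")
    }
    if (is.na(iL) || is.na(iR)) {
      diag["no_boundary"] <- diag["no_boundary"] + 1L
      next
    }
    j <- canonical_junction(L, R)
    if (j$L$site == j$R$site && j$L$side == "tail" && j$R$side == "head" &&
        j$L$strand == "+" && j$R$strand == "+") {
      diag["wild_type"] <- diag["wild_type"] + 1L
      next
    }
    diag["junctions"] <- diag["junctions"] + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      read = id, chrom = lft$chrom,
      site_a = j$L$site, side_a = j$L$side, strand_a = j$L$strand,
      site_b = j$R$site, side_b = j$R$side, strand_b = j$R$strand,
      key = sprintf("%s:%d%s%s>%d%s%s", lft$chrom,
                    j$L$site, substr(j$L$side, 1, 1), j$L$strand,
                    j$R$site, substr(j$R$side, 1, 1), j$R$strand),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  attr(out, "diagnostics") <- diag
  out
}

#' Cluster junction observations and apply the support threshold
#'
#' Observations are grouped on their exact canonical key (boundary snapping
#' already normalized coordinates, so clustering is exact grouping); support
#' is the number of distinct reads, and groups below `min_support` are
#' discarded.
#'
#' @param observations Output of [locate_junctions()].
#' @param min_support Minimum distinct supporting reads (default 5).
#' @return `data.frame` of supported junctions with a `support` column.
#' @export
cluster_junctions <- function(observations, min_support = 5L) {
  if (nrow(observations) == 0L) {
    out <- observations
    out$support <- integer(0)
    return(out[, c("chrom", "site_a", "side_a", "strand_a",
                   "site_b", "side_b", "strand_b", "support", "key")])
  }
  support <- tapply(observations$read, observations$key,
                    function(r) length(unique(r)))
  rep_rows <- observations[!duplicated(observations$key), , drop = FALSE]
  rep_rows$support <- as.integer(support[rep_rows$key])
  out <- rep_rows[rep_rows$support >= min_support,
                  c("chrom", "site_a", "side_a", "strand_a",
                    "site_b", "side_b", "strand_b", "support", "key"),
                  drop = FALSE]
  out <- out[order(out$chrom, out$site_a, out$site_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify SCRaMbLE events from supported junctions and depth
#'
#' Applies the orientation/depth rules (see the file header): a forward
#' tail-to-head junction skipping segments whose copy ratio is below
#' `deletion_max_ratio` is a deletion; a back-join whose spanned segments
#' have copy ratio at least `duplication_min_ratio` is a tandem duplication;
#' a reciprocal pair of orientation-flipped junctions bracketing segments
#' with copy ratio inside `inversion_ratio_range` is an inversion. Anything
#' else — including junctions whose depth evidence is missing or out of range
#' — is reported as `complex` with all evidence attached.
#'
#' @param junctions Output of [cluster_junctions()].
#' @param depth A `depth_profile` from [compute_depth()] on the same sample.
#' @param segment_map The reference segment map.
#' @param thresholds List with `deletion_max_ratio` (default 0.25),
#'   `duplication_min_ratio` (1.6), `inversion_ratio_range` (c(0.75, 1.25)).
#' @param genes Optional gene annotation `data.frame` (`name`, `start`,
#'   `end`, `strand`); overlapping gene names are added to `notes`.
#' @return `data.frame` of event calls: `chrom`, `type`, `seg_first`,
#'   `seg_last`, `site_a`, `site_b`, `support`, `mean_copy_ratio`,
#'   `junctions`, `notes`.
#' @export
classify_events <- function(junctions, depth, segment_map,
                            thresholds = list(deletion_max_ratio = 0.25,
                                              duplication_min_ratio = 1.6,
                                              inversion_ratio_range = c(0.75, 1.25)),
                            genes = NULL) {
  th <- utils::modifyList(list(deletion_max_ratio = 0.25,
                               duplication_min_ratio = 1.6,
                               inversion_ratio_range = c(0.75, 1.25)),
                          as.list(thresholds))
  ratio_of <- function(chrom, segs) {
    r <- depth$copy_ratio[match(paste(chrom, segs), paste(depth$chrom, depth$segment))]
    if (length(r) == 0L) NA_real_ else mean(r)
  }
  gene_note <- function(chrom, segs) {
    if (is.null(genes) || !length(segs)) return("")
    sm <- segment_map[segment_map$chrom == chrom & segment_map$segment %in% segs, ]
    if (!nrow(sm)) return("")
    lo <- min(sm$start); hi <- max(sm$end)
    hit <- genes$name[genes$start < hi & genes$end > lo]
    if (length(hit)) paste0("genes=", paste(hit, collapse = ",")) else ""
  }
  calls <- list()
  emit <- function(chrom, type, segs, site_a, site_b, support, keys, note = "") {
    mcr <- ratio_of(chrom, segs)
    notes <- paste(c(note, gene_note(chrom, segs)), collapse = " ")
    calls[[length(calls) + 1L]] <<- data.frame(
      chrom = chrom, type = type,
      seg_first = if (length(segs)) min(segs) else NA_integer_,
      seg_last = if (length(segs)) max(segs) else NA_integer_,
      site_a = site_a, site_b = site_b, support = support,
      mean_copy_ratio = mcr, junctions = paste(keys, collapse = ";"),
      notes = trimws(notes), stringsAsFactors = FALSE)
  }
  j <- junctions
  used <- rep(FALSE, nrow(j))

  # inversion: reciprocal flipped-orientation pairs first
  is_j1 <- j$side_a == "tail" & j$side_b == "tail" & j$strand_a == "+" & j$strand_b == "-"
  is_j2 <- j$side_a == "head" & j$side_b == "head" & j$strand_a == "-" & j$strand_b == "+"
  for (i in which(is_j1)) {
    m <- which(is_j2 & j$chrom == j$chrom[i] &
               j$site_a == j$site_a[i] & j$site_b == j$site_b[i] & !used)
    if (length(m)) {
      m <- m[1L]
      segs <- (j$site_a[i] + 1L):j$site_b[i]
      r <- ratio_of(j$chrom[i], segs)
      type <- if (!is.na(r) && r >= th$inversion_ratio_range[1] &&
                  r <= th$inversion_ratio_range[2]) "inversion" else "complex"
      note <- if (type == "complex") {
        if (is.na(r)) "inversion-pattern junction pair; depth missing"
        else "inversion-pattern junction pair; copy ratio out of range"
      } else ""
      emit(j$chrom[i], type, segs, j$site_a[i], j$site_b[i],
           j$support[i] + j$support[m], c(j$key[i], j$key[m]), note)
      used[c(i, m)] <- TRUE
    }
  }
  for (i in which(!used)) {
    chrom <- j$chrom[i]; a <- j$site_a[i]; b <- j$site_b[i]
    segs <- if (a < b) (a + 1L):b else integer(0)
    if (j$strand_a[i] == "+" && j$strand_b[i] == "+" &&
        j$side_a[i] == "tail" && j$side_b[i] == "head" && a < b) {
      r <- ratio_of(chrom, segs)
      if (!is.na(r) && r < th$deletion_max_ratio) {
        emit(chrom, "deletion", segs, a, b, j$support[i], j$key[i])
      } else {
        emit(chrom, "complex", segs, a, b, j$support[i], j$key[i],
             if (is.na(r)) "deletion-pattern junction; depth missing"
             else "deletion-pattern junction; copy ratio too high")
      }
    } else if (j$strand_a[i] == "-" && j$strand_b[i] == "-" &&
               j$side_a[i] == "head" && j$side_b[i] == "tail" && a < b) {
      r <- ratio_of(chrom, segs)
      if (!is.na(r) && r >= th$duplication_min_ratio) {
        emit(chrom, "tandem_duplication", segs, a, b, j$support[i], j$key[i])
      } else {
        emit(chrom, "complex", segs, a, b, j$support[i], j$key[i],
             if (is.na(r)) "duplication-pattern junction; depth missing"
             else "duplication-pattern junction; copy ratio too low")
      }
    } else {
      emit(chrom, "complex", segs, a, b, j$support[i], j$key[i],
           "unpaired or unrecognized orientation pattern")
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else data.frame(
    chrom = character(0), type = character(0), seg_first = integer(0),
    seg_last = integer(0), site_a = integer(0), site_b = integer(0),
    support = integer(0), mean_copy_ratio = numeric(0),
    junctions = character(0), notes = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$seg_first), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full split-read calling on a set of read pairs
#'
#' Convenience wrapper running QC filtering, mapping, depth profiling,
#' loxPsym splitting of unmapped reads, junction location, clustering and
#' classification against a parental reference chromosome (or list of
#' chromosomes).
#'
#' @param pairs A `read_pairs` data.frame.
#' @param reference A `lox_chromosome` or list of them (the parental genome).
#' @param min_mean_phred,drop_if_any_n QC parameters ([filter_read_pairs()]).
#' @param k,max_mismatch Mapper parameters ([map_reads()]).
#' @param min_flank,max_site_mismatch Split parameters
#'   ([split_read_at_loxpsym()]).
#' @param min_support Junction support threshold ([cluster_junctions()]).
#' @param snap_tolerance Boundary snap tolerance ([locate_junctions()]).
#' @param thresholds Depth thresholds ([classify_events()]).
#' @return List with `events`, `junctions`, `observations`, `depth`,
#'   `filter_stats`, `diagnostics`.
#' @export
call_events <- function(pairs, reference, min_mean_phred = 10,
                        drop_if_any_n = TRUE, k = 21L, max_mismatch = 4L,
                        min_flank = 15L, max_site_mismatch = 2L,
                        min_support = 5L, snap_tolerance = 2L,
                        thresholds = list()) {
  chroms <- if (inherits(reference, "lox_chromosome")) list(reference) else reference
  stopifnot(all(vapply(chroms, inherits, logical(1), "lox_chromosome")))
  segment_map <- do.call(rbind, lapply(chroms, derive_segment_map))
  genes <- do.call(rbind, lapply(chroms, function(ch) ch$genes))
  loxpsym <- chroms[[1L]]$loxpsym

  qc <- filter_read_pairs(pairs, min_mean_phred = min_mean_phred,
                          drop_if_any_n = drop_if_any_n)
  aln <- map_reads(qc$pairs, chroms, k = k, max_mismatch = max_mismatch)
  depth <- compute_depth(aln, segment_map)

  un <- aln[aln$status == "unmapped", , drop = FALSE]
  reads <- if (nrow(un)) {
    mate_seq <- ifelse(un$mate == 1L,
                       qc$pairs$seq1[match(un$read, qc$pairs$id)],
                       qc$pairs$seq2[match(un$read, qc$pairs$id)])
    stats::setNames(mate_seq, paste0(un$read, "/", un$mate))
  } else character(0)
  frags <- split_read_at_loxpsym(reads, loxpsym, min_flank = min_flank,
                                 max_site_mismatch = max_site_mismatch)
  obs <- locate_junctions(frags, chroms, segment_map,
                          snap_tolerance = snap_tolerance, k = k)
  junctions <- cluster_junctions(obs, min_support = min_support)
  events <- classify_events(junctions, depth, segment_map,
                            thresholds = thresholds, genes = genes)
  list(events = events, junctions = junctions, observations = obs,
       depth = depth, filter_stats = qc$stats,
       diagnostics = attr(obs, "diagnostics"))
}
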