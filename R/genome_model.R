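# Synthetic chromosome model and Cre/loxPsym rearrangement simulator.
#
# A chromosome is a sequence partitioned by 34-bp palindromic loxPsym sites
# into segments, the atomic units that SCRaMbLE shuffles. A rearranged
# molecule is represented as an ordered list of oriented segment blocks with
# exactly one loxPsym between consecutive blocks; this makes the Cre
# bookkeeping (one site retained per deletion junction, both retained for an
# inversion, one gained per tandem duplication) exact by construction, and
# the emitted sequence is always reconstructible from the provenance blocks.

#' Canonical loxPsym site sequence
#'
#' The 34-bp palindromic loxP variant used in the Sc2.0 synthetic chromosomes:
#' two 13-bp recombinase-binding arms around a symmetric 8-bp spacer, so the
#' site equals its own reverse complement and recombines in either
#' orientation.
#'
#' @return A 34-character DNA string.
#' @export
loxpsym_sequence <- function() {
  "ATAACTTCGTATAATGTACATTATACGAAGTTAT"
}

#' Build a toy synthetic chromosome
#'
#' Constructs a chromosome from random DNA segments separated by loxPsym
#' sites: `L` segments produce `L - 1` internal sites. Gene annotations are
#' optional bookkeeping used to label called events.
#'
#' @param segment_lengths Integer vector of segment lengths in bp, all > 0.
#' @param loxpsym Site sequence; a warning is issued if it is not a perfect
#'   reverse-complement palindrome.
#' @param genes Optional `data.frame` with columns `name`, `start`, `end`
#'   (0-based half-open) and `strand`; intervals must lie within the
#'   chromosome.
#' @param id Chromosome name.
#' @param seed Optional RNG seed; the same config and seed give byte-identical
#'   chromosomes.
#' @return An object of class `lox_chromosome` with fields `id`, `sequence`,
#'   `loxpsym_starts` (0-based site start coordinates), `loxpsym`, `genes`.
#' @export
build_toy_genome <- function(segment_lengths, loxpsym = loxpsym_sequence(),
                             genes = NULL, id = "chrSCR", seed = NULL) {
  segment_lengths <- as.integer(segment_lengths)
  if (length(segment_lengths) < 1L || any(segment_lengths <= 0L)) {
    stop("segment_lengths must contain at least one positive length")
  }
  if (!nzchar(loxpsym) || !is_dna(loxpsym)) {
    stop("loxpsym must be a non-empty DNA sequence over A/C/G/T/N")
  }
  if (!is_palindromic_site(loxpsym)) {
    warning("configured loxPsym site is not a reverse-complement palindrome; ",
            "orientation-independent recombination will not hold")
  }
  if (!is.null(seed)) set.seed(seed)
  segments <- vapply(segment_lengths, random_dna, "")
  sequence <- paste(segments, collapse = loxpsym)
  n_sites <- length(segment_lengths) - 1L
  site_w <- nchar(loxpsym)
  starts <- if (n_sites > 0L) {
    cumsum(segment_lengths)[seq_len(n_sites)] + site_w * (seq_len(n_sites) - 1L)
  } else integer(0)
  chrom <- structure(
    list(id = id, sequence = sequence, loxpsym_starts = as.integer(starts),
         loxpsym = loxpsym, genes = NULL),
    class = "lox_chromosome"
  )
  if (!is.null(genes)) {
    req <- c("name", "start", "end", "strand")
    if (!all(req %in% names(genes))) {
      stop("genes must have columns name, start, end, strand")
    }
    if (any(genes$start < 0) || any(genes$end > nchar(sequence)) ||
        any(genes$start >= genes$end)) {
      stop("gene intervals must be non-empty and within chromosome bounds")
    }
    chrom$genes <- genes[, req]
  }
  validate_chromosome(chrom)
  chrom
}

validate_chromosome <- function(chrom) {
  stopifnot(inherits(chrom, "lox_chromosome"))
  s <- chrom$loxpsym_starts
  w <- nchar(chrom$loxpsym)
  if (length(s) > 1L && any(diff(s) < w)) {
    stop("loxPsym sites must be strictly increasing and non-overlapping")
  }
  if (length(s)) {
    at <- substring(chrom$sequence, s + 1L, s + w)
    if (!all(at == chrom$loxpsym)) {
      stop("loxPsym annotation inconsistent with sequence in '", chrom$id, "'")
    }
  }
  invisible(chrom)
}

#' Derive the segment map of a chromosome
#'
#' Segments are the maximal intervals between consecutive loxPsym sites (and
#' the chromosome ends), indexed consecutively from 0; they are the
#' coordinate system every event call is reported in. Site index `j`
#' separates segment `j` from segment `j + 1`.
#'
#' @param chrom A `lox_chromosome`.
#' @return `data.frame` with columns `chrom`, `segment`, `start`, `end`
#'   (0-based half-open).
#' @export
derive_segment_map <- function(chrom) {
  validate_chromosome(chrom)
  w <- nchar(chrom$loxpsym)
  L <- nchar(chrom$sequence)
  s <- chrom$loxpsym_starts
  starts <- c(0L, s + w)
  ends <- c(s, L)
  data.frame(chrom = chrom$id, segment = seq_along(starts) - 1L,
             start = as.integer(starts), end = as.integer(ends),
             stringsAsFactors = FALSE)
}

#' Construct a SCRaMbLE event
#'
#' @param type One of `"deletion"`, `"inversion"`, `"tandem_duplication"`.
#' @param site_a,site_b loxPsym start coordinates on the current molecule,
#'   with `site_a < site_b`.
#' @param chrom Chromosome id (optional; filled in by [apply_event()]).
#' @return A `scramble_event`.
#' @export
scramble_event <- function(type, site_a, site_b, chrom = NA_character_) {
  type <- match.arg(type, c("deletion", "inversion", "tandem_duplication"))
  site_a <- as.integer(site_a); site_b <- as.integer(site_b)
  if (!(site_a < site_b)) stop("site_a must be strictly less than site_b")
  structure(list(type = type, site_a = site_a, site_b = site_b, chrom = chrom),
            class = "scramble_event")
}

# Identity rearrangement of a chromosome: one block per segment, all forward.
as_rearranged <- function(chrom) {
  if (inherits(chrom, "rearranged_genome")) return(chrom)
  validate_chromosome(chrom)
  seg_map <- derive_segment_map(chrom)
  segs <- substring(chrom$sequence, seg_map$start + 1L, seg_map$end)
  structure(
    list(chrom = chrom$id, parent = chrom,
         segment_seqs = segs, loxpsym = chrom$loxpsym,
         blocks = data.frame(segment = seg_map$segment,
                             orientation = rep("+", nrow(seg_map)),
                             stringsAsFactors = FALSE),
         truth_events = data.frame(chrom = character(0), type = character(0),
                                   site_a = integer(0), site_b = integer(0),
                                   stringsAsFactors = FALSE)),
    class = "rearranged_genome"
  )
}

#' loxPsym start coordinates of a molecule
#'
#' @param x A `lox_chromosome` or `rearranged_genome`.
#' @return Integer vector of 0-based site start coordinates on the current
#'   molecule.
#' @export
loxpsym_starts <- function(x) UseMethod("loxpsym_starts")

#' @export
loxpsym_starts.lox_chromosome <- function(x) x$loxpsym_starts

#' @export
loxpsym_starts.rearranged_genome <- function(x) {
  bl <- nchar(x$segment_seqs)[x$blocks$segment + 1L]
  n <- length(bl)
  if (n <= 1L) return(integer(0))
  w <- nchar(x$loxpsym)
  as.integer(cumsum(bl[-n]) + w * (seq_len(n - 1L) - 1L))
}

#' Emit the sequence of a rearranged molecule
#'
#' Concatenates the provenance blocks (reverse-complemented where the
#' orientation is `-`) with one loxPsym between consecutive blocks; this is
#' the reconstruction invariant of the Cre model.
#'
#' @param rg A `rearranged_genome`.
#' @return A DNA string.
#' @export
rearranged_sequence <- function(rg) {
  stopifnot(inherits(rg, "rearranged_genome"))
  segs <- rg$segment_seqs[rg$blocks$segment + 1L]
  flip <- rg$blocks$orientation == "-"
  if (any(flip)) segs[flip] <- revcomp(segs[flip])
  paste(segs, collapse = rg$loxpsym)
}

#' Provenance blocks of a rearranged molecule
#'
#' @param rg A `rearranged_genome`.
#' @return `data.frame` with columns `segment` (parental segment index),
#'   `orientation`, and `copy` (occurrence index of that segment).
#' @export
provenance <- function(rg) {
  stopifnot(inherits(rg, "rearranged_genome"))
  b <- rg$blocks
  b$copy <- stats::ave(seq_len(nrow(b)), b$segment, FUN = seq_along)
  b
}

#' Truth events accumulated on a molecule or a list of molecules
#'
#' @param x A `rearranged_genome` or list of them.
#' @return `data.frame` with columns `chrom`, `type`, `site_a`, `site_b`
#'   (site coordinates on the molecule at the time each event was applied).
#' @export
truth_events <- function(x) {
  if (inherits(x, "rearranged_genome")) return(x$truth_events)
  stopifnot(is.list(x))
  do.call(rbind, lapply(x, truth_events))
}

#' Apply a single Cre/loxPsym event
#'
#' Deletion removes `[site_a, site_b)` leaving exactly one loxPsym at the
#' junction; inversion reverse-complements the interval between the two sites
#' and retains both; tandem duplication inserts a second copy of
#' `[site_a, site_b)` at `site_b`, gaining one site.
#'
#' @param genome A `lox_chromosome` or `rearranged_genome`.
#' @param event A [scramble_event()] whose sites are loxPsym starts on the
#'   current molecule.
#' @return A `rearranged_genome` with the event appended to `truth_events`.
#' @export
apply_event <- function(genome, event) {
  stopifnot(inherits(event, "scramble_event"))
  rg <- as_rearranged(genome)
  sites <- loxpsym_starts(rg)
  ga <- match(event$site_a, sites)
  gb <- match(event$site_b, sites)
  if (is.na(ga) || is.na(gb)) {
    stop("event site coordinate is not a loxPsym start on the current molecule")
  }
  idx <- (ga + 1L):gb  # blocks strictly between the two sites, 1-based
  b <- rg$blocks
  if (event$type == "deletion") {
    b <- b[-idx, , drop = FALSE]
  } else if (event$type == "inversion") {
    mid <- b[rev(idx), , drop = FALSE]
    mid$orientation <- ifelse(mid$orientation == "+", "-", "+")
    b[idx, ] <- mid
  } else {  # tandem_duplication
    b <- rbind(b[seq_len(gb), , drop = FALSE],
               b[idx, , drop = FALSE],
               if (gb < nrow(b)) b[(gb + 1L):nrow(b), , drop = FALSE])
  }
  rownames(b) <- NULL
  rg$blocks <- b
  rg$truth_events <- rbind(
    rg$truth_events,
    data.frame(chrom = rg$chrom, type = event$type,
               site_a = event$site_a, site_b = event$site_b,
               stringsAsFactors = FALSE)
  )
  rg
}

#' Simulate a series of random SCRaMbLE events
#'
#' Each event picks a molecule (probability proportional to its number of
#' valid site pairs), a uniformly random pair of loxPsym sites on the current
#' molecule, and an event type from `type_probabilities`; events are applied
#' sequentially, so later events act on already-rearranged coordinates. Only
#' intramolecular events are generated.
#'
#' @param genome A `lox_chromosome`, `rearranged_genome`, or list of either.
#' @param n_events Number of events (>= 0).
#' @param type_probabilities Named numeric vector over the three event types,
#'   summing to 1. The default mix leans on deletions, the most frequent
#'   outcome among verified SCRaMbLEd strains.
#' @param seed Optional RNG seed; the same inputs and seed give identical
#'   truth-event lists and sequences.
#' @return A `rearranged_genome`, or a list of them if `genome` was a list.
#' @export
random_scramble <- function(genome, n_events,
                            type_probabilities = c(deletion = 0.5,
                                                   inversion = 0.3,
                                                   tandem_duplication = 0.2),
                            seed = NULL) {
  if (n_events < 0) stop("n_events must be >= 0")
  types <- c("deletion", "inversion", "tandem_duplication")
  if (!all(types %in% names(type_probabilities)) ||
      abs(sum(type_probabilities) - 1) > 1e-8) {
    stop("type_probabilities must be named over the three event types and sum to 1")
  }
  if (!is.null(seed)) set.seed(seed)
  was_list <- is.list(genome) && !inherits(genome, c("lox_chromosome", "rearranged_genome"))
  mols <- if (was_list) lapply(genome, as_rearranged) else list(as_rearranged(genome))
  for (i in seq_len(n_events)) {
    n_sites <- vapply(mols, function(m) length(loxpsym_starts(m)), integer(1))
    n_pairs <- n_sites * (n_sites - 1L) / 2
    if (all(n_pairs == 0)) {
      stop("no molecule has >= 2 loxPsym sites; cannot draw an event")
    }
    mi <- sample.int(length(mols), 1L, prob = n_pairs)
    sites <- loxpsym_starts(mols[[mi]])
    pair <- sort(sample(sites, 2L))
    type <- sample(types, 1L, prob = type_probabilities[types])
    mols[[mi]] <- apply_event(mols[[mi]], scramble_event(type, pair[1L], pair[2L],
                                                         mols[[mi]]$chrom))
  }
  if (was_list) mols else mols[[1L]]
}

#' @export
print.lox_chromosome <- function(x, ...) {
  cat(sprintf("<lox_chromosome> %s: %d bp, %d loxPsym sites, %d genes\n",
              x$id, nchar(x$sequence), length(x$loxpsym_starts),
              if (is.null(x$genes)) 0L else nrow(x$genes)))
  invisible(x)
}

#' @export
print.rearranged_genome <- function(x, ...) {
  cat(sprintf("<rearranged_genome> %s: %d blocks, %d loxPsym sites, %d truth events\n",
              x$chrom, nrow(x$blocks), length(loxpsym_starts(x)),
              nrow(x$truth_events)))
  invisible(x)
}

#' Write a genome as FASTA
#'
#' @param x Anything [as_reference()] understands (chromosome, rearranged
#'   molecule, list, named character vector).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(x, path) {
  ref <- as_reference(x)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref), path)
  invisible(path)
}

#' Write loxPsym sites (and genes, if any) as BED
#'
#' 0-based half-open intervals, one line per site named `loxPsym_<j>`.
#'
#' @param chrom A `lox_chromosome`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(chrom, path) {
  validate_chromosome(chrom)
  s <- chrom$loxpsym_starts
  bed <- data.frame(chrom = chrom$id, start = s, end = s + nchar(chrom$loxpsym),
                    name = sprintf("loxPsym_%d", seq_along(s) - 1L))
  if (!is.null(chrom$genes)) {
    bed <- rbind(bed, data.frame(chrom = chrom$id, start = chrom$genes$start,
                                 end = chrom$genes$end, name = chrom$genes$name))
  }
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write ground-truth events as TSV
#'
#' @param truth A truth-event `data.frame` (see [truth_events()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth_events <- function(truth, path) write_tsv(truth, path)
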