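# Distance-based phylogeny for protein families: p-distances from an existing
# alignment (pairwise deletion of gapped columns) and a from-scratch
# Saitou-Nei neighbor-joining implementation with deterministic lexicographic
# tie-breaking. Trees are returned as ape "phylo" objects so the surrounding
# ecosystem (plotting, Newick IO, cophenetic distances) applies directly.

#' Pairwise p-distance matrix from an aligned protein FASTA or vector
#'
#' `d(i, j)` is the fraction of differing residues over columns that are
#' ungapped in *both* sequences (pairwise deletion). The Poisson correction
#' `-log(1 - p)` is available for multiple substitutions.
#'
#' @param alignment Named character vector of equal-length aligned sequences,
#'   an `AAStringSet`, or a path to an aligned FASTA file.
#' @param model `"p"` (default) or `"poisson"`.
#' @param gap_chars Characters treated as gaps (default `-` and `.`).
#' @return Symmetric numeric matrix with taxon dimnames; the per-pair count
#'   of comparable columns is in `attr(x, "comparable_sites")`.
#' @export
p_distance_matrix <- function(alignment, model = c("p", "poisson"),
                              gap_chars = c("-", ".")) {
  model <- match.arg(model)
  if (is.character(alignment) && length(alignment) == 1L && file.exists(alignment)) {
    aln <- Biostrings::readAAStringSet(alignment)
    alignment <- stats::setNames(as.character(aln), names(aln))
  } else if (methods::is(alignment, "XStringSet")) {
    alignment <- stats::setNames(as.character(alignment), names(alignment))
  }
  n <- length(alignment)
  if (n < 2L) stop("need at least 2 sequences")
  if (length(unique(nchar(alignment))) != 1L) {
    stop("aligned sequences must all have equal length")
  }
  labels <- names(alignment)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  M <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
  gap <- matrix(M %in% gap_chars, nrow = n)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  comp <- matrix(nchar(alignment[1L]), n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !gap[i, ] & !gap[j, ]
      nc <- sum(ok)
      if (nc == 0L) {
        stop("sequences '", labels[i], "' and '", labels[j],
             "' share no comparable (ungapped) columns")
      }
      p <- sum(M[i, ok] != M[j, ok]) / nc
      d <- if (model == "poisson") {
        if (p >= 1) stop("p-distance of 1 cannot be Poisson-corrected")
        -log(1 - p)
      } else p
      D[i, j] <- D[j, i] <- d
      comp[i, j] <- comp[j, i] <- nc
    }
  }
  attr(D, "comparable_sites") <- comp
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou-Nei agglomeration: repeatedly join the pair minimizing
#' the Q-criterion `(n - 2) d(i, j) - r_i - r_j`, assign pendant branch
#' lengths by the standard two-point formulas, reduce the matrix, and close
#' with the 3-taxon (or 2-taxon) star. Ties in Q are broken by the
#' lexicographically smallest label pair, so the result is deterministic.
#' Branch lengths may be negative (an NJ artifact) and are reported as
#' computed. On an additive matrix the generating topology and path lengths
#' are recovered exactly.
#'
#' @param D Symmetric distance matrix with taxon labels as dimnames.
#' @return An unrooted `phylo` object (ape); the Newick string is attached as
#'   `attr(x, "newick")`.
#' @export
nj_tree <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be a square matrix")
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 taxa")
  labels <- rownames(D)
  if (is.null(labels)) stop("D must have taxon labels as dimnames")
  if (max(abs(D - t(D))) > 1e-12) stop("D must be symmetric")
  if (any(diag(D) != 0)) stop("D must have a zero diagonal")

  fmt <- function(x) sprintf("%.17g", x)
  node <- labels      # growing newick substrings
  key <- labels       # lexicographic tie-break keys (smallest leaf inside)
  M <- D
  while (length(node) > 3L) {
    m <- length(node)
    r <- rowSums(M)
    Q <- (m - 2) * M - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    ties <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    ties <- ties[ties[, 1] < ties[, 2], , drop = FALSE]
    pair_key <- apply(ties, 1L, function(ij) {
      k <- sort(c(key[ij[1]], key[ij[2]]))
      paste(k, collapse = "\r")
    })
    sel <- ties[order(pair_key)[1L], ]
    i <- sel[[1L]]; j <- sel[[2L]]
    li <- M[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- M[i, j] - li
    newick <- sprintf("(%s:%s,%s:%s)", node[i], fmt(li), node[j], fmt(lj))
    dnew <- (M[i, ] + M[j, ] - M[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    M2 <- rbind(cbind(M[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    M <- M2
    node <- c(node[keep], newick)
    key <- c(key[keep], min(key[c(i, j)]))
  }
  newick <- if (length(node) == 3L) {
    x <- (M[1, 2] + M[1, 3] - M[2, 3]) / 2
    y <- (M[1, 2] + M[2, 3] - M[1, 3]) / 2
    z <- (M[1, 3] + M[2, 3] - M[1, 2]) / 2
    sprintf("(%s:%s,%s:%s,%s:%s);", node[1], fmt(x), node[2], fmt(y),
            node[3], fmt(z))
  } else {
    sprintf("(%s:%s,%s:%s);", node[1], fmt(M[1, 2] / 2), node[2], fmt(M[1, 2] / 2))
  }
  tree <- ape::read.tree(text = newick)
  attr(tree, "newick") <- newick
  tree
}

#' Write a tree in Newick format
#'
#' @param tree A `phylo` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a distance matrix as TSV
#'
#' @param D Distance matrix from [p_distance_matrix()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(D, path) {
  df <- data.frame(taxon = rownames(D), as.data.frame(D, check.names = FALSE),
                   check.names = FALSE)
  write_tsv(df, path)
}

#' Simulate a protein alignment along a random tree
#'
#' Synthetic stand-in for a homolog family alignment: a random binary tree
#' with uniform branch lengths is generated, and sequences evolve from a
#' random root by per-site substitution with probability `1 - exp(-b)` on a
#' branch of length `b` (Poisson-style, uniform replacement among the 19
#' other residues). No indels are introduced, so the result is an alignment
#' by construction.
#'
#' @param n_taxa Number of taxa (>= 3).
#' @param n_sites Alignment columns (default 300).
#' @param branch_range Branch-length range (default `c(0.02, 0.25)`).
#' @param seed Optional RNG seed.
#' @return List with `alignment` (named character vector) and `tree` (the
#'   generating `phylo`).
#' @export
simulate_protein_alignment <- function(n_taxa, n_sites = 300L,
                                       branch_range = c(0.02, 0.25),
                                       seed = NULL) {
  stopifnot(n_taxa >= 3L)
  if (!is.null(seed)) set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  tree <- ape::rtree(n_taxa, rooted = TRUE,
                     br = function(k) stats::runif(k, branch_range[1], branch_range[2]))
  tree <- ape::reorder.phylo(tree, "cladewise")
  n_nodes <- n_taxa + tree$Nnode
  seqs <- vector("list", n_nodes)
  root <- n_taxa + 1L
  seqs[[root]] <- sample(aa, n_sites, replace = TRUE)
  for (e in seq_len(nrow(tree$edge))) {
    from <- tree$edge[e, 1L]; to <- tree$edge[e, 2L]
    s <- seqs[[from]]
    hit <- which(stats::runif(n_sites) < 1 - exp(-tree$edge.length[e]))
    for (h in hit) s[h] <- sample(setdiff(aa, s[h]), 1L)
    seqs[[to]] <- s
  }
  alignment <- vapply(seq_len(n_taxa), function(i) paste(seqs[[i]], collapse = ""), "")
  names(alignment) <- tree$tip.label
  list(alignment = alignment, tree = tree)
}
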