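# Split-read junction caller: splitting rules, junction geometry,
# clustering, classification, and invariances.

toy <- function(seed = 41, n_seg = 8, len = 800) {
  build_toy_genome(rep(len, n_seg), seed = seed)
}

test_that("reads are split at loxPsym only when both flanks reach 15 bp", {
  set.seed(42)
  lox <- loxpsym_sequence()
  r1 <- paste0(random_dna(40), lox, random_dna(26))
  f1 <- split_read_at_loxpsym(setNames(r1, "a"))
  expect_equal(nrow(f1), 2)
  expect_equal(f1$flank_length, c(40L, 26L))
  expect_equal(f1$sequence[1], substr(r1, 1, 40))
  expect_equal(f1$sequence[2], substr(r1, 75, 100))

  r2 <- paste0(random_dna(80), lox, random_dna(14))
  expect_equal(nrow(split_read_at_loxpsym(setNames(r2, "b"))), 0)

  r3 <- random_dna(100)
  expect_equal(nrow(split_read_at_loxpsym(setNames(r3, "c"))), 0)

  expect_error(split_read_at_loxpsym(setNames("ACGTACGT", "d")),
               "longer than")
})

test_that("site matching tolerates up to max_site_mismatch substitutions", {
  set.seed(43)
  lox <- loxpsym_sequence()
  mutate <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(length(ch), k)
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    paste(ch, collapse = "")
  }
  left <- random_dna(30); right <- random_dna(30)
  r2 <- paste0(left, mutate(lox, 2), right)
  f <- split_read_at_loxpsym(setNames(r2, "x"))
  expect_equal(nrow(f), 2)
  expect_equal(f$site_mismatches[1], 2)
  r3 <- paste0(left, mutate(lox, 3), right)
  expect_equal(nrow(split_read_at_loxpsym(setNames(r3, "y"))), 0)
})

test_that("split fragments reconstruct the read window on error-free reads", {
  set.seed(44)
  lox <- loxpsym_sequence()
  for (i in 1:50) {
    lf <- sample(15:60, 1); rf <- sample(15:60, 1)
    r <- paste0(random_dna(lf), lox, random_dna(rf))
    f <- split_read_at_loxpsym(setNames(r, "r"))
    expect_equal(nrow(f), 2)
    expect_identical(paste0(f$sequence[1], lox, f$sequence[2]), r)
  }
})

# Build a junction-spanning read from a rearranged molecule: the window of
# `width` bp centered on the retained site at molecule coordinate `jpos`.
junction_read <- function(donor_seq, jpos, left = 33, right = 33) {
  substr(donor_seq, jpos - left + 1, jpos + 34 + right)
}

locate_one <- function(read, ref) {
  frags <- split_read_at_loxpsym(setNames(read, "jr"))
  locate_junctions(frags, ref, derive_segment_map(ref))
}

test_that("deletion junctions are located with tail->head forward geometry", {
  g <- toy()
  sites <- g$loxpsym_starts
  rg <- apply_event(g, scramble_event("deletion", sites[3], sites[5], g$id))
  jpos <- loxpsym_starts(rg)[3]
  obs <- locate_one(junction_read(rearranged_sequence(rg), jpos), g)
  expect_equal(nrow(obs), 1)
  expect_equal(obs$site_a, 2L)  # 0-based site indices
  expect_equal(obs$site_b, 4L)
  expect_equal(c(obs$side_a, obs$side_b), c("tail", "head"))
  expect_equal(c(obs$strand_a, obs$strand_b), c("+", "+"))
})

test_that("a wild-type adjacency read produces no junction, on either strand", {
  g <- toy()
  read <- junction_read(g$sequence, g$loxpsym_starts[4])
  obs <- locate_one(read, g)
  expect_equal(nrow(obs), 0)
  expect_equal(attr(obs, "diagnostics")[["wild_type"]], 1)
  obs_rc <- locate_one(revcomp(read), g)
  expect_equal(nrow(obs_rc), 0)
  expect_equal(attr(obs_rc, "diagnostics")[["wild_type"]], 1)
})

test_that("inversion junctions appear as a reciprocal orientation-flipped pair", {
  g <- toy()
  sites <- g$loxpsym_starts
  rg <- apply_event(g, scramble_event("inversion", sites[3], sites[5], g$id))
  donor <- rearranged_sequence(rg)
  jp <- loxpsym_starts(rg)
  o1 <- locate_one(junction_read(donor, jp[3]), g)
  o2 <- locate_one(junction_read(donor, jp[5]), g)
  expect_equal(nrow(o1), 1); expect_equal(nrow(o2), 1)
  expect_equal(c(o1$side_a, o1$side_b), c("tail", "tail"))
  expect_equal(c(o1$strand_a, o1$strand_b), c("+", "-"))
  expect_equal(c(o2$side_a, o2$side_b), c("head", "head"))
  expect_equal(c(o2$strand_a, o2$strand_b), c("-", "+"))
  expect_equal(c(o1$site_a, o1$site_b, o2$site_a, o2$site_b),
               c(2L, 4L, 2L, 4L))
})

test_that("duplication junctions appear as a canonical back-join", {
  g <- toy()
  sites <- g$loxpsym_starts
  rg <- apply_event(g, scramble_event("tandem_duplication", sites[3], sites[5], g$id))
  jpos <- loxpsym_starts(rg)[5]  # junction between the two copies
  obs <- locate_one(junction_read(rearranged_sequence(rg), jpos), g)
  expect_equal(nrow(obs), 1)
  expect_equal(c(obs$side_a, obs$side_b), c("head", "tail"))
  expect_equal(c(obs$strand_a, obs$strand_b), c("-", "-"))
  expect_equal(c(obs$site_a, obs$site_b), c(2L, 4L))
})

test_that("the canonical key is invariant to reading the junction from either strand", {
  g <- toy()
  sites <- g$loxpsym_starts
  gap_of <- c(deletion = 2L, inversion = 2L, tandem_duplication = 4L)
  for (type in names(gap_of)) {
    rg <- apply_event(g, scramble_event(type, sites[2], sites[4], g$id))
    donor <- rearranged_sequence(rg)
    jpos <- loxpsym_starts(rg)[gap_of[[type]]]
    read <- junction_read(donor, jpos)
    k_fwd <- locate_one(read, g)$key
    k_rev <- locate_one(revcomp(read), g)$key
    expect_length(k_fwd, 1)
    expect_identical(k_fwd, k_rev)
  }
})

test_that("clustering applies the support-5 rule and matches a brute-force tally", {
  g <- toy()
  sites <- g$loxpsym_starts
  rg <- apply_event(g, scramble_event("deletion", sites[3], sites[5], g$id))
  jpos <- loxpsym_starts(rg)[3]
  mkobs <- function(n, offset = 0) {
    reads <- setNames(
      vapply(seq_len(n) - 1 + offset,
             function(o) junction_read(rearranged_sequence(rg), jpos,
                                       left = 20 + o, right = 46 - o), ""),
      sprintf("read%02d_%d", seq_len(n), offset))
    locate_junctions(split_read_at_loxpsym(reads), g, derive_segment_map(g))
  }
  obs5 <- mkobs(5)
  sup5 <- cluster_junctions(obs5, min_support = 5)
  expect_equal(nrow(sup5), 1)
  expect_equal(sup5$support, 5L)
  obs4 <- mkobs(4)
  expect_equal(nrow(cluster_junctions(obs4, min_support = 5)), 0)

  # two distinct junctions mixed: supports equal a dictionary tally
  rg2 <- apply_event(g, scramble_event("deletion", sites[6], sites[7], g$id))
  jpos2 <- loxpsym_starts(rg2)[6]
  reads2 <- setNames(
    vapply(0:6, function(o) junction_read(rearranged_sequence(rg2), jpos2,
                                          left = 18 + o, right = 48 - o), ""),
    sprintf("other%02d", 0:6))
  obs_mix <- rbind(mkobs(6),
                   locate_junctions(split_read_at_loxpsym(reads2), g,
                                    derive_segment_map(g)))
  sup <- cluster_junctions(obs_mix, min_support = 5)
  tally <- sapply(split(obs_mix$read, obs_mix$key), function(r) length(unique(r)))
  expect_equal(sort(sup$support), sort(unname(tally[tally >= 5])))
})

fake_depth <- function(g, ratios) {
  sm <- derive_segment_map(g)
  data.frame(chrom = sm$chrom, segment = sm$segment, start = sm$start,
             end = sm$end, mean_depth = 30 * ratios, median_depth = 30,
             copy_ratio = ratios)
}

test_that("classification follows the orientation/depth rule table", {
  g <- toy()
  sm <- derive_segment_map(g)
  jdel <- data.frame(chrom = g$id, site_a = 2L, side_a = "tail", strand_a = "+",
                     site_b = 4L, side_b = "head", strand_b = "+",
                     support = 8L, key = "d")
  jdup <- data.frame(chrom = g$id, site_a = 2L, side_a = "head", strand_a = "-",
                     site_b = 4L, side_b = "tail", strand_b = "-",
                     support = 9L, key = "u")
  jinv1 <- data.frame(chrom = g$id, site_a = 2L, side_a = "tail", strand_a = "+",
                      site_b = 4L, side_b = "tail", strand_b = "-",
                      support = 6L, key = "i1")
  jinv2 <- data.frame(chrom = g$id, site_a = 2L, side_a = "head", strand_a = "-",
                      site_b = 4L, side_b = "head", strand_b = "+",
                      support = 7L, key = "i2")
  r <- rep(1, 8)

  rdel <- r; rdel[4:5] <- 0.02   # segments 3 and 4 lost
  edel <- classify_events(jdel, fake_depth(g, rdel), sm)
  expect_equal(edel$type, "deletion")
  expect_equal(c(edel$seg_first, edel$seg_last), c(3L, 4L))

  rdup <- r; rdup[4:5] <- 2
  edup <- classify_events(jdup, fake_depth(g, rdup), sm)
  expect_equal(edup$type, "tandem_duplication")

  einv <- classify_events(rbind(jinv1, jinv2), fake_depth(g, r), sm)
  expect_equal(einv$type, "inversion")
  expect_equal(einv$support, 13L)

  # depth contradicting the orientation pattern degrades to complex
  expect_equal(classify_events(jdel, fake_depth(g, r), sm)$type, "complex")
  expect_equal(classify_events(jdup, fake_depth(g, r), sm)$type, "complex")
  rbad <- r; rbad[4:5] <- 2
  expect_equal(classify_events(rbind(jinv1, jinv2), fake_depth(g, rbad), sm)$type,
               "complex")
  # unpaired inversion-type junction is complex
  expect_equal(classify_events(jinv1, fake_depth(g, r), sm)$type, "complex")
  # missing depth is complex with a note
  nd <- fake_depth(g, r); nd$copy_ratio <- NA_real_
  out <- classify_events(jdel, nd, sm)
  expect_equal(out$type, "complex")
  expect_match(out$notes, "depth missing")
})

test_that("gene annotations are attached to implicated segments", {
  genes <- data.frame(name = "LSB3", start = 2600L, end = 3100L, strand = "+")
  g <- build_toy_genome(rep(800, 8), genes = genes, seed = 45)  # in segment 3
  sm <- derive_segment_map(g)
  jdel <- data.frame(chrom = g$id, site_a = 2L, side_a = "tail", strand_a = "+",
                     site_b = 4L, side_b = "head", strand_b = "+",
                     support = 8L, key = "d")
  r <- rep(1, 8); r[4:5] <- 0
  out <- classify_events(jdel, fake_depth(g, r), sm, genes = genes)
  expect_match(out$notes, "LSB3")
})

test_that("calling is invariant to mate swap and read order", {
  g <- build_toy_genome(rep(1500, 8), seed = 46)
  sites <- g$loxpsym_starts
  rg <- apply_event(g, scramble_event("inversion", sites[3], sites[6], g$id))
  pairs <- simulate_read_pairs(rg, coverage = 30, error_rate = 0.001, seed = 47)
  base <- call_events(pairs, g)$events

  swapped <- pairs
  swapped[, c("seq1", "qual1", "seq2", "qual2")] <-
    pairs[, c("seq2", "qual2", "seq1", "qual1")]
  swapped[, c("start1", "strand1", "start2", "strand2")] <-
    pairs[, c("start2", "strand2", "start1", "strand1")]
  expect_equal(call_events(swapped, g)$events, base)

  set.seed(48)
  shuffled <- pairs[sample(nrow(pairs)), ]
  expect_equal(call_events(shuffled, g)$events, base)
})
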