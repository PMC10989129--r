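# Chromosome model and Cre event mechanics.

test_that("toy genome construction obeys the segment/site arithmetic", {
  g1 <- build_toy_genome(500, seed = 1)
  expect_equal(nchar(g1$sequence), 500)
  expect_length(g1$loxpsym_starts, 0)

  g3 <- build_toy_genome(c(100, 200, 300), seed = 2)
  expect_equal(nchar(g3$sequence), 668)  # 600 + 2 * 34
  expect_equal(g3$loxpsym_starts, c(100L, 334L))
  expect_equal(substr(g3$sequence, 101, 134), loxpsym_sequence())

  again <- build_toy_genome(c(100, 200, 300), seed = 2)
  expect_identical(g3$sequence, again$sequence)

  expect_error(build_toy_genome(c(100, 0)), "positive")
  expect_error(build_toy_genome(100, loxpsym = "ACGTX"), "DNA")
  expect_warning(build_toy_genome(c(50, 50), loxpsym = "ACGTAAGG"),
                 "palindrome")
})

test_that("the canonical loxPsym site is a perfect palindrome", {
  expect_true(is_palindromic_site(loxpsym_sequence()))
  expect_equal(nchar(loxpsym_sequence()), 34)
})

test_that("segment maps tile the chromosome outside the sites", {
  g3 <- build_toy_genome(c(100, 200, 300), seed = 2)
  sm <- derive_segment_map(g3)
  expect_equal(sm$start, c(0L, 134L, 368L))
  expect_equal(sm$end, c(100L, 334L, 668L))
  expect_equal(sm$segment, 0:2)

  g1 <- build_toy_genome(500, seed = 1)
  sm1 <- derive_segment_map(g1)
  expect_equal(nrow(sm1), 1)
  expect_equal(c(sm1$start, sm1$end), c(0L, 500L))

  g10 <- build_toy_genome(sample(80:300, 10), seed = 3)
  sm10 <- derive_segment_map(g10)
  expect_equal(sum(sm10$end - sm10$start) + 9 * 34, nchar(g10$sequence))
})

test_that("apply_event implements the Cre model exactly on the 668 bp toy", {
  g <- build_toy_genome(c(100, 200, 300), seed = 2)
  ev <- function(type) scramble_event(type, 100, 334, g$id)

  del <- apply_event(g, ev("deletion"))
  del_seq <- rearranged_sequence(del)
  expect_equal(nchar(del_seq), 434)  # 668 - 234
  expect_equal(loxpsym_starts(del), 100L)
  expect_equal(del_seq,
               paste0(substr(g$sequence, 1, 100), loxpsym_sequence(),
                      substr(g$sequence, 369, 668)))

  inv <- apply_event(g, ev("inversion"))
  inv_seq <- rearranged_sequence(inv)
  expect_equal(nchar(inv_seq), 668)
  expect_equal(provenance(inv)$orientation, c("+", "-", "+"))
  expect_equal(inv_seq,
               paste0(substr(g$sequence, 1, 134),
                      revcomp(substr(g$sequence, 135, 334)),
                      substr(g$sequence, 335, 668)))

  dup <- apply_event(g, ev("tandem_duplication"))
  expect_equal(nchar(rearranged_sequence(dup)), 902)  # 668 + 234
  expect_equal(sum(provenance(dup)$segment == 1), 2)
  expect_equal(max(provenance(dup)$copy), 2)

  expect_error(apply_event(g, scramble_event("deletion", 99, 334)),
               "not a loxPsym start")
  expect_error(scramble_event("deletion", 334, 100), "strictly less")
  expect_error(scramble_event("translocation", 1, 2))
})

test_that("length and site-count accounting is exact for random events", {
  set.seed(11)
  types <- c("deletion", "inversion", "tandem_duplication")
  for (i in 1:200) {
    g <- build_toy_genome(sample(60:200, sample(4:9, 1)))
    sites <- g$loxpsym_starts
    pair <- sort(sample(sites, 2))
    type <- sample(types, 1)
    rg <- apply_event(g, scramble_event(type, pair[1], pair[2], g$id))
    d <- pair[2] - pair[1]
    delta <- nchar(rearranged_sequence(rg)) - nchar(g$sequence)
    expect_equal(delta, switch(type, deletion = -d, inversion = 0,
                               tandem_duplication = d))
    in_interval <- sum(sites >= pair[1] & sites < pair[2])
    inside <- sum(sites > pair[1] & sites < pair[2])
    n_after <- length(loxpsym_starts(rg))
    expect_equal(n_after - length(sites),
                 switch(type, deletion = -in_interval, inversion = 0L,
                        tandem_duplication = inside + 1L))
    # every annotated site occurrence is the configured palindromic site
    seq_after <- rearranged_sequence(rg)
    occ <- substring(seq_after, loxpsym_starts(rg) + 1, loxpsym_starts(rg) + 34)
    expect_true(all(occ == loxpsym_sequence()))
  }
})

test_that("provenance blocks rebuild the emitted sequence byte-for-byte", {
  set.seed(12)
  for (i in 1:20) {
    g <- build_toy_genome(sample(60:200, 12))
    rg <- random_scramble(g, n_events = 3, seed = i,
                          type_probabilities = c(deletion = 0.2,
                                                 inversion = 0.5,
                                                 tandem_duplication = 0.3))
    # independent reconstruction from the parental segment map
    sm <- derive_segment_map(g)
    blocks <- provenance(rg)
    pieces <- substring(g$sequence, sm$start[blocks$segment + 1] + 1,
                        sm$end[blocks$segment + 1])
    pieces[blocks$orientation == "-"] <- revcomp(pieces[blocks$orientation == "-"])
    expect_identical(paste(pieces, collapse = loxpsym_sequence()),
                     rearranged_sequence(rg))
  }
})

test_that("random_scramble is reproducible, honors n_events = 0, and errors without sites", {
  g <- build_toy_genome(rep(100, 6), seed = 5)
  id0 <- random_scramble(g, 0, seed = 1)
  expect_identical(rearranged_sequence(id0), g$sequence)
  expect_equal(nrow(truth_events(id0)), 0)

  a <- random_scramble(g, 5, seed = 42)
  b <- random_scramble(g, 5, seed = 42)
  expect_identical(truth_events(a), truth_events(b))
  expect_identical(rearranged_sequence(a), rearranged_sequence(b))

  g1 <- build_toy_genome(c(100, 100), seed = 6)  # one site only
  expect_error(random_scramble(g1, 1, seed = 1), "2 loxPsym sites")
  expect_error(random_scramble(g, 3, type_probabilities = c(deletion = 1)),
               "sum to 1")
})

test_that("event-type draws follow the configured probabilities", {
  g <- build_toy_genome(rep(60, 6), seed = 7)
  probs <- c(deletion = 0.5, inversion = 0.3, tandem_duplication = 0.2)
  set.seed(1000)
  types <- vapply(1:1000, function(i) {
    truth_events(random_scramble(g, 1, type_probabilities = probs))$type
  }, "")
  counts <- table(factor(types, names(probs)))
  for (t in names(probs)) {
    se <- sqrt(probs[[t]] * (1 - probs[[t]]) / 1000)
    expect_lt(abs(counts[[t]] / 1000 - probs[[t]]), 3 * se)
  }
})

test_that("multi-chromosome genomes confine events to one molecule", {
  g1 <- build_toy_genome(rep(100, 5), id = "chrA", seed = 8)
  g2 <- build_toy_genome(rep(100, 5), id = "chrB", seed = 9)
  out <- random_scramble(list(g1, g2), 6, seed = 3)
  expect_length(out, 2)
  tr <- truth_events(out)
  expect_equal(nrow(tr), 6)
  expect_true(all(tr$chrom %in% c("chrA", "chrB")))
})

test_that("genome and annotation writers emit standard formats", {
  genes <- data.frame(name = "YFG1", start = 10L, end = 60L, strand = "+")
  g <- build_toy_genome(c(100, 100), genes = genes, seed = 10)
  fa <- tempfile(fileext = ".fa"); bed <- tempfile(fileext = ".bed")
  write_genome_fasta(g, fa)
  back <- Biostrings::readDNAStringSet(fa)
  expect_equal(as.character(back[[1]]), g$sequence)
  write_sites_bed(g, bed)
  lines <- read.table(bed, sep = "\t")
  expect_equal(nrow(lines), 2)  # 1 site + 1 gene
  expect_equal(lines$V2[1], 100)
  expect_error(build_toy_genome(c(100, 100),
                                genes = data.frame(name = "x", start = -1L,
                                                   end = 5L, strand = "+")),
               "bounds")
})
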