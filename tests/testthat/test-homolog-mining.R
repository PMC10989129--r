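# Homolog-mining filters, ORF extraction, chimera and RR truncation.

test_that("hit filtering applies strict thresholds and the family whitelist", {
  mk <- function(bit, id, len, fam = "Apocynaceae") {
    data.frame(bit_score = bit, percent_identity = id, alignment_length = len,
               family = fam, stringsAsFactors = FALSE)
  }
  expect_equal(nrow(filter_homolog_hits(mk(1200, 80, 1100))), 1)
  # exact thresholds fail on every axis (strict inequalities)
  expect_equal(nrow(filter_homolog_hits(mk(1000, 80, 1100))), 0)
  expect_equal(nrow(filter_homolog_hits(mk(1200, 75, 1100))), 0)
  expect_equal(nrow(filter_homolog_hits(mk(1200, 80, 1000))), 0)
  expect_equal(nrow(filter_homolog_hits(mk(1001, 76, 1001))), 1)
  # taxonomy: case-insensitive whitelist; empty whitelist disables it
  expect_equal(nrow(filter_homolog_hits(mk(1200, 80, 1100, "RUBIACEAE"))), 1)
  expect_equal(nrow(filter_homolog_hits(mk(1200, 80, 1100, "Poaceae"))), 0)
  expect_equal(nrow(filter_homolog_hits(mk(1200, 80, 1100, "Poaceae"),
                                        family_whitelist = character(0))), 1)
  # empty table and malformed input
  expect_equal(nrow(filter_homolog_hits(mk(1, 1, 1)[0, ])), 0)
  expect_error(filter_homolog_hits(data.frame(bit_score = 1)), "missing required")
  expect_error(filter_homolog_hits(mk(1200, 140, 1100)), "\\[0, 100\\]")
})

test_that("filtering equals a row-by-row re-check on a random table and is idempotent", {
  hits <- simulate_homolog_hits(500, seed = 61)
  out <- filter_homolog_hits(hits)
  manual <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    manual[i] <- hits$bit_score[i] > 1000 && hits$percent_identity[i] > 75 &&
      hits$alignment_length[i] > 1000 &&
      tolower(hits$family[i]) %in% tolower(mia_families())
  }
  expected <- hits[manual, ]; rownames(expected) <- NULL
  expect_equal(out, expected)
  expect_equal(filter_homolog_hits(out), out)       # idempotent
  expect_true(all(out$subject %in% hits$subject))   # subset, order preserved
  expect_identical(out$subject, hits$subject[manual])
})

test_that("hit tables round-trip through the tabular dialect", {
  hits <- simulate_homolog_hits(20, seed = 62)
  f <- tempfile(fileext = ".tsv")
  write_homolog_hits(hits, f)
  back <- read_homolog_hits(f)
  expect_equal(back$bit_score, hits$bit_score)
  expect_equal(back$subject_seq, hits$subject_seq)
  expect_equal(back$family, hits$family)
})

test_that("longest_orf handles canonical and degenerate cases", {
  o <- longest_orf("ATGAAATAG")
  expect_equal(o$protein, "MK")
  expect_equal(o$frame, 1)
  expect_equal(c(o$start, o$end), c(0L, 9L))
  expect_equal(o$strand, "+")

  expect_null(longest_orf("CCCCCCCCCCCC"))            # no ATG
  expect_null(longest_orf("ATGAAAAAAAAA"))            # no stop
  expect_null(longest_orf("ATNGAATAG", search_both_strands = FALSE))  # N blocks start
  expect_error(longest_orf("ATGXXXTAG"), "DNA")

  # N inside the body translates to X
  o2 <- longest_orf("ATGAANAAATAG", search_both_strands = FALSE)
  expect_equal(o2$protein, "MXK")

  # reverse-strand ORF reported on input coordinates
  s <- revcomp("ATGAAACCCTAA")
  o3 <- longest_orf(s)
  expect_equal(o3$strand, "-")
  expect_equal(o3$protein, "MKP")
  expect_equal(revcomp(substr(s, o3$start + 1, o3$end)), "ATGAAACCCTAA")
})

test_that("longest_orf equals exhaustive enumeration on random sequences", {
  set.seed(63)
  for (i in 1:30) {
    s <- random_dna(2000)
    mine <- longest_orf(s)
    oracle <- brute_force_orf(s)
    if (is.null(oracle)) {
      expect_null(mine)
    } else {
      expect_equal(mine$strand, oracle$strand)
      expect_equal(mine$start, oracle$start)
      expect_equal(mine$end, oracle$end)
      expect_equal(mine$protein, oracle$protein)
    }
  }
})

test_that("reported ORF is invariant under reverse-complementing the input", {
  set.seed(64)
  for (i in 1:10) {
    s <- random_dna(1500)
    a <- longest_orf(s)
    b <- longest_orf(revcomp(s))
    expect_equal(is.null(a), is.null(b))
    if (!is.null(a)) {
      expect_equal(a$protein, b$protein)
      expect_equal(a$length, b$length)
    }
  }
})

test_that("N-terminal chimera swapping matches the 1-29 aa exchange design", {
  set.seed(65)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  cr <- paste(c("M", sample(aa, 492, TRUE)), collapse = "")   # CrG8H-like length
  te <- paste(c("M", sample(aa, 498, TRUE)), collapse = "")
  ce_cr <- make_chimera(te, cr, 29)   # TeG8H N-terminus on the CrG8H body
  expect_equal(nchar(ce_cr), nchar(cr))
  expect_equal(substr(ce_cr, 1, 29), substr(te, 1, 29))
  expect_equal(substr(ce_cr, 30, nchar(cr)), substr(cr, 30, nchar(cr)))

  expect_identical(make_chimera(te, cr, 0), cr)
  # swapping back over the prefix recovers the original acceptor
  expect_identical(make_chimera(cr, make_chimera(te, cr, 29), 29), cr)
  expect_error(make_chimera("MAB", cr, 10), "smaller than")
  # no new residues appear
  expect_true(all(strsplit(ce_cr, "")[[1]] %in%
                  c(strsplit(cr, "")[[1]], strsplit(te, "")[[1]])))
})

test_that("RR truncation removes residues 2..(RR-1) and keeps the start Met", {
  expect_equal(truncate_at_rr("MABCRRDEF"), "MRRDEF")
  expect_equal(truncate_at_rr("MRRXYZ"), "MRRXYZ")  # motif at residue 2
  # RR motif first appears at residue 88: residues 2-87 are removed
  set.seed(66)
  aa_no_r <- setdiff(strsplit("ACDEFGHIKLMNPQSTVWY", "")[[1]], "R")
  prot <- paste(c("M", sample(aa_no_r, 86, TRUE), "RR",
                  sample(aa_no_r, 400, TRUE)), collapse = "")
  tr <- truncate_at_rr(prot)
  expect_equal(substr(tr, 1, 3), "MRR")
  expect_equal(nchar(tr), nchar(prot) - 86)  # residues 2..87 removed
  expect_equal(substr(tr, 2, nchar(tr)), substr(prot, 88, nchar(prot)))

  expect_error(truncate_at_rr("MABCDEF"), "no RR")
  expect_error(truncate_at_rr("ABCRRD"), "methionine")
})
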