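---
title: "Detecting SCRaMbLE rearrangements from split reads, and the companion screening statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting SCRaMbLE rearrangements from split reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scramblesv)
```

## The problem

Sc2.0 synthetic yeast chromosomes carry a 34-bp palindromic loxPsym site
downstream of every nonessential gene. Inducing Cre recombinase (SCRaMbLE)
recombines random pairs of these sites, producing deletions, inversions and
tandem duplications of the *segments* between sites — an in-vivo generator of
genome diversity that can be screened for improved metabolite production
(here: geraniol, en route to 8-hydroxygeraniol and monoterpenoid indole
alkaloids). Identifying *which* rearrangement a high-yield strain carries
requires whole-genome sequencing and a breakpoint caller that understands the
loxPsym geometry. This package implements that caller together with
everything needed to validate it end to end on synthetic data, plus the
screening and enzyme-mining statistics used around it:

1. a chromosome/segment model and an exact Cre event simulator,
2. a PE100 paired-end read simulator with a Phred-faithful substitution
   error model,
3. the QC rule (mean Phred < 10 or any N removes the pair),
4. an ungapped seed-and-extend read mapper with per-segment depth profiling,
5. the loxPsym split-read junction caller with orientation/depth event
   typing,
6. homolog-mining filters, longest-ORF extraction, N-terminal chimera and
   RR-motif truncation,
7. p-distance neighbor-joining phylogeny,
8. OD340 microplate screening statistics (calibration, 1.5-fold hit calling,
   specific activity).

## The Cre model

A molecule is represented as an alternating sequence of oriented segment
blocks and single loxPsym sites. Events act between two site *start*
coordinates `a < b` of the current molecule:

* **deletion** removes `[a, b)` and retains exactly one loxPsym at the
  junction (length change `-(b - a)`);
* **inversion** reverse-complements the interval between the sites and keeps
  both (length unchanged — the palindromic site is its own reverse
  complement, so interior sites survive intact);
* **tandem duplication** inserts a second copy of `[a, b)` at `b` (length
  change `+(b - a)`).

Because the representation never concatenates two sites or drops a junction
site, the block list *is* the provenance record: re-assembling the blocks
with single-site separators reconstructs the emitted sequence byte for byte,
and the site-count bookkeeping (deletion: minus the sites inside `[a, b)`;
duplication: plus the interior sites plus one) is exact. These are tested as
invariants over thousands of random events.

`random_scramble()` draws site pairs uniformly and event types from a
configurable distribution, default (deletion 0.5, inversion 0.3, tandem
duplication 0.2). Event-type rates are not something the simulator can
learn from data; the default leans on deletions, the outcome SCRaMbLE
experiments typically recover most often, and is a fixed package choice
rather than a fitted quantity. Only intramolecular
events are simulated — interchromosomal translocations are rare enough in
practice to be left out of scope — and composite outcomes ("duplication &
deletion") arise as sequences of primitives, not as a fourth primitive.

## Junction geometry and event typing

Reads that span a novel junction fail contiguous mapping because at least 15
bp on one side belong elsewhere (at the mapper's allowance of 4 mismatches
per 100 bp, a foreign 15-bp flank is essentially never absorbed). Each
unmapped read is scanned for a loxPsym occurrence (≤ 2 mismatches inside the
site; both orientations coincide because the site is palindromic). If both
flanks reach **15 bp**, the read is split and each flank is placed on the
reference; flank ends are snapped to segment boundaries within 2 bp. A
junction is the canonical pair of boundary attachments
`(site index, head|tail, strand)`; reading the same junction from the other
strand flips both strands and swaps the sides, and the caller keys on the
lexicographically smaller representation, which makes it invariant to mate
swapping and input order. Junctions supported by at least **5** distinct
reads survive clustering (the support rule is read as ≥ 5; the alternative
"> 5" is configurable).

Typing combines the orientation pattern with depth evidence from uniquely
mapped reads (per-segment mean depth normalized by the chromosome's median
segment depth):

| pattern (canonical)                   | depth of spanned segments | call |
|---------------------------------------|---------------------------|------|
| `tail(+) → head(+)`, `a < b`          | < 0.25                    | deletion |
| `head(−) → tail(−)`, `a < b`          | ≥ 1.6                     | tandem duplication |
| `tail(+) → tail(−)` paired with `head(−) → head(+)`, same `(a, b)` | within [0.75, 1.25] | inversion |
| anything else, or depth out of range  | —                         | complex (evidence attached) |

The three depth thresholds are package choices — orientation alone cannot
separate a clean deletion from a composite that restores copy number, so
depth bands complete the rule table; all are exposed in the configuration, and every call reports its mean copy ratio so composite
events typed `complex` remain interpretable.

## The mapper and why it is exact

The mapper is deliberately ungapped: every SCRaMbLE junction co-occurs with
a full loxPsym, so the signal lives in split reads, not gapped alignments.
Placements are found by exact k-mer seeding and verified by Hamming
counting over both strands. The requested seed length (default `k = 21`) is
capped at `floor(read_length / (max_mismatch + 1))`: by the pigeonhole
principle a placement with at most `max_mismatch` mismatches must contain
one exact seed chunk, so the seeded search finds *every* placement within
the allowance and is provably identical to a brute-force scan of all
positions — which the test suite verifies against an independently coded
full Hamming profile on dozens of random genomes. Ties are reported as
`multi` (never an arbitrary placement), so the repeated loxPsym sequence
cannot fake unique evidence; only `unique` alignments contribute to depth.

## Read simulation and QC

Pair count is `ceiling(coverage × L / (2 × read_length))`; insert sizes are
Normal(350, 35) truncated to `[2 × read_length, mean + 4 sd]`
(conventional short-insert library values); fragment starts are uniform with no GC bias. The run-constant Phred
value is derived from the requested error rate and substitutions are
injected at exactly the rate the emitted Phred implies, so the QC filter
sees honest qualities. Contamination switches (`low_quality_fraction`,
`n_base_fraction`) exist purely to exercise the filter. The QC rule removes
a pair when either mate has mean Phred below 10 or contains an N;
"Phred-score < 10" is interpreted as the *mean* per mate, with `min` and
`fraction_below` summaries available because preprocessing tools differ in
how they summarize per-read quality.

## Desk-scale validation conditions

The simulations used by the tests and the acceptance script run on a toy
chromosome of 11 segments (1.5–2.4 kb each, ~20.8 kb total) with 10 loxPsym
sites, sequenced at 30× PE100 with 0.1% substitution error. At these
conditions a junction is covered by ~11 split-informative reads in
expectation (37 eligible read starts × 0.3 reads/bp), so the support-5 rule
passes with a modest margin; this is the package's chosen validation scale,
small enough that the full recovery grid (3 types × spans 1–3 × 10 seeds,
plus event-free controls) runs in minutes. The read simulator itself
defaults to a production sequencing design (PE100 at 85×). What passing these
tests shows is that the caller's geometry, thresholds and bookkeeping are
correct on data matching its model (uniform coverage, substitution-only
errors, isolated events); it does not certify behavior on real libraries
with coverage bias, indels, adapter artifacts, or overlapping nested events.

## Mining, phylogeny and screening statistics

**Homolog filtering** is a pure row predicate with strict inequalities — a
hit passes only with bit score > 1000, identity > 75%, alignment length
> 1000 and (by default) a family among the MIA-producing Apocynaceae,
Rubiaceae, Gentianaceae and Loganiaceae (case-insensitive; an empty
whitelist disables the taxonomy test). The similarity search itself is out
of scope: the module consumes a standard 12-column tabular hit file plus
subject sequence and family columns.

**`longest_orf()`** scans all six frames for complete ATG→stop spans (an
explicit in-sequence stop is required — the "protein-encoding" check), with
codons containing N translating to X and never acting as start or stop.
Length ties are broken by the lexicographically smallest translated protein,
then forward strand, then smallest start; protein-first tie-breaking is what
makes the reported ORF invariant under reverse-complementing the input,
which the suite asserts. Reverse-strand coordinates are reported on the
input sequence.

**`make_chimera()`** swaps an N-terminal prefix (default 29 residues, the
span used to dissect the G8H membrane anchor): `donor[1..n] +
acceptor[n+1..end]`, so chimera length always equals acceptor length and
applying the swap back is an involution. **`truncate_at_rr()`** removes
residues `2..(p−1)` up to the first RR dipeptide while keeping the start
methionine — the standard plastid-targeting-sequence truncation for
cytosolic expression of plant terpene synthases (e.g. removing residues
2–87 when the motif begins at 88).

**Phylogeny**: p-distances use pairwise deletion of gapped columns (a
Poisson correction is available); p-distance with pairwise deletion, the
common default across standard phylogeny software, is the package default. The
NJ implementation is the classical Saitou–Nei agglomeration with
deterministic lexicographic tie-breaking and no bootstrap resampling; on
additive matrices it provably recovers the generating topology
and path lengths, which the suite checks to 1e-9 against trees the matrices
were built from, with an independent NJ implementation as a cross-check on
noisy matrices. Negative branch lengths, a known NJ artifact, are reported
as computed.

**Screening**: the GeDH assay couples geraniol oxidation 1:1 to NAD⁺→NADH,
read as OD340 gain. The plate generator follows the assay protocol in
reading each well three times and recording the replicate mean (raw
per-reading noise 0.002 OD, a typical plate-reader repeatability), which is
what makes a 1.5-fold discrimination reliable at the starting strain's
small signal. Signals are endpoint differences over the 30-min run
(a max-slope option exists for saturating kinetics); calibration is an OLS
line of ΔOD340 against 0–8 mg/l standards that refuses extrapolation outside
the standards' span; hits are wells at ≥ 1.5 × the mean reference ΔOD340
(the boundary is deliberately inclusive — "1.5-fold increase" is read as
≥ 1.5), making hit calling invariant to rescaling the optics. Broth
concentrations apply the ×2 factor from the 1:1 broth:buffer assay mix.
Specific activity uses Beer–Lambert with the standard NADH extinction
coefficient 6220 M⁻¹cm⁻¹ (configurable; the value is a textbook constant,
a textbook constant):
`U/mg = slope / (ε × path) × volume × 10⁶ / mass`.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere; site index `j` separates
  segment `j` from segment `j + 1`.
* Fragment alignment allowance scales with flank length
  (`min(2, floor(len / 25))`); fragments that map non-uniquely, cross
  chromosomes, or fail boundary snapping are dropped and counted in the
  diagnostics rather than guessed at.
* A configured site that is not a reverse-complement palindrome triggers a
  warning (orientation-independent recombination then fails to hold).
* `error_rate = 0` emits Phred 40 with exactly zero substitutions (the
  Phred-faithfulness contract applies to positive rates).
* Depth ratios are `NA` (and calls degrade to `complex` with a note) when a
  chromosome's median segment depth is zero.
* The `pipeline_config()` document rejects unknown keys, and
  `run_end_to_end()` derives all per-stage seeds from one integer, so a run
  is reproducible from a single value.

## Known limitations

* Interchromosomal translocations, circular intermediates and nested or
  overlapping events are out of scope; overlapping junction evidence types
  as `complex` rather than being phased.
* The error model is substitution-only (no indels, optical duplicates or
  adapter read-through), and coverage is uniform.
* The mapper is ungapped by design and unsuitable as a general-purpose
  aligner.
* The phylogeny stage validates on simulated alignments with known
  generating trees; regenerating any particular published family tree would
  require its sequences and alignment settings.
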