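---
title: "Detecting sIR-mediated plastome inversion heteroplasmy from short reads"
author: "sirhet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sIR-mediated plastome inversion heteroplasmy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirhet)
```

## The problem

Chloroplast genomes (plastomes) are circular molecules whose structure is
more dynamic than their conserved gene content suggests. Beyond the
well-known "flip-flop" recombination between the two canonical large
inverted repeats, a *short* inverted-repeat (sIR) pair — two copies of a
sequence of a few tens of base pairs, present in opposite orientations and
separated by tens of kilobases — can serve as a substrate for intramolecular
homologous recombination. Recombination between the two arms inverts the
entire spanned segment, producing an alternative structural isoform. Within
a single plant both configurations can coexist (structural heteroplasmy),
usually with one form strongly predominating.

`sirhet` detects this situation directly from ordinary paired-end short-read
data. The study system it is built around is a ~160 kb plastome carrying a
53 bp sIR pair whose arms bound a ~22 kb region: the minor inverted isoform
is present at frequencies from below 1% up to a few percent, far too rare to
affect a consensus assembly, but clearly visible in the geometry of
individual read pairs.

## The method

The pipeline has four stages.

**1. sIR discovery.** The genome is compared against its own reverse
complement with exact k-mer seeding (k = 12). Seeded diagonals are extended
to maximal exact-match runs, and nearby runs are merged — across
substitution gaps on the same diagonal, and across small diagonal shifts for
indels — as long as the merged arm pair keeps an identity at or above the
floor (`min_identity`, default 0.8). A reported arm therefore always begins
and ends on exact matches; this is the convention we adopt for "maximal
extension", and it guarantees that a perfect planted pair is reported at
exactly its planted coordinates rather than with a few chance-complementary
flanking bases attached. Identity is defined as matches over alignment
columns of an end-free global alignment (match +1, mismatch −1, gap −2);
a pair is a *complete* match iff both arms have equal length and identity 1.
Default arm-length bounds (30–1000 bp) and span bounds (5–60 kb) capture the
53 bp / 22 kb case while excluding the canonical large IRs and trivial
microrepeats; all are exposed as arguments and on the command line.

**2. Hairpin prediction.** Each arm's capacity to fold back on itself is
assessed with a combinatorial stem-loop model: among all antiparallel stems
of strict Watson–Crick pairs (no G·T wobble — this is DNA — and no bulges)
with a loop of at least 3 nt, the maximal stem wins; ties prefer the smaller
loop, then the leftmost 5′ start. This is deliberately not a thermodynamic
model: free-energy folding is out of scope, and the structure of interest
(a 7 bp stem with an 8 nt loop in the conserved 22 bp arm motif) is
recoverable combinatorially. On an arm of length n the search is O(n²) with
run-length sharing along antidiagonals, instant at realistic arm sizes.

**3. Isoform construction.** The inverted-type reference replaces the
substring from arm1 start to arm2 end with its reverse complement. For a
complete-match pair the arm sequences at both boundaries are unchanged, and
the construction is an involution. Including both arms in the inverted
segment is a convention: for complete pairs it is provably equivalent to
inverting only the spacer, and for incomplete pairs it corresponds to a
crossover at the arm midpoint — the true crossover point inside the repeat
is not resolvable from short reads, so one deterministic convention is
required and this is ours. The coordinate map between the references is the
identity outside the segment and an order-reversing reflection inside it.
Spanned regions that cross the origin of the circle are refused; a
pre-rotation utility (`rotate_clear()`) re-linearises the genome first.
Coordinates are 0-based half-open internally and 1-based inclusive in every
user-facing report.

**4. Read-pair classification and frequency.** Against the normal reference,
a candidate pair must either (a) be discordant in orientation with an outer
mate span within `span_tolerance_bp` (default 1000) of the spanned-region
width — the expected "insert" of an inversion-supporting pair is the ~22 kb
region itself — or (b) carry a soft clip of at least `min_clip_bp` (default
20) whose junction falls within an arm (±30 bp of slop for chance-match
extension past the junction). Clip fragments are remapped to the window
(`vicinity_bp`, default 1000) around the *opposite* arm and accepted at
identity ≥ 0.9 over at least 90% of the clip. Fully aligned candidates must
additionally satisfy the arm-overlap rule: a mate intersecting an arm, or
one mate wholly inside the region with the other wholly outside but within
`vicinity_bp` of an arm. Every candidate must finally align to the
inverted-type reference as a proper FR pair with a mate span strictly below
`inverted_max_span_bp` (500 bp, a strict bound). Pairs with 1–3
mismatches+indels are kept and flagged `minor_variant`; noisier pairs are
excluded with a logged reason, never silently dropped.

Supporting pairs are assigned Patterns I–VIII. The pictorial definitions in
the source material do not pin Roman numerals to geometries, so we fix an
operational taxonomy consistent with all textual constraints: fully aligned
pairs give I (arm1 overlap, mate outside the region), II (arm2, mate
outside), III (arm1, mate not outside), IV (arm2, mate not outside) and V
(no arm overlap, interior/exterior geometry); soft-clipped pairs give VI
(clip at arm1, mate outside), VII (clip at arm2, mate outside) and VIII
(clip at an arm, mate inside). Labels may permute I–IV/VI–VII relative to
the original figures; counts remain comparable because the taxonomy is
recorded with the output.

The frequency estimate is

> frequency (%) = 100 × supporting pairs / mean depth over the spanned region,

with one read *pair* as the unit of support (the published tables count
discordant paired-end reads as units, and their totals and percentages are
mutually consistent under this reading, e.g. 35 pairs at mean depth 507.25
give 6.90%). Mean depth follows the common depth-utility default: primary,
non-duplicate, non-QC-fail alignments; soft-clipped bases contribute
nothing; no MAPQ or base-quality threshold. Note the estimator is a *support
statistic*, not an unbiased estimator of the molecular fraction f: only
fragments whose sequenced geometry reveals the inversion (roughly, fragments
covering a breakpoint, ~2·insert/genome of all fragments from the minor
isoform) can support it, so the ratio frequency/f is a constant of
proportionality determined by the fragment geometry. The package's tests
measure that constant with the simulator's truth oracle and verify the
estimate is monotone in f and proportionally stable.

## Alignment layer

External SAM (any aligner, e.g. BWA-MEM with split alignments marked
secondary) is the production path; the package parses the minimal SAM text
dialect (mandatory 11 columns, `@SQ` header, `NM` tag) and never requires
BAM. For a self-contained desk run it also ships a small seed-and-extend
mapper: exact 21-mers sampled every 7 bases along the read (plus the final
offset) against a hash of the doubled reference (doubling handles
circularity; positions are reported modulo length), then ungapped
verification. The maximal-scoring contiguous window (match +1, mismatch −3)
becomes the M segment; the remainder becomes soft clips, which is exactly
the behaviour needed at an inversion breakpoint. Among equal-scoring
placements the lowest reference offset wins, then forward strand —
determinism matters more than cleverness here. The internal mapper does not
do gapped alignment: the simulator's error model is substitution-only and
indel-containing real data should arrive as external SAM. One behaviour
worth knowing: a read crossing a breakpoint aligns *through* the arm (the
arm is the same sequence in both isoforms), so its clip junction sits at an
arm boundary and the clip length is the overhang beyond the arm — reads
poking fewer than `min_clip_bp` bases past an arm are genuinely
undetectable by the clip path, and the candidate rules treat them
accordingly.

## The simulator and what passing tests mean

`sim_config()` defaults encode the study conditions: 160 kb circular genome
at 38% GC, a 53 bp arm pair spanning 22 kb — precisely, 22 000 bp from
arm1 start to arm2 end — 150 bp paired reads with insert 400 ± 50 bp
(truncated at 300), depths in the hundreds (the study's per-sample depths
range from ~170× to ~1200×; we default to 500× and use 300× in the heavier
multi-run tests to keep runtimes reasonable), and an inverted-isoform
fraction f between 0 and 10%. Background sequence is i.i.d.; a rejection
step redraws any genome in which a second exact inverted repeat of ≥ 30 bp
arises by chance, and the four bases flanking the planted pair are resampled
so the planted match is maximal. One RNG stream is consumed in a fixed
documented order (background, arm, placement, fragment starts, inserts,
origin uniforms, errors), so runs are byte-reproducible and — because the
origin uniforms sit at a fixed stream position — fragment origins are
monotonically coupled across f at a common seed. Optional arm mutations
(substitutions/deletions) exercise the incomplete-match and minor-variant
code paths. Qualities are constant Q40 placeholders; the pipeline never
reads them.

The truth oracle (`truth_supporting_set()`) recomputes, from fragment
coordinates and the coordinate map alone — never from alignments — which
inverted-origin fragments must satisfy the detection criteria, including
the deterministic scoring-window behaviour at a breakpoint. On error-free
mixtures the detector is required to reproduce this set *exactly* (no false
positives, no false negatives), and at f = 0 with 0.5% substitution errors
it is required to report nothing at all across 20 seeds. What this does and
does not show: the simulator has no indel errors, no coverage bias, no PCR
duplicates, no repeat landscape beyond the planted pair, and no
quality-score structure, so passing these tests demonstrates correctness of
the geometric criteria and their implementation, not robustness to every
artefact of real libraries. On real data the external-aligner path, the
minor-variant tolerance (≤ 3 edit operations) and the strict
inverted-reference check carry that burden.

## Numerical and degenerate-input choices

* Identity scoring (+1/−1/−2, end-free) is fixed and documented because the
  source material never defines identity for an "incomplete" pair.
* The identity floor 0.8 separating a degraded arm from "absent" is our
  choice, stated as such.
* Zero evidence at zero depth reports 0% with a warning rather than NaN.
* Nonzero evidence at zero depth is an error (it cannot arise from a
  consistent alignment set).
* Empty regions, wrapping regions where forbidden, malformed SAM records
  and non-nucleotide characters fail fast with specific messages.
* All randomness flows from explicit integer seeds; nothing derives from
  the wall clock.

## Problem sizes used by the test-suite

Unit tests run on 10–64 kb genomes in seconds. The oracle-equivalence and
specificity checks run the full study geometry (160 kb, 53 bp arms, 22 kb
span) at 300× over 30 seeded runs, and the monotonicity check at 500× over
30 more (6 seeds × 5 values of f, common seeds across f); these sizes keep
the whole suite in the tens of minutes on one CPU while leaving the
per-run supporting-pair counts large enough for stable ratios. The
discovery-vs-brute-force comparison uses 100 genomes of 4–4.8 kb, where the
exhaustive all-diagonal oracle is affordable.

## Known limitations

* Only one sIR pair is analysed per run (`pair_index` selects among
  discovered pairs); multi-event genomes are future work.
* The internal mapper is substitution-only; use an external aligner for
  indel-rich data.
* The crossover position inside an incomplete arm pair is not identifiable
  from short reads; the midpoint convention changes which arm variant ends
  up at which boundary of the inverted reference.
* Flip-flop isomers of the canonical large IRs, point heteroplasmy, and
  inversions lacking flanking inverted repeats are explicitly out of scope.
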