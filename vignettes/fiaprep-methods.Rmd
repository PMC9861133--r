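---
title: "Methods: FIA-HRMS pre-processing in fiaprep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FIA-HRMS pre-processing in fiaprep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiaprep)
```

## The problem

Flow-injection analysis coupled to high-resolution mass spectrometry
(FIA-HRMS) trades chromatographic separation for speed: the sample is
infused directly into the source, and one acquisition collapses into a
centroided peak list of (m/z, intensity) pairs. Untargeted metabolomics at
this scale needs three things between the raw peak lists and statistics:
removal of the carrier/extraction-solvent background, alignment of the
peak lists of all samples into one feature-by-sample intensity matrix, and
a first-pass annotation of the aligned masses. `fiaprep` implements that
workflow as composable functions plus a single orchestrator,
`run_pipeline()`.

All mass comparisons use one relative tolerance $t$ in parts per million,

$$\mathrm{ppm}(a, b) = \frac{|a - b|}{b}\times 10^6,$$

with the **reference** mass in the denominator: the blank peak during blank
subtraction, the running mean during alignment, the theoretical mass during
adduct grouping and annotation. At $t \le 20$ ppm the denominator choice is
immaterial to first order, but fixing it makes every result bit-for-bit
reproducible. Matching is inclusive (`<= t`), and ppm ties are broken
toward the lower m/z so no outcome depends on input order.

## Blank subtraction

Each sample is paired with its blank through an explicit manifest (the
pairing is a property of the acquisition design that cannot be inferred
from file contents; a manifest supports both one-to-one and shared blanks
without guessing). For every sample peak independently, the blank peaks
within $t$ are collected and the intensity of the *closest* one (in ppm) is
subtracted once. A blank peak may serve several sample peaks. Differences
clamped at zero are removed: negative intensities are physically
meaningless, and zero is treated as missing downstream anyway. The full
candidate table (sample m/z, blank m/z, ppm, selected flag) is returned for
audit.

An optional per-peak intensity cut-off (strictly `<`, so a peak equal to
the cut-off survives) follows the subtraction. Its default is 0 — the
identity — because FIA-HRMS intensities are heavy-tailed over several
orders of magnitude and blank and sample intensity distributions overlap,
so no universal threshold separates signal from background; the knob exists
for users who have an instrument-specific reason to use it. A feature-level
reading of the cut-off ("below the value in all samples") is a defensible
alternative; the per-peak placement inside the blank-subtraction stage is
the one implemented, and a feature-level filter can be applied to the
matrix afterwards by the user.

## Alignment

Alignment is greedy with a progressively updated mean. Every peak of the
first sample seeds a feature whose running mean starts at that peak's m/z.
For each later sample, features are visited in ascending running-mean
order; each feature claims the unassigned peak of that sample closest in
ppm to its running mean (within $t$), and the mean is re-averaged
immediately, so subsequent comparisons see the drifted mean. Peaks left
unassigned after all features have been visited seed new features. The
procedure is a single forward pass: earlier samples are never re-scanned
after the mean drifts. Consequences that tests assert exactly:

* every input peak belongs to exactly one feature (partition), so total
  intensity is conserved into the matrix;
* a feature holds at most one peak per sample — the matrix has one cell
  per (feature, sample);
* rows are sorted by final mean m/z and feature ids are assigned 1-based
  after that sort.

Matrix cleaning replaces any stored 0 with `NA`, and the sample cut-off
(default 1) removes features detected in no more than that many samples.
Feature ids are deliberately *not* renumbered by the filter, so a surviving
row remains traceable to the pre-filter matrix.

## Adduct grouping (positive mode)

Electrospray in positive mode ionizes a neutral metabolite M mainly as
[M+H]⁺, with sodium and potassium adducts [M+Na]⁺/[M+K]⁺ from ubiquitous
salts. The grouping pass treats each row, in ascending mean m/z, as a
putative [M+H]⁺ anchor: it forms the neutral mass $M = m/z - m_{H^+}$,
computes the theoretical $M + m_{Na^+}$ and $M + m_{K^+}$, and searches the
not-yet-regrouped rows within $t$ (closest ppm wins). Matches are moved
directly beneath the anchor and labelled; a claimed row is skipped when its
own turn as anchor comes (first-claim). Rows are only permuted and
labelled, never duplicated or lost.

The "mass of hydrogen" here is the **proton**, 1.00727646 u, not the
neutral atom (1.00782503 u): [M+H]⁺ gains a proton, and the 0.000549 u
electron mass is ~3.7 ppm at m/z 150 — material at a 6 ppm tolerance.
Likewise the sodium/potassium constants are **cation** masses (atomic mass
minus one electron): Na⁺ = 22.98922070 u, K⁺ = 38.96315791 u. Both
conventions' constants are exposed by `ion_masses()` so either can be
reproduced explicitly.

## Annotation

`build_adduct_database()` parses HMDB-style metabolite XML (accession,
name, monoisotopic mass; tag names configurable, defaulting to HMDB's
conventions including its historically misspelled
`monisotopic_molecular_weight`) and expands each metabolite into its
theoretical adduct m/z values — M+H, M+Na, M+K in positive mode, M−H in
negative — using the same `ion_masses()` constants as the grouping stage,
a single source of truth. Records lacking a usable monoisotopic mass are
skipped and counted. The monoisotopic (not average) mass is the only
defensible choice for high-resolution data. The table is sorted by
theoretical m/z with a deterministic tie order, so identical XML yields a
byte-identical table. The XML document is parsed in memory; for multi-GB
database dumps a pre-built table can be cached and re-read as CSV
(`write_adduct_database()`/`read_adduct_database()`), which is the
recommended route.

`annotate_matrix()` collects, per feature, all database entries within $t$
of the mean m/z via interval lookup on the sorted table (sub-linear per
query). Exactly one match fills accession, name and adduct; several
matches report only the count — note a feature matching the *same*
metabolite under two adducts counts as 2, since matches are m/z-to-entry,
and users can collapse by accession downstream using the always-written
candidate audit CSV, which loses no information. Annotation never alters
mean m/z, intensities or row count, and accepts a matrix re-read from its
CSV, so it can run independently of alignment.

## The synthetic generator

`simulate_batch()` emulates the structural features the pipeline keys on:
planted feature centers in m/z 80–1000, multiplicative (ppm-scale) mass
jitter — instrument accuracy is specified in ppm, so jitter in Th would be
wrong — lognormal intensities (FIA-HRMS matrices span intensities from
~10 AU to ~10⁷ AU, a heavy-tailed regime), per-sample detection dropout,
solvent contaminants planted in blank and sample at equal base intensity
(an intensity-mismatch knob exercises the clamping path), and a fraction
of features emitted as full adduct triplets with a consistent neutral
mass. Defaults: 10 samples, 60 features, jitter sigma 0.8 ppm, detection
probability 0.8, 20 contaminants, triplet fraction 0.2.

Planted centers — including the theoretical Na/K masses of *every*
feature, not just the triplets, since the annotation database carries
those entries — keep a pairwise separation above 50 ppm, and infeasible
requests are refused rather than silently relaxed. Under these conditions
(separation > 4t, 3-sigma jitter < t/2 at t = 6 ppm) recovery is exact:
feature count equals planted count, contaminant removal and triplet
grouping and single-match annotation recall are all 100%, and the tests
assert them as equalities, not approximately. What passing these tests
does **not** show: behavior on real data with overlapping isotope
envelopes, in-source fragments, detector saturation, or features closer
together than the tolerance — there the greedy single-pass alignment can
split or merge features, and annotation ambiguity is the norm rather than
the exception.

## Numerical and design choices

* Exact duplicate m/z values within one spectrum are merged by intensity
  sum at ingestion — centroided data should not contain them, and summing
  is lossless for subtraction.
* Candidate windows are located with `findInterval()` on sorted mass
  vectors, slightly widened, then filtered by the exact ppm predicate, so
  windowing can never change a result, only speed it up. Brute-force
  all-pairs oracles in the test suite confirm equivalence on random
  instances.
* The tolerance $t$ is a required parameter with no default: it should be
  the instrument's external calibration boundary (6 ppm Orbitrap-class,
  20 ppm Q-TOF-class), a fact about the acquisition that a library
  default would silently get wrong.
* CSV is the canonical, bit-stable output; the Excel mirror is written
  only when `writexl` is installed. Missing values are empty cells.
* Determinism everywhere: no stage uses randomness, ties are broken by
  mass, and the simulator is seeded — re-running a configuration
  reproduces outputs byte for byte.

## Problem sizes in the test suite

Oracle-equivalence checks run on 100 random instances of up to 200 peaks
(blank subtraction) and databases of up to ~10⁴ entries (annotation);
alignment invariants on 50 seeded batches; planted-truth recovery on 20
seeded six-sample batches of 40 features with 12 contaminants and 25%
triplets. These sizes exercise every code path and boundary while keeping
the whole suite fast enough to run on every change.

## Known limitations

Single charge is assumed throughout (no z > 1, no dimers, no NH₄⁺/Cl⁻
adducts); negative-mode adduct grouping is not offered; annotation is a
first-pass m/z lookup that cannot distinguish isobars — identities require
MS/MS confirmation; and the aligner's single forward pass means the final
running mean can drift so that an early member sits slightly more than $t$
from the *final* mean (the join-time bound is what is guaranteed).
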