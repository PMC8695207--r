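---
title: "Herbicide-likeness scoring: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Herbicide-likeness scoring: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herblike)
```

## The problem and the model

Compounds that kill seedlings in agar-plate assays frequently fail on
soil-grown plants, and the failures track physico-chemistry rather than
target biology: soil-inactive hits are on average more lipophilic and far
more often positively charged at physiological pH. Commercial herbicides, by
contrast, occupy a fairly tight envelope in descriptor space. The
herbicide-likeness score turns that envelope into a single interpretable
number per compound.

The model has three layers:

1. **A descriptor set** — ten physico-chemical properties evaluated for the
   major (micro)species at pH 7.4: molar mass (g mol⁻¹), percentage of heavy
   atoms that are aromatic, polar surface area (Å²), log *D*₇.₄, log *S*,
   log *P*, and the integer counts of rotatable bonds, H-bond acceptors,
   H-bond donors and net formal charge.
2. **A reference model** (`hl_reference`) — for each continuous descriptor a
   mean μ and standard deviation σ; for each count a mode. The packaged
   `published_reference()` carries the printed statistics of 360 commercial
   herbicides (e.g. log *P* 2.9 ± 1.5, PSA 72 ± 39 Å², charge mode 0);
   `fit_reference()` refits those statistics from any library with complete
   descriptors, using the arithmetic mean and the *sample* SD (n − 1): the
   reference library is treated as a sample of the herbicide universe, not
   the universe itself.
3. **Scoring rules** (`hl_rules`) — continuous descriptors score by the band
   of z = |x − μ|/σ (1.5 / 1.0 / 0.5 / −1.0 for z ≤ 1, ≤ 2, ≤ 3, > 3);
   log *P* is weighted double (3.0 / 2.0 / 1.0 / −1.0) with no extra penalty
   beyond 3 SD. Counts score by offset from the mode (1.5 at the mode,
   decaying to 0.5 at ±2, catch-all −1.0 beyond), except formal charge,
   which is weighted heavily and asymmetrically: +3.0 at the mode, +2.0/+1.0
   on the anionic side, but −3.0 at offset +2, reflecting how strongly
   double positive charge predicts soil failure. The total over ten
   descriptors spans −12 to +18.

The score assumes descriptors act independently (it is a sum, not a joint
density) and that the reference envelope is roughly symmetric per descriptor
(bands use |z|). Both are simplifications the original weighting was designed
around, and both are inherited knowingly here.

## Numerical and boundary conventions

* **Band edges are inclusive.** "Within one standard deviation" is read as
  z ≤ 1, so a value exactly at k·σ takes the better score. Boundary cases
  thus consistently favour the candidate.
* **σ = 0 degenerates cleanly**: z is 0 at the mean and +∞ elsewhere, so a
  zero-variance reference scores only exact matches into band 1.
* **Half-point arithmetic.** All rule scores are validated to be multiples
  of 0.5 and totals are summed as integers of half-points, so the reported
  total is *exactly* the sum of the per-descriptor scores — no float drift,
  and equality comparisons against thresholds such as "17 or more" are safe.
  Threshold comparisons use ≥ throughout.
* **Mode ties** in `fit_reference()` resolve to the smallest tied value
  (deterministic; a message records the tie).
* **Ranking ties** resolve lexicographically by `compound_id`; equal totals
  carry no scientific ordering.
* **The charge rule is non-monotone as printed** (offset +2 scores −3.0 but
  |offset| > 2 scores −1.0). It is implemented exactly as specified, with no
  smoothing: the rule encodes a deliberate, targeted penalty, not a distance.
* **Unspecified H-bond-acceptor cells.** The published offset table leaves
  acceptor offsets −1 and −2 unspecified. The default
  (`hba_na_policy = "mirrored"`) mirrors the +1/+2 scores (1.0, 0.5),
  consistent with the symmetry of every other count row; `"strict"` instead
  assigns the catch-all −1.0. Both are selectable everywhere rules are
  built; with the published reference (acceptor mode 2) the choice touches
  only compounds with 0 or 1 acceptors.
* **Quantiles** (`percentile_interval()`) use linear interpolation between
  order statistics (`stats::quantile` type 7).
* **The two-sample t-test variant** is not fixed by the published analysis;
  `compare_descriptors()` defaults to the pooled-variance Student's t (the
  classic reading of "two-sample t-test") with Welch selectable, and records
  the variant in its output. Count descriptors are tested as printed values
  despite their discreteness, as in the original comparison. No
  multiple-testing correction is applied across the nine rows, again
  matching the original analysis.
* **Fisher's exact test** on charge classes (positive ≥ +1 versus
  non-positive) is two-sided by summation of tables with probability at most
  that of the observed table.

## Descriptor backends

Two providers sit behind one contract, and downstream scoring never inspects
which produced a record.

**Table backend** (`read_compound_table()`): authoritative. Reads CSV/TSV
with a canonical header (`column_map` adapts foreign headers), parses
numbers locale-independently, rejects rows with missing fields or fractional
counts into a reasons table, and errors with coordinates on structural
problems (duplicate identifiers, non-numeric text). All reproduction of
published numbers runs on this backend, because the original descriptors
were computed with a commercial package (ChemAxon Marvin 20.19) whose
log *P*/log *D*/log *S*/pKa models cannot be cloned.

**Computed backend** (`compute_descriptors()`): best-effort from SMILES via
OpenBabel. Multi-fragment inputs (salts) are reduced to the largest covalent
fragment (logged). Aromatic percentage counts heavy atoms only — the
convention of descriptor software — with a flag to include hydrogens; PSA is
topological PSA. pH 7.4 states use a small SMARTS table of ionisable groups
with textbook class pKa values (carboxylic ≈ 4.8, sulfonic ≈ −1, tetrazole
≈ 4.9, aliphatic amines ≈ 10–10.7, amidine/guanidine ≈ 12.5) and the
Henderson–Hasselbalch relation: an acid with pKa < 7.4 is deprotonated, a
base with pKa > 7.4 protonated, and log *D*₇.₄ = log *P* − Σ log₁₀(1 +
10^±(pH−pKa)) over recognised sites. A molecule with no recognised ionisable
group keeps log *D* = log *P* exactly. H-bond donors are counted as donor
*atoms* (so deprotonating an acid removes one; protonating a tertiary amine
adds one; primary/secondary amines keep theirs). log *S* uses the published
ESOL regression on descriptors already in hand. These are coarse class-level
treatments, adequate for the backend's role — trivially checkable molecules
and exploratory scoring — not a pKa engine; molecules with unusual
ionisation chemistry will be misassigned, which is why the table backend is
the one used for any quantitative claim.

## The synthetic generator

`generate_library()` draws libraries with the statistical structure the
method assumes: continuous descriptors independent normals with configurable
(μ, σ); counts from explicit categorical distributions so the generating
mode is controlled exactly (a Poisson would tie mode control to the mean).
`herbicide_like_spec()` uses the published herbicide means and SDs, counts
from discretised normals peaked at the published modes (spreads 2.5, 1.5 and
1.3 for rotatable bonds, acceptors and donors — wide enough that the
generated libraries are not caricatures), and a charge distribution over
−2..+2 of 2.0 / 25.0 / 72.2 / 0.6 / 0.2 %, reflecting that only three of
the 360 commercial herbicides carry positive charge.
`antimalarial_like_spec()` shifts exactly the two descriptors that separate
soil failures from herbicides: log *P* ~ N(4.2, 1) and a positive-charge
mass of 25 %. Aromatic percentage is clamped to [0, 100] and molar mass/PSA
floored at small positive values so every record is a valid descriptor set;
with the default parameters the clamps are hit in far under 1 % of draws and
the moment distortion is negligible at test tolerances.

What the generator does **not** emulate: correlations between descriptors
(log *P* and log *S* are strongly anti-correlated in real chemistry; here
they are independent), multimodality, heavy tails, and any notion of
chemical realisability — generated records carry no structures. Because the
score itself treats descriptors independently, independent marginals are
sufficient for testing the scoring layer; conclusions about real libraries
still require real descriptor tables.

Determinism: a spec's seed is applied locally (the ambient RNG stream is
saved and restored), and the same seed always reproduces the identical
library, byte-for-byte through the CSV writer.

## Test design and problem sizes

The scoring tables are verified cell-by-cell against constants typed
independently of the implementation, and totals are enumerated over the full
cross-product of band/offset classes (4⁶ × 6⁴ ≈ 5.3 million combinations)
by vectorised accumulation, against an independent lookup-table sum; the
brute-force minimum over that enumeration is −12. The aggregate scorer is
additionally checked compound-by-compound on a seeded subsample of
realisable combinations. Fisher p-values are compared with exhaustive
hypergeometric enumeration over all 5 370 two-by-two tables with margins at
most 12 and two non-empty groups. Parameter recovery runs at n = 500
(means within 3σ/√n, SDs within 20 %) and n = 1000 (exact mode recovery);
group separation at n = 500 per arm. These sizes give comfortable
statistical margins while keeping the whole suite around half a minute.

One acceptance check — reproduction of the published mean scores (13.6 for
the herbicides, 14.4 / 11.9 for soil-active / plate-only antimalarials) and
the eleven-compound ≥ 17 shortlist of the 631-compound liver-stage library —
requires the original supplementary descriptor datasets, which are not
redistributable with the package. The test states exactly where to place
them (`inst/extdata/esi/dataset{1,2,3}.csv` with the canonical header) and
fails with that message when they are absent rather than silently skipping:
the capability is implemented and exercised on synthetic data, but the
published numbers can only be recomputed from the published descriptors.

## Known limitations

* The computed backend's protonation rules are class-level; zwitterions,
  polyprotic interplay and tautomer-dependent pKa are out of scope, and its
  log *S*/log *D* are regressions, not measurements.
* The published reference model uses printed (rounded) constants by design;
  refitting from a descriptor table will differ in the last digit.
* The score is a triage heuristic: it encodes where herbicides live in
  descriptor space, not whether a plant target exists. High-scoring inactive
  compounds are expected and observed.
* Robust statistics (trimmed means, MAD) and learned weights are explicit
  non-goals; the weights are fixed by the published rules.
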