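---
title: "Harmonizing multi-source microfossil occurrence data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing multi-source microfossil occurrence data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(foramforge)
library(dplyr)
```

## The problem

Deep-sea drilling programs, literature compilations and data archives all
hold species-level occurrence records of planktonic foraminifera, but in
incompatible shapes: different table layouts, five different abundance
encodings, ages expressed as numbers, biozone assignments or
magnetostratigraphic chrons on assorted timescales, and coordinates given
only for the modern position of a drift-displaced site. foramforge turns
such heterogeneous per-sample tables into one harmonized, age-modelled,
paleo-rotated, quality-flagged occurrence dataset — one row per species per
sample depth per hole — and computes the validation summaries (richness per
time bin, stratigraphic-range completeness, latitude–time coverage) that
tell you whether the result is fit for macroecological use.

Every stage is testable because the package also ships a synthetic-core
generator with known truth: a seeded corpus of drill holes with
piecewise-linear age–depth curves, species occurrences drawn from known
stratigraphic ranges, marker events observable as presence transitions,
injected reworked contaminants, and cross-source duplicates recorded in a
ledger.

## Pipeline stages and their models

### Ingestion and schema

Source tables are read through a per-source column mapping (YAML), in
either long (one row per species per sample) or wide (samples × species)
layout; unmapped metadata becomes `NA`. After all upstream stages, records
missing any of the four *crucial* columns — species name, abundance, age,
paleocoordinates — are removed, each with exactly one primary reason.
Identifiers are assigned after a deterministic sort on (hole, depth,
species), so `rowID`s are stable across re-runs.

### Taxonomy

Raw names are whitespace- and case-normalized; open-nomenclature qualifiers
(`cf.`, `aff.`, `?`, `sp.`) mark a record as not resolvable to a species
concept and it is rejected — a deliberately conservative reading of
"unclear or imprecise". A curated synonymy maps each raw name to its senior
synonym with a status; typos must be listed explicitly (no fuzzy matching —
silent auto-correction of taxon names causes more damage than it repairs).
Rows of one sample that resolve to the same senior name are merged with
abundances summed (set to one for presence/absence samples), retaining the
original names and values comma-joined. Synonym merging runs *before*
relative abundances are computed, so percentages reflect merged taxa.

### Abundance

Five encodings are supported: counts, relative percent abundances,
specimens per gram, ordinal binned codes, and presence/absence. The default
binned vocabulary is N &lt; P &lt; R &lt; F &lt; C &lt; A &lt; D coded
0..6; because a letter's meaning is dataset-dependent ('A' can mean absent
or abundant), per-dataset override vocabularies are honoured. A stray
letter inside an otherwise counted sample records presence without a count
and is assigned 0.01. Counted and per-gram samples get
`rel.abun = 100 × abundance / num.ind`, where `num.ind` is the recorded
specimen total when available and the within-sample sum otherwise. For
binned and presence/absence samples `rel.abun` stays absent: ordinal codes
are not proportions, and fabricating percentages from them would poison any
downstream community analysis. Zero-abundance records are retained in the
full dataset (they are evidence of sampling) but excluded from the main
one.

### Chronology

Marker events (first/last occurrences, acme limits, magnetochron
boundaries) are calibrated to GTS 2020 ages through an event table keyed by
taxon, event type, zonal scheme and region — the same datum can define
different zones in different schemes, and some datums are diachronous
between basins and climate belts. Sites are assigned to regions using
configurable Atlantic longitude bounds (default 70°W–20°E) and an inclusive
tropical belt at |lat| ≤ 23.5°. The abbreviations LO/HO are ambiguous
(lowest vs last occurrence); they are resolved from the study's full event
list: LO paired with HO reads as *lowest*, LO mixed with FO reads as
*last*.

Tie points are placed at the midpoint of the bracketing sample pair — for
an extinction, halfway between the shallowest presence and the first absent
sample upcore — with the event's age midpoint as the age and its calibrated
width as the range. A datum whose presence run reaches the cored interval's
end is not bracketed and yields no tie. Because single-grain occurrences in
shipboard-style data are frequently reworked material, presences are
cleaned before datum picking: only runs of at least three consecutive
sampled depths count as occupancy (`min_run = 3`; two adjacent reworked
grains are rare but observed in the synthetic corpora, hence three). A 0 Ma
seafloor tie is added only when the sediment surface is explicitly declared
Holocene/Recent/Modern.

### Age–depth models

Tie points are split into intact stratal segments wherever a
depth-consecutive age gap exceeds 10% of the hole's tie-point age range
(the comparison uses a 1e-9 relative tolerance so a gap sitting exactly on
the threshold does not split), and at declared structural breaks. "Age
range of the core" is read literally as max − min tie age of the hole
before splitting. Within each segment five estimators are fitted:

* **zone** — mean of the bounding tie ages, error = bounding width;
  magnetostratigraphic ties take precedence where they bracket a depth;
* **magneto** — the same using magnetostratigraphic ties only;
* **interp** — piecewise-linear interpolation between depth-consecutive
  ties, error propagated as the larger of the two bracketing tie ranges
  (the column is standard but no formula is, so the conservative max);
* **model** — with fewer than 5 ties an OLS line of age on depth; with 5 or
  more a penalized cubic regression spline (mgcv, basis dimension
  `min(10, n − 1)`, smoothness by GCV with the effective-degrees-of-freedom
  cost inflated by γ = 1.1). The smooth is *not* constrained to be
  monotone: reversals are informative diagnostics, and forcing monotonicity
  would hide bad tie points.

The estimator with the lowest RMSD against the tie ages at tie depths is
selected; RMSD ties break in the order interp &gt; model &gt; zone &gt;
magneto, preferring estimators that honour the ties exactly. Manual
confirmation of an age model is replaced by a per-hole override that
bypasses the criterion. The linear/GAM r² is unadjusted. Samples outside
every segment's tie-point depth span cannot be confidently dated and are
dropped with a logged reason; samples that arrive with a numeric age keep
it (`age.calc = "orig"`).

### Paleocoordinates

Plate motions are finite (Euler-pole) rotations parsed from the GPlates
`.rot` dialect, with the standard sign convention (positive =
counter-clockwise looking down the pole from outside the sphere). The total
rotation of a plate at an arbitrary age interpolates between the bracketing
table entries in stage-rotation space — the stage rotation's angle is
scaled linearly about its own axis, equivalent to spherical linear
interpolation — and then composes through the plate circuit to the anchor.
Naive interpolation of pole latitude/longitude/angle is wrong for large
angles and is not used. Sample age is matched by interpolation rather than
nearest table node; the alternative would quantize paleolatitudes at
coarse-stepped models. Modern samples (age 0) keep their modern
coordinates. Records whose plate or age the model cannot cover are left
unrotated and later fail the crucial-column filter.

### Quality control

Cross-source duplicates — identical on species, numeric abundance (to
1e-9), sample depth and coordinates — collapse to the record from the
highest-priority source. Records falling significantly outside their
species' known stratigraphic range are flagged `trim = "exc"`: more than
2 Ma outside in the Neogene (record age &lt; 23 Ma) and more than 5 Ma in
the Paleogene, the looser bound reflecting larger age-model errors in older
sediment. The era is keyed to the record's assigned age (the paper-trail
leaves the keying open; the record age is what the threshold is protecting,
and it is configurable). Nothing is deleted — the flag ships with the data
so users choose their own trim.

### Metrics

Richness is distinct species per half-open 1 Ma bin over the trimmed set.
Completeness is the fraction of bins overlapping a species' range
(range treated as closed, bins half-open; a range endpoint sitting exactly
on a bin edge does not pull in the bin beyond it, so a 5–10 Ma range with
1 Ma bins expects exactly five) in which the species occurs. Partial bins
at range ends count as expected. The coverage grid folds hemispheres into
absolute-latitude bands (default 30°).

## The synthetic corpus: what it emulates and what it does not

`simulate_core()` builds one hole: a piecewise-linear age–depth truth (one
sedimentation rate per depth segment, default two segments), an optional
hiatus, species presences drawn from known ranges with a stated detection
probability (default 1), abundances rendered in any encoding, barren
samples retained as zero-abundance rows, and contaminants injected per
record at a stated rate, always placed more than the trim tolerance +
0.5 Ma outside the species' range. `simulate_corpus()` staggers hole
surfaces 4 Ma apart with rates of 4 and 6.25 m/Ma over a 100 m core
(≈20.5 Ma per hole), cycles the source dialects (wide counts, long binned,
long presence/absence), and mirrors 10% of records into a duplicate source
with a ledger. The default species pool has 51 species with 8 Ma ranges
whose boundaries tile 0–58 Ma every 1 Ma — about eight coexisting species
and a marker event every million years, the density of a well-zoned pelagic
section. The default corpus is ~5,000 records over 12 holes; the test suite
and the acceptance script use these sizes throughout.

What passing tests on this corpus show: the mechanics of ingestion,
merging, conversion, datum picking, segmentation, estimator selection,
rotation, deduplication and trimming recover a known truth exactly or to
stated bounds. What they do not show: robustness to real-world taxonomic
drift between historical datasets, diachronous datums, non-linear
sedimentation within segments, patchy preservation, or age models built
from sparse, conflicting shipboard data — real data are harder than the
generator in all these ways, and the paper-trail columns (`r2`, `n.pts`,
`age.calc`, `trim`) exist precisely so users can audit those harder cases.

## Numerical choices

* Hiatus threshold comparisons use a 1e-9 relative tolerance (strict
  "greater than" semantics at the printed precision).
* Duplicate matching rounds numeric keys to 9 decimals.
* Rotation angle extraction from a matrix uses `atan2` of the skew norm
  against trace−1, stable to &lt; 1e-12° near the identity where `acos`
  loses six digits; near half-turns the axis comes from the symmetric part.
* Interpolation through tie points collapses coincident-depth ties to
  their mean age before `approx`.
* RMSD ties in estimator selection break by the documented preference
  order; `which.min` applies it via candidate ordering.
* Degenerate inputs: segments with one tie fall back to the zone
  estimator; trend fits are unavailable (`NULL`) when all ties share one
  depth; an empty tie set drops the hole with a logged reason.

## Known limitations

* Typo correction requires explicit synonymy entries; unknown names are
  rejected to a curation log rather than guessed.
* The smooth estimator can be non-monotone between widely spaced ties.
* Composite-depth splicing across holes (mcd) is out of scope; depths are
  mbsf throughout.
* Plate assignment is an input; the package does not construct plate
  polygons.
* Completeness is computed over all species with records; restricting to a
  clade or wall-texture group is the caller's subsetting decision.
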