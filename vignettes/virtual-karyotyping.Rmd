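---
title: "Virtual karyotyping of soft-masked assemblies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual karyotyping of soft-masked assemblies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virtukaryo)
```

## The problem

Classical fish cytogenetics describes a karyotype by chromosome number and
morphology: the diploid number 2n, the counts of bi-armed (metacentric m,
submetacentric sm) and uni-armed (subtelocentric st, acrocentric a)
chromosomes, and the fundamental number NF — the total arm count. With
chromosome-level genome assemblies, the same kind of per-chromosome portrait
can be computed directly from sequence: a *virtual karyotype* that shows, in
windows along each size-sorted chromosome, how repetitive the sequence is and
how GC-rich its repetitive and non-repetitive fractions are. The repeat
annotation comes for free with soft-masking, the convention by which repeat
pipelines lowercase repetitive sequence and leave the rest uppercase.

`virtukaryo` implements this portrait and the two analyses that naturally
accompany it in salmonid work: a group-wise contrast of genome size against
genomic GC% (salmonids versus other teleosts), and the cytotaxonomic
arithmetic over a curated review table of brown trout (genus *Salmo*)
karyotypes. Because no particular assembly version is pinned anywhere in the
workflow, everything is validated against seeded synthetic genomes whose true
composition is known exactly.

## Windowed composition

Every base of a soft-masked sequence belongs to exactly one of three classes:

* **repeat** — lowercase `a/c/g/t`;
* **non-repeat** — uppercase `A/C/G/T`;
* **ambiguous** — any other IUPAC letter in either case (N above all).

The class partition is a package invariant: the three counts always sum to
the sequence length. Ambiguous bases are excluded from every GC and
repeat-fraction denominator — an N-rich assembly gap must not drag a window's
GC% toward zero. Consequently an empty fraction has a *missing* GC (`NA`),
never 0; a 0 would silently corrupt any mean or plot computed downstream.

`window_chromosome()` tiles `[0, length)` with non-overlapping windows
(0-based half-open coordinates, matching BED). Two boundary decisions matter:

* the trailing window is kept at its true (shorter) length, so that window
  totals conserve the chromosome length exactly;
* windows whose unambiguous content is below a threshold (default 50% of the
  window) are flagged `low_confidence` but retained in tables — dropping
  them would break the conservation invariants — and drawn grey in plots and
  skipped by dispersion statistics.

For each window the GC% of the two fractions and of their union obey the
mixture identity
`n_rep * gc_rep + n_nonrep * gc_nonrep = (n_rep + n_nonrep) * gc_total`,
which the test suite checks exactly (in counts) against a naive per-base
oracle. Aggregating window counts into coarser windows reproduces a direct
computation at the coarser size, so profiles at several resolutions are
mutually consistent.

The default window size is 100 kb; the multi-resolution workflow in
`analysis/02_virtual_karyotype.R` uses 50 kb, 100 kb and 500 kb. These sizes
are this package's own defaults, chosen so that a typical 0.5–3 Gb fish
assembly yields tens to hundreds of windows per chromosome — enough for
dispersion statistics, few enough to plot.

## The virtual karyotype

`build_virtual_karyotype()` orders chromosomes by assembled length,
descending, with ties broken by name (ascending) so the ordering is total and
deterministic, and assigns size ranks (1 = largest). Ranks matter because
assembly naming rarely follows size: a statement like "the 5S rDNA cluster
sits on the fourth largest chromosome" is exactly what comparison with a
microscope karyotype needs, and features supplied in BED are therefore
reported with their rank.

Rendering choices:

* per-window fill encodes the repeat fraction on a red (0%) to green (100%)
  scale with **fixed** endpoints — rescaling to the data would make two
  genomes' plots incomparable;
* the vertical position of each window box is its GC%, so composition and
  base content are read off a single panel;
* feature markers are placed at the feature midpoint and stacked when they
  would overlap;
* the backing window table written next to the image *is* the input profile
  (restricted to retained chromosomes), not a recomputation, and is
  byte-stable across runs.

"Homogenization of GC% along chromosomes" is a qualitative claim; the package
operationalizes it as the dispersion — standard deviation and interquartile
range — of window GC values per chromosome (`homogeneity_report()`). This is
an interpretation, and it is flagged as such: the statistic is computed over
confident, non-missing windows only, and chromosomes with fewer than two such
windows are flagged rather than reported with a meaningless dispersion.

## Genome size versus GC%

`group_trends()` contrasts a focal group against the rest. Design choices,
each genuinely open in the source material:

* GC% is correlated against **log10 of genome size in Mb**. Fish genome
  sizes spread multiplicatively (roughly 0.3–3 Gb at chromosome level), so a
  log scale is the natural axis; the slope is then percentage points of GC
  per tenfold size change.
* Pearson's r is reported alongside Spearman's rho. The rank correlation
  hedges the scale choice: it is invariant under any strictly monotone
  transform of size.
* Focal-group membership defaults to a genus-list match for Salmonidae and
  can be overridden with an explicit species list or regex
  (`assign_groups()`).
* No multiple-testing correction is applied: two groups, descriptive
  comparison.
* Groups need at least three records; a group with constant size or GC is
  flagged `degenerate` rather than fitted.

The difference-of-slopes report states the focal-minus-other slope
difference, its standard error from the interaction model, and whether the
signs oppose — the qualitative claim of interest.

## Karyotype arithmetic and the review table

`compute_nf()` implements NF = 2·(m + sm) + (st + a): subtelocentric and
acrocentric chromosomes are scored uni-armed. Part of the literature scores
subtelocentrics bi-armed, which inflates NF by the st count; scoring
differences, not biology, explain most NF disagreement between reports of
the same form. `nf_from_counts(..., st_biarmed = TRUE)` reproduces the
alternative convention on request so both values can be reported side by
side, but subtelocentrics are never promoted silently.

The packaged review table (`load_karyotype_table()`) transcribes the printed
cells of the brown-trout literature review verbatim, 66 records across six
drainage basins. Cell notation: `lo-hi` is an observed range (ASCII hyphen in
the fixture; en dashes are accepted on input, and one source prints a
reversed range, which is kept in printed order while arithmetic uses the
sorted bounds); `x/y` is a split where both subclasses were determined (so
`14/8` is 14 m + 8 sm, a bi-armed total of 22); an empty cell or a lone `/`
is typed *missing* — as is an individuals count of `embryos` — never coerced
to zero. Ranges propagate through NF by interval arithmetic (minima with
minima, maxima with maxima).

`validate_record()` checks each record's internal arithmetic: bi-armed +
uni-armed must equal 2n, and the reported NF must equal the recomputed one;
for ranged cells the reported interval must lie within the computed bounds.
Findings are returned, never thrown, and carry a severity: `mismatch` for a
genuine inconsistency, `info` for a value that cannot be checked. On the
packaged table the only finding is informational — one historical record
(Ochrid Lake) reports 2n and NF without arm counts.

Two documented literature inconsistencies are deliberately *surfaced, not
resolved*:

* the flathead trout karyotype of 7 m + 5 st + 28 a pairs is reported with
  NF = 96, but uni-armed st/a scoring gives 2·14 + 66 = 94; validation
  reports the mismatch rather than silently passing;
* the "alabalach" trout is quoted with 2n = 84 in parts of the literature
  while its tabulated record prints 2n = 80; the table carries the printed
  value.

## Synthetic data: what it emulates, and what it does not

`generate_genome()` draws a genome whose statistical structure matches what
the windowed analysis assumes: alternating repetitive and non-repetitive
blocks with geometrically distributed lengths (default mean repeat block 500
bp — interspersed-repeat scale, and short enough to exercise window-boundary
code), i.i.d. bases within each fraction at that fraction's GC target with G
and C equally likely, and independent N overlay (default 1%, a typical gap
content). The defaults used by the analysis scripts (55% repeats, repeat
fraction GC 55% versus 42% non-repeat) mirror a repeat-rich, repeat-GC-rich
salmonid-like assembly.

What it does **not** emulate: repeat families and their age structure,
isochore-scale GC heterogeneity, dinucleotide composition, telomere/
centromere structure, and clustered (rather than independent) assembly gaps.
Passing the recovery tests therefore shows that the measurement machinery is
unbiased and correctly calibrated under the stated model — it does not show
that any particular real assembly is homogeneous or repeat-rich. The optional
smoke procedure (`analysis/05_real_assembly_smoke.R`) exists for running the
identical pipeline on a user-supplied soft-masked assembly.

Every generator takes a single integer seed and is byte-deterministic given
it; each emits a *truth* record of the realized (not merely targeted)
composition, computed during generation by a direct pass over the drawn
bases, so expected values of any downstream statistic can be formed without
re-reading the FASTA.

`generate_trend_table()` draws genome sizes log-uniformly (default 300–3000
Mb per group — one decade, the spread of chromosome-level teleost
assemblies) and GC as intercept + slope·log10(size) + Gaussian noise, clipped
to (0, 100). Default slopes are +2 (focal) and −2 (other) % GC per log10 Mb
with noise SD 1%, intercepts 35% and 48% so both groups sit in the realistic
37–43% band at typical sizes.

## Validation problem sizes

The suite's stochastic checks run at sizes chosen to give the statistics
clear room: composition recovery on twenty seeded 1 Mb genomes (a fraction
of ~500 kb bases puts 3 binomial SEs at about 0.2 percentage points of GC);
trend recovery on 200 replicate tables of 50 records per group (slope
standard error ≈ 0.5, so ±2 slopes are ~4 SEs from zero and sign recovery is
essentially certain); window-engine equivalence on 100 random sequences up to
10 kb against a per-base oracle. The dispersion oracle for stratified GC uses
the two-point mixture SD with a Monte-Carlo standard error of
`sd/sqrt(2(n-1))`.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open everywhere internally and in BED output;
  1-based inclusive appears only in human-readable messages.
* `min_length` in `read_masked_fasta()` defaults to 1 Mb, dropping unplaced
  scaffolds so the karyotype shows assembled chromosomes only; every
  exclusion is logged.
* Duplicate FASTA names, non-IUPAC characters and malformed BED intervals
  are hard errors naming the offending record or line.
* An empty feature set, a single-record summary table, and an all-ambiguous
  assembly (GC = `NA`) are all legal inputs with defined results.
* Sorting ties (equal chromosome lengths) break by name so every ordering is
  reproducible.

## Known limitations

The tool measures what soft-masking asserts: the quality of the repeat
annotation is inherited from the input and cannot be assessed here.
Fraction-specific GC in very small or mostly-masked windows is noisy, which
is why confidence flagging exists. The comparative analysis is descriptive —
records are not phylogenetically independent, and a phylogenetically
corrected regression is a deliberate non-goal. Virtual-to-cytogenetic
chromosome assignment is by size rank only, which in practice identifies only
the few largest chromosomes unambiguously.
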