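---
title: "bnpcp: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bnpcp: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnpcp)
```

This vignette is the package's own account of its science: what each
stage assumes, which parameters matter and why they default to the values
they do, what the synthetic-data generator emulates (and therefore what a
green test does and does not establish), and where the design was
genuinely open.

## The experimental setting

An epitope-tagged bait protein is affinity-purified together with its
native complexes, separated intact on a blue native gel, and the lane is
cut bottom-to-top into equal fractions (48 in the design this package
mirrors). Each fraction is analyzed separately by LC-MS/MS and quantified
with MaxQuant, producing one `Intensity k` and one `iBAQ k` column per
fraction. Fraction 1 is the gel bottom and therefore the *low*-mass end;
every interface in this package uses that orientation.

Two quantities carry all downstream inference:

* the **migration profile** — a protein's fraction intensities divided by
  its total intensity, so that proteins of very different abundance
  become comparable shapes; and
* the **bait-normalized iBAQ ratio** — iBAQ approximates molar abundance,
  so the per-fraction ratio to the bait tracks stoichiometry relative to
  the bait across the separation.

## Stage by stage

### Reading and filtering (`read_quant_table`, `filter_quant_table`)

The table dialect is MaxQuant's: tab-delimited, `"+"` marker columns for
contaminants / reverse hits / proteins only identified by site,
semicolon-separated protein groups (the first, majority protein becomes
the canonical identifier), and blank or missing cells meaning "not
detected", read as 0 and never imputed. Fraction columns are ordered by
their numeric suffix, not file order. Filtering always removes QC-flagged
records. Nonspecific binders identified from control purifications are
either removed or merely annotated (`is_control`); the pipeline defaults
to annotation, because marking control-list proteins in outputs (rather
than silently deleting them) preserves the evidence trail, and the
original analysis appears to have marked rather than removed them.

### Profiles and molecular weight (`build_profiles`, `calibrate_mw`)

Profiles are built from the intensity columns; iBAQ is reserved for
stoichiometry. A zero-total protein keeps an all-zero profile flagged by
`total_intensity = 0` and is excluded from clustering (no distance is
meaningful for it). Apparent mass is interpolated piecewise-linearly in
log10(mass) against fraction — gel migration is approximately log-linear
in mass — exact at the ladder anchors, and refusing queries outside the
ladder span rather than extrapolating.

### Replicate alignment (`align_replicates`)

Gel cutting differs between replicates by an integer number of fractions,
so replicates are aligned by shifting one of them. The defining formula
is the difference of the bait apex fractions. That estimator is exact on
clean data but brittle under missingness: zeroing the bait's single most
intense cell (10% per cell under the default dropout) moves the raw
argmax by up to the full peak separation. `method = "profile"` therefore
searches integer lags for the minimum Manhattan distance between the two
(dropout-repaired) bait profiles; it agrees with the apex method on clean
data and is what the pipeline uses. Only integer shifts are considered —
no warping — and shifted profiles are zero-padded and truncated at the
gel edges without renormalization.

### Clustering (`manhattan_matrix`, `average_linkage`, `bait_region_of_interest`)

Distances are Manhattan on normalized profiles; clustering is UPGMA
(average linkage), maintained with the exact Lance–Williams update and a
deterministic tie-break (lowest cluster-index pair; leaves numbered in
input order). Average linkage on a metric is reducible, so merge heights
are non-decreasing and height cuts are well defined.

The "region of interest" around the bait is the bait's cluster at the
first merge reaching `k` members, `k = 15` by default. This value was
calibrated on the synthetic fixture: the complex's flat-ratio subunits
have *identical* noiseless profile shapes, so the bait's cluster reaches
any small `k` among those near-duplicates before the entity-biased
subunits (distance ≈ 0.3) join; a cut at `k` near the core-subunit count
systematically misses them, while `k = 15` (bait + 7 core + 3 enriched +
4 partners) recovered the full complex with zero contaminants in 100/100
noisy runs. On real data `k` should be set from the expected interactome
size; it is a config field.

### Bait peaks and entities (`detect_peaks`, `assign_entity`)

Peak detection works on the repaired profile: an isolated zero cell (a
zero flanked by nonzero neighbors) is a MaxQuant-style missing value
punched into an otherwise smooth peak, and is repaired by neighbor
interpolation; genuine zero baselines (runs of zeros) are untouched.
Local maxima (plateaus of equal values merge; apex at the lowest index)
are filtered by topographic prominence relative to the profile maximum
(`min_prominence = 0.25`). The default smoothing window is 1 — no
smoothing — because under multiplicative noise the off-peak baseline is
exactly zero, so smoothing does not remove false peaks; it only dilutes
sharp true peaks (and especially dropout-repaired apexes) into the
inter-peak valley. On data with additive baseline noise a window of 3–5
is appropriate; both the prominence threshold and the window were
calibrated on the synthetic fixture (100-seed recovery rates) and are
documented as such.

Region bounds: between two kept apexes the boundary is the midpoint of
the refined apexes (lower middle for odd separations) — the inter-peak
minimum itself wanders by ±1 fraction under noise and that wander flips
membership calls of partners whose peaks sit one fraction from the
boundary; outward, a region extends while the profile keeps falling and
is truncated below 1% of the peak height, which keeps regions tight so
that "outside all regions" (≥ 80% of mass, e.g. a monomer band) remains
meaningful. Entity shares are sums of (repaired, renormalized) profile
mass inside each region; calls use `call_threshold = 0.2`, i.e. a fifth
of the protein's signal co-migrating with an assembly counts as presence.

### Stoichiometry (`ratio_series`, `fit_slope`, `classify_trend`)

Ratios are taken only where the bait iBAQ is positive (the ratio is
undefined elsewhere; such fractions are skipped and counted). The window
defaults to fractions 26–36, the peak limits of the design this package
mirrors. OLS of ratio on fraction index with a t-test on the slope
(df = n−2) operationalizes the visual "horizontal trend line" call at
`alpha = 0.05`; the original analysis classified trends visually and
prescribed no test. Options, all off by default: `log_ratios` (fits
log-ratio, the correct error model under multiplicative noise — kept off
by default because raw normalized iBAQ is what the field plots),
`drop_zeros` (treat zero iBAQ as missing rather than as ratio 0 — the
pipeline turns this on, since a handful of dropout zeros otherwise
dominate the residuals), and Benjamini–Hochberg adjustment reported
alongside (the original analysis applied none, so the primary call stays
unadjusted).

Numerical guard: a fitted change across the window below 1e-8 of the
typical ratio magnitude is floating-point residue of a constant series
(the 0/0 t-statistic is otherwise arbitrary) and is treated as slope 0.

### Co-occupancy (`proxy_set`, `venn3`, ...)

Gene identity is uppercased symbol string match — published target lists
are compared as given, with no alias resolution and no peak-to-gene
assignment (those belong to the upstream ChIP-seq studies). Percentages
round half-up to integers, matching how such overlaps are reported.
`venn3_from_counts` exists for worked examples where only printed
partition counts are available; its members are synthetic placeholder
symbols and are labeled as such.

### Pipeline and demo (`run_pipeline`, `demo_run`)

Stages run in a fixed order; a failed stage is recorded and everything
downstream is skipped. Replicates are kept separate and reported per
replicate (whether the original analysis averaged them is not stated);
pooled fits across the aligned replicates are used only where a single
estimate is wanted, and the regression window for replicate 2 is shifted
by the alignment offset. Outputs contain no timestamps, so a rerun of the
same config is byte-identical.

`demo_run` asserts six qualitative patterns on the default fixture. Two
evaluation choices deserve explanation:

* **Entity patterns** are judged on the aligned replicate-consensus
  profile (mean of replicate 1 and shifted replicate 2). A fraction
  missing in one replicate is covered by the other — that is what
  replication is for — and the consensus makes the bimodality and
  membership calls robust to the ~19% per-pair chance that some apex cell
  is dropped out in one replicate.
* **Trend patterns** are judged on median-centered log-ratio fits. The
  bait is the shared denominator of every ratio, so its per-fraction
  noise tilts *all* slopes coherently; centering each slope (pooled and
  per replicate) on the median slope of the assessed subunits removes
  that common term exactly, and the median is robust to the enriched
  minority. "Ascending" requires centered pooled p < 0.01 with a positive
  centered slope in each replicate; a flat expectation is only overturned
  by a *replicated* signal (centered pooled p < 0.001 and per-replicate
  p < 0.05 with agreeing sign). The thresholds are stringent because the
  compound assertion spans ten subunits across several seeds: per-call
  error near the conventional 0.05 would fail the joint check routinely
  on truly flat inputs. They were chosen from 100-seed aggregate error
  rates on the fixture, not from any particular seed.

## The synthetic world

`default_truth()` states the simulated world once: 48 fractions; two
entities with apexes at fractions 29 and 33 (both inside the regression
window), Gaussian widths 0.8 fractions (the peaks partially overlap, as
in the motivating separation), entity II carrying 1.15× the bait amount;
seven flat-ratio core subunits; three subunits 2× enriched in entity II;
one entity-I-only, two entity-II-only, and one both-entity partner; six
contaminants with unstructured background profiles. Noise is
multiplicative log-normal (CV 0.1 by default; MS intensity noise is
multiplicative), dropout is independent Bernoulli zeroing per cell (rate
0.1), replicate 2 is shifted by one fraction, and iBAQ is intensity
divided by a seed-deterministic per-protein theoretical-peptide count.
The Gaussian kernel is truncated at the gel bounds and not renormalized —
mass that would run off the gel is simply lost. The source study reports
neither per-fraction variance nor missingness rates; these defaults are
design decisions, stated once and not revisited.

What the generator does **not** emulate: peptide- or spectrum-level
effects, intensity-dependent (left-censored) missingness, gel smearing
beyond Gaussian peaks, correlated noise across fractions, ragged
fraction-to-fraction cutting beyond a rigid integer shift, and any
between-protein interference. A green test therefore establishes that the
algorithms recover a known two-assembly structure under multiplicative
noise and uniform dropout — not that they are robust to every artifact of
real BN-PAGE MS data. In particular, real missingness is
abundance-dependent, which would make the single-cell dropout repair
*more* effective than in the simulated world (real dropout rarely hits
the most intense cell), so the simulated difficulty is, if anything,
adversarial.

## Numerical conventions

* Profile normalization asserts sums within 1e-12; comparisons in tests
  use that tolerance.
* Apex ties break toward the lowest fraction; UPGMA ties break toward the
  lowest cluster-index pair; both are contracts, tested with exact-tie
  fixtures.
* Percent rounding is half-up (`floor(x + 0.5)`), not banker's rounding.
* Degenerate inputs are classed errors (`bnpcp_value_error`,
  `bnpcp_format_error`, ...): all-zero profiles for apex/peak operations,
  empty reference sets, non-monotone ladders, regression windows with
  fewer than 3 usable fractions.

## Known limitations

* Overlapping bait peaks are split at the apex midpoint, not
  deconvolved; a Gaussian-mixture deconvolution is out of scope.
* Entity labels are positional (I = lower fraction = lower mass); mass
  meaning attaches only when a ladder is supplied.
* The co-cluster cut rule needs an expected complex size `k`; there is no
  automatic model selection on cluster number.
* Trend classification assumes an approximately linear ratio change
  across the window; a sharp sigmoidal transition inflates lack-of-fit
  and weakens, but does not bias, the test.
* At noise CV 0.2 *with* 10% dropout, consensus bait bimodality still
  fails in roughly 2–3% of replicate pairs (measured over 100 seeds);
  the demo treats this as a property of the stated world, not a bug.
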