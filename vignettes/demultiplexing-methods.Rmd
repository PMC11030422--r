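---
title: "Demultiplexing top-down DIA data: model, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demultiplexing top-down DIA data: model, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tddemux)
```

## The demultiplexing problem

Top-down DIA co-fragments every intact proteoform ion inside each preset
isolation window, cycle after cycle. The resulting MS/MS spectra are
multiplexed: fragments of all co-isolated proteoforms are superimposed, and
a database search over them is unreliable. `tddemux` converts the
deconvoluted *feature* representation of such a run — single-charge
proteoform features (SCPFs) on the MS1 side, fragment features per
isolation window on the MS/MS side, each with a per-cycle extracted ion
chromatogram (XIC) — into pseudo non-multiplexed MS/MS spectra, one per
SCPF, by deciding which fragment features belong to which precursor.

The package deliberately *consumes* deconvoluted features rather than
producing them: spectral deconvolution and envelope detection are a
separate, well-served problem. A light `link_envelopes()` helper (merge
per-scan records by charge and 10 ppm mass agreement across adjacent
cycles) is provided as plumbing only.

## The matching model

Everything rests on chromatographic coherence: a fragment produced by a
precursor must co-elute with it.

**Round 1 — apex gate.** A fragment survives only if the distance between
its apex cycle and the SCPF's apex cycle is at most `min(t, ⌊c/2⌋)`,
where `c` is the number of cycles in which the SCPF is observed and
`t = 3` cycles by default. Scaling the gate with `c` keeps it tight for
narrow precursors (a 1-cycle precursor admits only co-apex fragments).
Apex ties break to the earliest cycle so results are reproducible.

**Round 2 — logistic pair score.** Survivors `L` are scored by a logistic
regression on three dimensionless attributes:

* *normalized intensity rank* — the fragment's intensity rank within `L`
  (descending, ties by mass then id) divided by `|L|`; intense fragments
  score near `1/|L|`;
* *normalized cycle number* — fragment observed-cycle count divided by the
  SCPF's `c` (deliberately uncapped: a fragment observed in more cycles
  than its precursor is informative, not an error);
* *shared XIC* — the area under the pointwise minimum of the two
  unit-area elution profiles, in `[0, 1]`.

Fragments scoring above 0.55 are kept; when fewer than 25 pass, the top 25
of `L` by score are kept without filtering. The fallback trades precision
for searchability — a pseudo spectrum with too few fragment masses cannot
be identified at all — and is recorded per spectrum (`fallback` flag).

**Round 3 — mass-group quotas.** The retained list is split at 1500 Da.
The top 25 scorers of the low-mass group and the top `T − 25` of the
high-mass group are reported, where `T = 2(l − 1)` estimates the number of
theoretical terminal fragment masses of a proteoform of length
`l = round(mass / 111.1254)` (the Averagine average residue mass); 25
approximates the number of theoretical terminal fragments below 1500 Da.
For very small precursors `T − 25` is negative; the high quota clamps to 0
and the low quota to `T`, preserving the quota's intent (`l` is also
clamped at 2 so `T ≥ 2`). One retained feature counts as one mass:
features are assumed deduplicated upstream by the feature detector.

**Greedy window loop.** Within a window, SCPFs are processed in decreasing
total intensity (ties by mass ascending, then id); each SCPF's cascade runs
against the *remaining* fragment pool and its retained fragments are
removed before the next SCPF. Fragment re-use across pseudo spectra of a
window is therefore impossible by construction. An SCPF whose round-1 list
is empty emits nothing (logged when `verbose = TRUE`); emitting an empty
block would only burden the downstream search.

### Training the score

Training data come from pairing SCPFs with the round-1 survivors of their
window and labeling each pair positive when the fragment mass matches a
b/y mass of the proteoform identified for that SCPF within 10 ppm (the
same tolerance used for search elsewhere; a fragment may pair with several
SCPFs). The fit is plain maximum-likelihood logistic regression — the
attributes are already normalized ratios, so no standardization or
regularization is applied; a 70:30 random split (seeded, bit-for-bit
reproducible) provides held-out balanced accuracy and ROC-AUC. Aliased
coefficients (a constant attribute in a degenerate training set) are set
to zero rather than propagating `NA` scores.

## Noise filtering

Raw centroided spectra are cleaned before feature work: each spectrum's
noise level `h` is the centre of the modal bin of its intensity histogram,
and peaks below `r·h` are removed (`r1 = 3` for MS1, `r2 = 1` for MS/MS; a
peak exactly at `r·h` is kept, reading "less than" literally). The
histogram rule needs a binning policy: equal-width bins over
`[0, max intensity]`, `max(10, ⌈√n⌉)` bins, modal ties toward the lower
bin, and the centre clamped into `[min, max]` observed intensity so `h` is
attainable (without the clamp a spectrum of identical peaks would get
`h < v`). The noise level computed for a spectrum is cached on it, making
filtering idempotent.

## Numerical choices in the shared XIC

The XIC is a vector sampled at cycle centres; the shared area needs a
continuous profile. Each XIC is interpolated linearly through its support
(first to last nonzero cycle) and ramped to zero over half a cycle beyond
each edge; a single-cycle feature becomes a unit-base triangle. The ramp
is not cosmetic: with a hard discontinuity at the support edge, the area
under the pointwise minimum depends on the integration grid, and no finite
grid agrees with a finer one to 1e-6. With continuous piecewise-linear
profiles, both are integrated on a uniform grid of 100 points per cycle
spanning the union of supports, and the minimum is integrated *exactly*
within each cell by solving for the crossing point of the two linear
pieces. Since every profile breakpoint (integers and half-integers) lies
on the grid, the result is exact up to floating point, and the acceptance
suite verifies agreement with an independent fine-grid trapezoid oracle to
1e-6 over 1000 random pairs.

## The synthetic generator

`simulate_run()` emulates one gas-phase fraction of a TD-DIA experiment:
twenty 4-m/z isolation windows over precursor m/z 720–800, with one MS1
and twenty MS/MS scans per cycle. Proteoforms are random sequences steered
to a target mass (a glycine/alanine tail closes the gap to within ~7 Da)
so their precursor m/z lands mid-window at a sampled charge (9–18).
Elution profiles are Gaussians truncated at 1% of peak height and sampled
at cycle centres; fragment features inherit the precursor profile with
configurable apex jitter (default sd 0.4 cycles) and width variation, and
their intensities decay geometrically along each ion series (ratio 0.95,
25 detectable ions per series, ≥ 200 Da). Decoy fragments (40 per occupied
window) have unrelated elution profiles and masses rejection-sampled at
least 50 ppm from every catalog b/y mass, so pair labels are unambiguous.
A configurable fraction of proteoforms is planted as co-isolated pairs in
a shared window with a minimum apex separation (default 4 cycles). The
cycle count defaults to 60 and the default run holds 20 proteoforms —
sizes chosen so a full simulated experiment fits comfortably in an
interactive session while still exercising every window.

What the generator does *not* emulate — and what passing tests therefore
cannot show about real data: isotope-resolved peak shapes and overlapping
fragment envelopes, charge-state envelope structure, retention-time drift
and tailing peaks, intensity-dependent mass error, and real fragmentation
chemistry (every b/y ion down a geometric ladder, rather than
sequence-dependent cleavage preferences). Results on real runs hinge on
the upstream feature detector's behaviour under those effects.

`simulate_labeled_pairs()` skips the run entirely and draws pair
attributes from class-conditional distributions (positives: high shared
XIC, low rank, cycle ratio near 1; positive prevalence 0.1355, matching
the label mix reported for real training data) — useful for exercising the
model fit at scale.

## Tie-breaking and degenerate inputs

All orderings are total: intensity ties break by mass ascending then
feature id, score ties likewise, apex ties to the earliest cycle. This
makes the greedy loop invariant to input permutations of equally intense
SCPFs, which the suite checks. All-zero XICs are rejected as invalid
features; empty windows, empty survivor lists and empty runs produce empty
(but valid) outputs rather than errors. An envelope split exactly 50/50
between two windows is unassigned — the window rule demands a strict
majority, which also guarantees an SCPF can never sit in two windows.

## Duplicate removal

Identifications within a run are ranked by SCPF intensity; each is removed
if it is a duplicate of *any* better-ranked identification (kept or
removed): same protein and mass difference within 10 ppm of 0 or
±1.00235 Da, the common one-isotope deconvolution error. The ppm bound is
taken relative to the larger mass — the conventional statement of the rule
names no reference mass, and the larger one is the more permissive
symmetric choice. Cross-run
merging concatenates per-run survivors, re-ranks and reapplies the rule.
Note the procedural rule is order-dependent only through the intensity
ranking: a chain `{m − 1.00235, m + 1.00235}` without the centre mass is
*not* a duplicate pair, and both members survive.

## Output

Pseudo spectra serialize as msalign-style text blocks (`BEGIN IONS` /
`END IONS`, precursor mass/charge/intensity headers, one
`mass intensity charge` line per fragment), ordered by precursor intensity
with fragments by mass, so output is deterministic. Because msalign header
requirements vary across search-engine versions, the writer exposes a
`dialect` option (`"minimal"`, `"toppic"` — the latter adds `ID`, `SCANS`,
`ACTIVATION` bookkeeping) instead of hard-coding one set. Fragment
intensities are the fragment features' total intensities and charges the
feature charges; the pseudo spectrum is a feature-level object, not a peak
list.

## Problem sizes used by the test and acceptance suites

Oracle agreement uses 1000 random XIC pairs and 1000 random windows;
greedy invariants are checked over five simulated runs (100 windows);
model recovery uses 10,000 labeled pairs with a 70:30 split; the
end-to-end check demultiplexes 20 windows of co-isolated proteoform pairs
with apex separation ≥ 4 cycles and requires ≥ 80% of each proteoform's
own detectable b/y fragment features and ≤ 20% contamination per emitted
spectrum; dedup correctness is verified on planted duplicate clusters
against a union-find oracle. These sizes are the package's reference
conditions and are reproduced by `scripts/acceptance.R` from a single
seed.

## Known limitations

* Window assignment uses *observed* envelope intensities; whether
  theoretical envelopes would serve better is untested here.
* The score is a three-attribute logistic model; it cannot express
  interactions (e.g. rank mattering less for wide precursors).
* The round-2 fallback deliberately admits low-scoring fragments for
  sparse precursors, trading contamination for identifiability.
* Quota round 3 treats each feature as one mass; if the upstream detector
  emits duplicate masses, the quota is effectively loosened.
* The generator's simplifications listed above mean real-data performance
  must be established with a search engine downstream, which is outside
  this package's scope.
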