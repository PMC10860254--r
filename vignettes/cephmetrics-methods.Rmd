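---
title: "Methods: landmark accuracy, the 22-item analysis, and the device-comparison models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landmark accuracy, the 22-item analysis, and the device-comparison models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cephmetrics)
library(dplyr)
```

## The problem

Cephalometric analysis quantifies skeletal, dental and soft-tissue relations
on a lateral skull radiograph by placing named landmarks and deriving angles,
distances and ratios between them. Landmark localisation is the dominant
error source, and whether the input device (a tablet traced with a finger
versus a desktop with a mouse) degrades localisation is a practical question
for orthodontic education. `cephmetrics` implements the full analysis chain
for such a device-comparison study: ingesting tracing exports, scoring
landmark accuracy against an expert consensus, computing the Münster 22-item
measurement battery, quantifying rater agreement, and fitting the
mixed-effects comparison models — plus a synthetic-study generator so the
entire chain can be exercised and calibrated without access to patient data.

## Coordinate frame and geometry

All coordinates are image pixels in the y-down frame: x increases anteriorly
(the patient faces right), y increases caudally. The bundled consensus
coordinates follow this convention (the nose tip Ap has the largest x,
Menton the largest y). Geometric primitives (`angle_at_vertex()`,
`angle_between_lines()`, `signed_point_line_distance()`,
`line_intersection()`, `construct_xi()`) are deliberately thin wrappers
around exact vector algebra; all angle operations are invariant under rigid
motion and uniform scaling to 1e-9 degrees, which the test suite checks
property-style against independently coded brute-force formulas.

Two sign conventions matter clinically and are fixed throughout:

* *anterior-positive* point-to-line distances are measured against a line
  directed cranial-to-caudal (used for the convexity of point A, incisor
  positions, lip-to-E-line);
* *inferior-positive* distances against a line directed
  posterior-to-anterior (used for the vertical molar distance).

Near-parallel line intersections (|sin| < 1e-9) are an error rather than a
huge coordinate; this only arises for degenerate tracings.

## Constructed landmarks

Gnk (constructed gnathion) is the intersection of the mandibular plane
(hT–Me) and the facial plane (N–Po), solved as a 2×2 linear system. Xi (the
ramus midpoint) is defined here as the centre of the rectangle aligned with
the Frankfurt horizontal (FH, P–Or): its along-FH coordinate is the midpoint
of R1 and R2, its across-FH coordinate the midpoint of R3 and R4. The
textbook wording of the R2/R4 constructions leaves Xi's rule implicit; this
rectangle-centre reconstruction reproduces the bundled consensus Xi to
within 0.2 px (and Gnk to 0.05 px), which we treat as validation of the
reconstruction, not as a quoted definition. Manual placements of Gnk/Xi win
by default (students place them in the study design); `derive_constructed()`
fills in absent ones and reports manual-vs-constructed distances for audit.

## The 22-item measurement battery

The measurement rules (see `measurement_definitions()`) are geometric
reconstructions from the classical analyses the battery descends from
(Downs, Ricketts, Rakosi, Steiner). Each rule was validated by recomputing
the battery from the bundled image-A consensus coordinates: all 13
angle-valued items agree with the consensus measurement means within 0.1°
and all 8 mm-valued items within 0.15 mm once the pixel spacing is
calibrated. Spacing is not part of the landmark export, so
`calibrate_spacing()` inverts any one mm-valued item; anchoring on the
convexity of point A (3.25 mm) gives 0.2043 mm/px for image A, and anchoring
on the relative mandibular length instead agrees within 0.2%, a useful
internal-consistency check.

One item is flagged `reconstructed` rather than `verified`: the
maxillary/mandibular length ratio. The natural rule |Co–Po| / |Co–A| yields
1.159 on the consensus coordinates against a reported mean of 1.17. A
ratio-of-means versus mean-of-ratios discrepancy (per-rater ratios averaged)
would explain the gap, but since that cannot be verified from coordinates
alone the item is flagged and excluded from the fidelity guarantee.

Facial axis uses the obtuse convention (180° minus the acute angle); the
palatal-plane angle is the signed inclination of FH minus that of Spp–Spa,
so a palatal plane sloping caudally-anteriorly relative to FH is negative.
Both conventions reproduce the signs of the consensus values.

## Accuracy metrics

Radial error is the Euclidean distance between a placed landmark and its
reference, converted to mm by the pixel spacing; the mean radial error (MRE)
of a tracing averages its 33 radial errors. The successful detection rate
(SDR) is the percentage of placements with error *strictly below* a
threshold (1/2/4/8 mm; 2 mm is the conventional clinically acceptable
limit). Strictness at the boundary is configurable but immaterial for
continuous errors. Per-landmark confidence intervals use the normal
approximation mean ± 1.96·SD/√n, matching two-decimal reporting; the CI
method of the emulated study is not documented, and we chose the simplest
defensible one.

## Interrater reliability

Reference coordinates are the arithmetic mean of six expert tracings, and
their agreement is quantified by ICC(A,k) — the two-way absolute-agreement
intraclass correlation for averaged ratings in the McGraw–Wong taxonomy:

ICC(A,k) = (MSR − MSE) / (MSR + (MSC − MSE)/n),

with MSR/MSC/MSE the between-target, between-rater and residual mean squares
of the two-way ANOVA. Bands follow Koo–Li (poor < 0.5, moderate < 0.75,
good < 0.9, excellent above). Negative estimates are reported, not truncated.
For per-landmark reliability the ratings matrix pools the image-by-axis
coordinate values as targets (2 images × 2 axes = 4 targets by default),
because one ICC per landmark spanning both images is what the emulated study
reports; a `per_axis` mode keeps x and y separate for users who prefer the
other interpretation — the pooled construction is a design choice, not a
documented fact about the original analysis.

## Mixed models and selection

Per-tracing MRE and tracing time are modelled as
`response ~ fixed effects + (1 | subject)`. Candidate fixed effects are
device, image, gender and analysis order; all fits used for testing are ML,
not REML, because likelihood-ratio tests of fixed effects are only valid
under ML (REML is available for final reporting). Selection is two-stage:
each effect is screened singly against the intercept-only model by LRT at
α = 0.05; screened-in effects are then added in ascending order of stage-1
p-value (ties alphabetical), each kept only if its incremental LRT is
significant. The insertion order is our choice where the emulated procedure
("increasing number of significant effects") is ambiguous. Wald 95%
intervals match the symmetric intervals the study design reports.
Singular fits (e.g. zero subject variance) are flagged, not errors; in the
one-record-per-subject limit the fit collapses to least squares.

Calibration is checked by simulation in the test suite: the device-effect
LRT holds its nominal size under the null at the study's exact design size
(161 subjects, 277 records), and across 50 regenerated studies the image,
gender and order effects are recovered without detectable bias, with the
selection procedure finding exactly the generating effect sets in at least
80% of runs.

## The synthetic-study generator

`simulate_study()` emulates the cohort the pipeline was built for, and its
defaults *are* those study conditions: 161 students (108 female), 116 of
whom trace both cephalograms — one per device, with the image-device pairing
alternating across the cohort as it was switched semester-wise — giving 277
tracings; per-landmark placement noise calibrated so expected radial errors
match the cohort norms (`cohort_accuracy()`); fixed effects of +0.21 mm for
image B and −0.24 mm for male students on MRE; tracing times with a
23.79-minute first-analysis mean and a −11.72-minute second-analysis
learning effect.

Placement noise is bivariate normal. Isotropic noise with per-axis SD σ has
Rayleigh-distributed radial error with mean σ√(π/2); per-landmark σ are
obtained by inverting this from the target means. Anisotropy (an SD ratio
with a major-axis orientation, natural for landmarks on gradually curved
edges such as R1/R3/R4/Ba/Co/P, whose error ellipses stretch along the
edge) is opt-in, since the cohort norms report only means and SDs, not
covariances; the general radial-error mean uses the complete elliptic
integral of the second kind, evaluated by quadrature.

A tracing's expected MRE is shifted additively by the fixed effects, the
subject intercept and a residual draw, implemented by scaling the
per-landmark mean profile multiplicatively; the baseline profile is centred
so the *marginal* expected MRE equals the configured per-landmark means
despite the shifts. The configured residual SD is on the *response* scale:
averaging 33 radial draws already contributes about 0.23 mm of sampling
noise, so the generator sizes its explicit residual component as the
root-difference, and a mixed model fitted to the simulated records
estimates a residual near the configured value rather than an inflated one
(an early version added the two, which measurably deflated the power of the
gender contrast and attenuated nothing else; the calibration suite caught
it).

Unreported nuisance parameters were fixed once at plausible values and
exposed in the configuration, with no claim of fidelity: subject-intercept
SD 0.3 mm and residual SD 0.4 mm (these reproduce the order of magnitude of
the reported standard errors), time subject SD 3 min and residual SD 4 min,
times floored at 1 minute. The time SDs are deliberately small enough that
the floor is hit in under 2% of draws — a floored normal with a heavy lower
tail truncates second analyses asymmetrically and would bias the recovered
learning effect toward zero, breaking the generator's additive-truth
contract (the calibration suite also caught this). A lognormal option
exists; the emulated study reports only medians/IQRs, which a floored
normal does not attempt to match — in particular the simulated median
tracing time is *not* calibrated. The image-B pixel spacing is an arbitrary
fixed 0.125 mm/px: errors are generated in mm, so every downstream
mm-valued result is independent of this choice.

What the generator does *not* emulate: heavy-tailed placement blunders
(real per-landmark SDs are often as large as the means, which Rayleigh noise
cannot produce — simulated SDRs are therefore systematically different from
the cohort's even though MREs match), between-landmark error correlation
within a tracing, and drop-out structure beyond the both/single split.
Passing closure tests therefore validates the pipeline's bookkeeping and the
estimators' calibration, not distributional realism of student behaviour.

With `include_rejects = TRUE` the generator appends the excludable tracings
the ingestion rules must catch — 16 wrong-cephalogram, 5 screenshot, 3
missing-landmark and 2 invalid files — so exclusion accounting can be tested
end to end (303 raw files, 277 included, 9141 landmarks).

## Submission format and pseudonymisation

The tracing application's export schema is not published; the package
defines one (shipped as `inst/extdata/submission-schema.json`): metadata
keys, ISO-8601 UTC timestamps of the first and last placement, and a
landmark array of `{name, x, y}`. Serialisation is full-precision, so
write-then-parse is the identity, and a fixed seed regenerates a study byte
for byte. Pseudonyms are SHA3-256(name + salt) digests ranked
lexicographically and formatted as zero-padded 1-based integers: equal names
map to equal pseudonyms, the mapping is deterministic per salt, and raw
names never appear downstream. Duplicate submissions (same subject, image
and device) keep the earliest first-placement timestamp by default
(configurable); the emulated study does not state its tie-break.

## Problem sizes and numerical choices

The test-suite simulations use the study's own design size where the
property being checked depends on it (size of the LRT: 500 null replicates
at 161/277; recovery and selection consistency: 50 regenerated studies) and
smaller cohorts elsewhere, chosen as the smallest sizes at which the checked
property is stable. Monte-Carlo assertions use fixed seeds and tolerances
derived from the corresponding closed forms (Rayleigh moments, binomial
SEs), never tuned constants. Degenerate inputs are defined errors: empty
error vectors, matrices with zero total variance (ICC undefined, reported
`NA`), reversed timestamps, near-parallel intersections, zero-length angle
arms.

## Known limitations

* The measurement rules are validated against a single image's consensus
  recomputation; image B's consensus measurements are not reproduced by
  construction from its coordinates and were not used for validation.
* The ratio item is a reconstruction (above).
* ICC confidence intervals and F-tests are out of scope.
* The generator's Gaussian effect structure and Rayleigh radial errors are
  modelling assumptions recorded in the configuration, not estimates.
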