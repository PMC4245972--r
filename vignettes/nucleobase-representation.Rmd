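---
title: "The nucleobase-bead representation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The nucleobase-bead representation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebase)
```

# The model

`ebase` treats a nucleic-acid structure as a set of oriented beads, one per
nucleotide.  The bead of a base is the centroid of the three alternate
atoms C2, C4 and C6 of its six-membered ring, together with an orthonormal
frame: x from the centroid toward C2, z normal to the ring plane, y
completing a right-handed system.  Only these three atoms are required per
base, so the representation applies uniformly to RNA and DNA, to purines
and pyrimidines, and degrades gracefully on incomplete residues (residues
missing any ring atom are skipped at parse time).

Two conventions deserve comment because the underlying geometry fixes them
only up to a sign:

* **Ring-normal orientation.**  The normal is the cross product of the
  ordered atom pairs (C2, C4) for pyrimidines and (C2, C6) for purines
  (vectors taken from the centroid).  This particular pairing makes the
  Watson-Crick edge of *both* base classes fall at similar positive in-plane
  angles, so that vectors collected from purine and pyrimidine observers can
  be pooled into one distribution.  The test suite pins this property: for
  an ideal Watson-Crick pair, both orderings of the pair vector land in the
  same angular sector (theta near 60 degrees).
* **Indexing.**  Nucleotides are indexed 1..N in file order (R convention);
  author numbering (chain, residue number, insertion code) is preserved
  separately and used in all reporting output.

The position of base k in the frame of base j is the pair vector r_jk
(Angstrom), reported in cylindrical coordinates rho, theta, z.  Pairing
anisotropy is encoded by the ellipsoidal scaling r̃ = (r_x/a, r_y/a, r_z/b).

# Parameters

| parameter | default | units | role |
|---|---|---|---|
| a | 5.0 | Å | in-plane semi-axis of the ellipsoidal scaling |
| b | 3.0 | Å | normal semi-axis |
| shellMax | sqrt(2.5) ≈ 1.581 | scaled | outer shell radius: essentially all pairing/stacking contacts fall inside |
| shellMin | 1.0 | scaled | inner shell radius (steric exclusion); reporting only |
| zSplit | 2.0 | Å | \|z\| boundary between pairing and stacking zones |
| rCutoff | 2.4 | scaled | cutoff of the smooth G mapping; γ = π/rCutoff |
| bandwidth | 0.25 | Å | kernel width of the scoring density |

These defaults are the calibration constants of the representation and are
exposed through `scalingParams()` mainly for sensitivity analysis, not for
routine adjustment.  The edge sectors within the pairing zone are softer
choices: the sugar span (190°–290°) reflects the region sterically occupied
by the sugar, and the Watson-Crick peak sits near 60°; the default sector
bounds (WC 30°–100°, Hoogsteen 100°–190°, sugar 190°–290°) are configurable
because only the sugar span and the WC peak position are sharply determined
by the geometry.  `shellMin` is deliberately *not* applied when enumerating
pairs for scoring and deviation: the scoring density and the G mapping are
defined by their own cutoffs, and an inner bound would discard genuinely
observed close contacts from training.

# Scoring

`fitScoreModel()` collects the unscaled pair vectors r of all *ordered*
shell pairs — both orderings of a pair are two partially independent
observations — and `evaluateDensity()` averages isotropic Gaussian kernels
of width `bandwidth` over them.  Two deliberately documented choices:

* **Normalization.**  p(r) is a true density (kernels normalized,
  average taken).  Any positive rescaling of p leaves all rankings
  unchanged, so normalization is a matter of interpretability; the density
  form lets users compare values across models with different training-set
  sizes.
* **Inclusion rule.**  A vector r_jk enters training when its own scaled
  norm is below `shellMax` (one-sided rule).  Requiring mutual shell
  membership — the convention used when *counting* annotated pairs — is
  available via `mutual = TRUE`; on idealized fixtures the two rules give
  nearly identical models.

The structure score `eScore()` is the **sum** of densities over ordered
pairs, not a product/log-likelihood: summation damps the influence of
low-count regions, where a product would let one unusual (but real) contact
veto an otherwise native-like conformation.  Pairs beyond
`shellMax + 3·bandwidth/min(a, b)` in scaled norm are skipped; their kernel
contribution is below e^{-4.5} of the peak and this keeps the score exactly
additive over far-separated substructures.  `rankDecoys()` reports the
normalized rank — the fraction of decoys scoring strictly above the native;
ties do not count as better, so a duplicate of the native cannot hurt it.

# Deviation metrics

The naive pair-vector distance d (no cutoff) is exact but non-local: a
single far-away base changes it arbitrarily.  The G mapping restores
locality without introducing discontinuities:

* G(r̃) = 0 identically for r̃ ≥ rCutoff, and |G| → 0 continuously at the
  cutoff (tested to 1e-6);
* |G(r̃ᵅ) − G(r̃ᵝ)| ≈ |r̃ᵅ − r̃ᵝ| for small vectors (within 10 % below
  r̃ = 0.5);
* |G| ≤ 2/γ everywhere.

At the origin the direction of r̃ is undefined; the sine factor vanishes
there, so the implementation maps the direction term to zero and the fourth
component carries the value 2/γ — G is continuous at the origin too.

`eRMSD()` normalizes the summed squared G differences by the number of
nucleotides N, not by the number of pairs.  With the per-nucleotide
normalization the values land on an O(1) scale where experience places
near-native structures below ≈0.8 and clearly non-native ones above ≈1,
and the metric grows (rather than dilutes) with the number of disrupted
interactions.  Correspondence between structures is strictly positional;
no alignment or gap handling is attempted.

The baselines: `atomRMSD()` superposes by least squares with a proper
rotation only (a mirror image never superposes to zero); `dRMSD()` uses
the ring-centroid beads by default so that all metrics live on the same
representation (heavy-atom dRMSD via `selection = "heavy"`); `infScore()`
compares annotated interaction sets, where an interaction is identified by
its unordered pair and zone — edge sectors are deliberately ignored because
the internal sector bounds are approximate.

## Kinetic-proximity analysis

`cvCurve()` computes, for each time lag τ, the deviation d between all
frame pairs (t, t+τ) and reports CV(τ) = σ_d/⟨d⟩.  The per-pair series at
fixed lag is strongly autocorrelated, so naive standard errors would be
optimistic; errors come from a Flyvbjerg–Petersen block-doubling analysis,
read off at the largest blocking level that still retains at least 8
blocks.  The error of the CV combines the blocking errors of the mean and
of the variance by first-order propagation, neglecting their covariance.
When the mean distance is zero (identical frames) the CV is reported as 0
rather than NaN.

# Motif search

A query is segmented at chain boundaries and at backbone gaps (consecutive
ring centroids above 12 Å apart, about twice the consecutive-centroid
distance in a helix); each segment must have at least two nucleotides.
Candidate windows matching each segment length slide over the target's own
segments; with `maxBulges = 1` windows one nucleotide longer are also tried
with each *internal* nucleotide deleted, which recovers copies of the motif
interrupted by a bulged base (the deleted position is reported).  For
multi-segment queries, ordered non-overlapping window combinations are
enumerated, with a configurable cap (default 1e5, breaches warned) to bound
the worst case.

Deduplication keeps the lowest-eRMSD variant among matches sharing more
than half their nucleotides, and runs *before* thresholding, so the match
set at threshold t1 is always a subset of the match set at t2 > t1 — a
property the tests assert.  The default reporting threshold of 0.7 sits
between the near-native (<0.8) and non-native (>1) eRMSD ranges; both the
threshold and the single-bulge default are approximations of the original
search protocol, whose exact cutoffs are not published, and are exposed as
arguments.

# The fixture generators

`makeAformDuplex()` places idealized per-nucleotide heavy-atom templates on
an ideal A-form helix.  The templates (shipped as
`inst/extdata/nucleotide_templates.csv`, plain text) contain Chemical
Component Dictionary idealized monomer geometry expressed in the standard
Watson-Crick pair reference frame, with the glycosidic torsion set to the
A-form anti value; the strand-II partner of a base is the (x, −y, −z) flip
of its complement's template.  Helix parameters default to standard fiber
values — twist 32.7°/step, rise 2.81 Å/step — plus typical A-RNA placement
(x-displacement −4.4 Å, inclination +15°).  Construction self-checks that
every Watson-Crick partner annotates as PAIRING and every sequential
intra-strand neighbour as STACKING.

What the fixtures emulate: exact Watson-Crick geometry (partner beads at
ρ ≈ 5.7 Å, θ ≈ 60°, |z| ≈ 0 — the canonical peak), helical stacking,
register-shifted mispairing, Gaussian coordinate noise
(`perturbStructure`), and diffusive drift (`makeTrajectory`, a seeded
random walk in conformation space).  What they do not emulate: sequence-
dependent geometry, non-canonical pairs (Hoogsteen/sugar-edge contacts,
wobble), realistic backbone conformational ensembles (the idealized ribose
is O4'-endo, which places the phosphate somewhat further from the helix
axis than fiber A-RNA), loops and junctions, and any physically realistic
dynamics — the random walk has no restoring force or barrier structure.
Passing tests therefore demonstrate the correctness and the stated
invariances of the computations, and the qualitative behaviours (register
shifts scored as large interaction changes, noise degrading scores
monotonically), but not predictive performance on experimental ensembles;
for that the scoring model should be trained on a large curated structure
(e.g. a ribosomal subunit) via `ebase train`, and the analyses rerun on
real data.

All generators are deterministic given their arguments and seed, and leave
the global RNG state untouched.

# Numerical choices and degenerate inputs

* Ring atoms closer than 1e-3 Å² of triangle area are rejected as
  degenerate (collinear) rather than producing an arbitrary frame.
* When the two orderings of a pair disagree about the |z| zone boundary,
  the ordering with the smaller scaled norm decides — the closer view is
  the better-defined one, and the choice is deterministic.
* theta is the two-argument arctangent of (r_y, r_x), reported in degrees
  in [0, 360).
* Structures with a single nucleotide score 0 and have empty pair
  enumerations; empty reference annotations make INF an error (undefined)
  rather than silently 0.
* Score models serialize to JSON with 17 significant digits, so a reloaded
  model reproduces densities bit-for-bit.
* PDB output carries the format's 1e-3 Å precision; round-trip tests are
  asserted at that tolerance.

# Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated
fixtures: duplexes of 2–6 base pairs, decoy ensembles of 100–200 structures
per condition, and trajectories of 25–50 frames.  These sizes were chosen
as the smallest that make the statistical assertions stable (e.g. the
scalar/vector metric correlation over 200 perturbed 12-mers, or the 95/100
native-recognition count); all analyses scale to structures of hundreds of
nucleotides, where the quadratic pair enumeration remains modest.

# Known limitations

* The eRMSD requires positional correspondence; molecules of different
  lengths must be pre-aligned by the user (the motif search is the
  exception, handling bulges explicitly).
* The internal annotator classifies geometry only; it does not reproduce
  full annotation taxonomies (cis/trans Leontis–Westhof families,
  base-sugar or base-phosphate contacts).
* Edge-sector assignment is approximate away from the canonical WC peak.
* The scoring function is sequence-independent by construction; pairs that
  are geometrically canonical but chemically impossible are not penalized.
* mmCIF files are read but not written.
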