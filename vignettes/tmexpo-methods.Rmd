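---
title: "Measuring and predicting transmembrane helix rotational angles from lipid exposure"
author: "tmexpo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and predicting transmembrane helix rotational angles from lipid exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmexpo)
```

## The model

A transmembrane helix (TMH) buries one face against the protein core
and exposes the other to the lipids. `tmexpo` works with two coupled
descriptions of that asymmetry:

1. **Lipid exposure**: per-residue relative accessible surface area
   (rASA) in the lipid environment, computed with a 2.0 Å probe —
   roughly a –CH₂ group of a hydrocarbon tail rather than a water
   molecule — and normalised by the residue's reference area in an
   extended Gly-X-Gly tripeptide. rASA < 5% defines a buried residue;
   the threshold follows the classical burial convention and the strict
   inequality means a residue exactly at 5% counts as exposed.

2. **Rotational angle**: the clockwise angle, viewed down the helix
   axis from the N-terminal side, from the first TM residue's Cα vector
   to the lipid-facing direction (the outward vector from the molecular
   centre through the helix centre), in [0°, 360°).

The bridge between them is the **rASA moment**. An ideal α-helix
advances 100° per residue around the helical wheel, so residue *i* sits
at θᵢ = (i − 1)·100°. Summing the per-residue scores as 2-D vectors,

$$x = \sum_i s_i \cos\theta_i,\qquad y = \sum_i s_i \sin\theta_i,$$

gives a moment whose direction (γ = arccos(x/|M|); θ = γ if y ≥ 0,
else 360° − γ) points toward the most exposed face. With observed or
predicted rASA as the scores, θ is the predicted rotational angle. The
moment length |M| measures how anisotropic the exposure is: a helix
buried all round (or exposed all round) has |M| ≈ 0 and no meaningful
direction, which the package reports as an undefined direction (NA with
a warning in pipelines, an error from the low-level accessor) rather
than a fabricated 0°.

### Assumptions

* The 100°-per-residue wheel assumes a regular α-helix. Kinked,
  disrupted or reentrant segments break the periodicity; for these the
  moment direction degrades gracefully rather than being specially
  handled (no kink splitting — a single axis is fitted per helix).
* The lipid-facing direction assumes the helix is on the protein
  perimeter. The molecular centre is defined from the TM-segment Cα
  atoms of the *chain unit* only; a flag for whole-complex centres is
  deliberately not provided because subunit context changes what
  "lipid-facing" means for interface helices — those residues are
  excluded from training instead.

## Angle measurement details

**Principal axis.** The axis is the null direction of the scatter of
second differences of consecutive Cα positions. For any ideal helix the
second differences point exactly radially, so this estimator recovers
the construction axis to machine precision regardless of helix length,
where the naive largest-variance direction of the Cα cloud is tilted by
~2° for an 18-residue helix (the circular component does not average
out over partial turns). Near-collinear traces, where curvature carries
no signal, fall back to the dominant cloud direction. The sign always
points N→C (the N-terminal half centroid to C-terminal half centroid
decides).

**Handedness.** The top-view frame (u, v, axis) is right-handed with
the axis pointing N→C, so increasing atan2(v, u) is *clockwise as seen
from the N-terminal side* — the same sense in which the wheel advances
+100°/residue. A cross-module test pins this convention: a helix built
so that only residue *i* faces the lipids must yield the same angle
from the geometry path (structure → axis → projection → angle) and from
the moment path (delta profile at *i* → θ = (i − 1)·100°).

**First residue.** The first annotated TM residue possessing a Cα; a
fallback is recorded in the output when the annotated first residue is
missing.

## Surface area details

ASA uses deterministic dot-sphere (Shrake–Rupley style) sampling: a
Fibonacci spiral of `n_points` (default 960) on each atom's expanded
sphere (van der Waals radius + probe), with points tested against
neighbouring expanded spheres. The estimator is exact for an isolated
atom and converges as the point set grows; at the default density,
doubling `n_points` moves no per-residue area on the bundled fixtures
by more than 2%. Radii follow the NACCESS/Chothia convention from an
editable table (element defaults plus atom-name overrides); hydrogens
are ignored, alternate locations resolve to the highest-occupancy
conformer, and HETATM groups are excluded by default (configurable).
This is a self-contained reimplementation verified by analytic and
invariance properties, not a bit-exact replica of any particular
slicing implementation.

The interface-exclusion rule compares each residue's rASA computed from
its subunit alone and from the whole complex; a difference above 1e-3
(a tolerance needed because the two values are floating-point area
sums; small enough to catch any real contact) or any missing atom
excludes the residue from training and evaluation. On multimeric
fixtures the subunit value is never smaller than the complex value — a
property test, since occlusion can only remove surface.

## Feature encoding

Each residue is encoded over a sliding window of 17 positions, 28
features per position (476 total), all in [0, 1]:

* 20 PSSM log-odds squashed by 1 − 1/(1 + e^(−v));
* one Jensen–Shannon conservation score (log₂, raw — no windowing, no
  Z-transform) against a BLOSUM-style background (configurable; the
  background choice was open and frequencies are the standard ones);
* volume / 237.2, polarity sigmoid, charge class (1 / 0.5 / 0),
  contact propensity / 1.43, insertion-energy sigmoid, amphiphilicity
  sigmoid with the *positive* sign in the exponent (its printed
  convention), turn propensity / 2.7.

Window positions beyond the chain are padded with 0.5 (sigmoid-neutral)
except charge, contact propensity and volume, which get 0. The layout
order is a package choice, so vectors carry a `schema_version` and
models refuse vectors from a different layout. The three anchors
(237.2 = Tyr volume, 1.43 = Cys contact, 2.7 = Pro turn) are asserted
when the property table loads. The bundled property table is a
constructed stand-in (labelled synthetic in the file) because the
original numeric tables are not redistributable here; the insertion
energies are the published Hessa values and the Eisenberg consensus
hydrophobicity scale is bundled verbatim. Conservation is computed per
window position (17 values), the more informative of the two readings
of a per-window score.

## Models

Burial classification uses a C-SVC (RBF, cost 2¹, γ 2⁻⁴); rASA
regression uses an ε-SVR (RBF, cost 2⁻¹, γ 2⁻⁵, loss width 10⁻³,
termination tolerance 10⁻²) — LIBSVM via `e1071`, with `scale = FALSE`
since the encoder already delivers [0, 1] features. Regressor outputs
are clamped to [0, 1]. No class weighting is applied and only decision
values are used. Cross-validation is chain-wise leave-one-out: each
fold holds out every residue of one chain, and the fold loop asserts
programmatically that held-out indices never reach the training set.

## Synthetic fixtures

The generator builds what the measurement model assumes, so that every
stage has a planted ground truth:

* `idealHelix` / `helixBundle`: canonical Cα geometry (rise 1.5 Å,
  twist 100°, radius 2.3 Å) with a crude deterministic backbone (N, C,
  O, CB; CB pointing radially outward) sufficient for PDB round-trips
  and completeness checks. Bundle truth angles come from the analytic
  construction, not from the code path under test.
* `periodicRasa`: baseline + amplitude · cos(θᵢ − φ) (defaults 0.25 ±
  0.25, spanning buried-to-exposed like a perimeter helix), optional
  clamped Gaussian noise. For n a multiple of 18 the noiseless moment
  direction equals φ exactly.
* `synthTrainingSet`: per-chain exposure wheels with random phases;
  the first three features are smooth functions of the target, the rest
  uniform noise.

What these fixtures do *not* emulate: real side-chain packing, kinks,
tilt, sequence-dependent exposure, or the noise structure of real
surface areas. Passing tests therefore demonstrate the correctness of
the implemented operations and conventions, not field accuracy on real
membrane proteins — the bundled 73-helix benchmark of published angle
pairs anchors the evaluation metrics to real numbers instead.

## Numerical choices

* Undefined moment direction below |M| = 10⁻⁹ (the direction formula
  divides by |M|).
* Degrees everywhere; radian conversion isolated in two helpers.
* Error-distribution counts at printed thresholds use a 10⁻⁹ degree
  guard so a pair equal to a threshold up to round-off lands on the
  inclusive side ("at least 100.29°" is read inclusively — the
  alternative strict reading would count five, not six, of the
  benchmark helices).
* Burial at exactly the threshold is exposed (strict `<`).
* Altloc ties resolve to the first conformer encountered.
* The outlier/ramp post-processing hook on moment profiles defaults to
  the identity; no published formulas exist for it, so the default
  pipeline is the plain moment.
* Report display rounds half-up to 2 decimals; internals keep full
  precision.

## Problem sizes

Tests and the acceptance script run on deliberately small instances:
bundles of 2–4 helices of 10–20 residues, surface sampling at 240–1920
points, training sets of 3–5 chains × 36–90 residues, 1000-profile
moment-oracle sweeps. These sizes exercise every code path and
invariant; the algorithms scale to real chains (hundreds of residues,
thousands of atoms) with the same code.

## Known limitations

* Kinked or strongly curved helices get a single global axis; their
  angles are less meaningful (consistent with the degraded accuracy
  reported for such helices wherever moment methods are used).
* The SASA sampler trades bit-compatibility with legacy slicing codes
  for determinism and self-containment; absolute areas differ by small
  sampling-dependent amounts.
* The bundled property table is a labelled synthetic stand-in; users
  with access to the original scales should drop in their own TSV.
* mmCIF input, biological-assembly reconstruction and automatic
  TM-segment annotation are out of scope; annotations arrive as a TSV.
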