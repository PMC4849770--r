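---
title: "Methods: comparing p-HLA and p-HLA-TCR ensemble dynamics"
author: "phladyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing p-HLA and p-HLA-TCR ensemble dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phladyn)
```

## The problem

Class-I MHC (HLA) molecules present short peptides to T-cell receptors.
Altered peptide ligands differing by a single residue can abolish the T-cell
response even though the crystal structures of the corresponding
peptide-HLA-TCR complexes are nearly superimposable. The working hypothesis
behind this package is that the discriminating signal is dynamic rather than
static: reactive complexes maintain a richer network of surface salt
bridges, pay a different conformational-entropy price on TCR binding, and
show distinct per-residue fluctuation patterns. `phladyn` provides the
analysis layer for that comparison: given conformational ensembles of the
free molecules, the binary (peptide-HLA) and the ternary (peptide-HLA-TCR)
complexes, it computes the geometric, fluctuational, electrostatic-contact
and entropic descriptors and compares them across species.

The package analyses ensembles; it does not produce them. Inputs are
multi-model PDB files (one MODEL per frame) or DCD trajectories paired with
a PDB topology, read through `bio3d`. For validation it ships a synthetic
generator whose ground truth is known in closed form.

## Stability descriptors

**RMSD series.** Every frame is superposed (Kabsch, proper rotation
enforced via the SVD determinant correction) on a fit selection — by
default the main-chain atoms N, CA, C, O — and the RMSD to a reference
structure is measured on a selection of choice. The *drift* is the
ordinary-least-squares slope of RMSD against time, converted from Å/ps to
pm·ns⁻¹ (×10⁵); a drift compatible with zero over the run is the usual
stationarity check. The slope's standard error is reported so that the
"drift ≠ 0" question is a t-test, not a judgement call.

**Radius of gyration.** R_G = √(Σ mᵢ|rᵢ − r_CoM|²/Σ mᵢ) per frame, with
mean and standard error over the series. R_G rises when a complex
dissociates or a chain unfolds, so a flat series at the expected value
(≈17 Å for a binary head domain, ≈30 Å for a ternary complex at full
scale) indicates the peptide stayed in its groove.

**Principal-axis projections.** The inertia tensor of a body selection is
diagonalised per frame; the probe (peptide) centre of mass is expressed in
that frame. Eigenvector signs are arbitrary, so axes 1–2 are anchored, per
frame, to give non-negative projections of the CoM offset, and the third
axis completes a right-handed system. This per-frame anchoring makes the
trace exactly invariant under arbitrary global rigid motions (verified to
1e-8 Å in the tests); the price is a possible sign flip if the probe
crosses a principal plane, which does not occur for a peptide held in its
groove. The long (smallest-moment) axis is the third local coordinate, and
its orientation — hence the sign of displacements along it — is fixed only
up to handedness.

## Fluctuation profiles and their comparison

The average structure is computed by iterative superposition (fit all
frames to a running mean, re-average, stop when the mean moves < 1e-6 Å
RMS; ≤ 10 iterations — two or three suffice for harmonic ensembles).
Per-atom RMSF is √⟨|rᵢ − ⟨rᵢ⟩|²⟩ over frames fitted to that average.
Residues aggregate their scope atoms (backbone or all) by a mass-weighted
mean, consistent with the mass weighting used for the entropy covariance;
the aggregation convention matters only at the ~1% level for backbone
scopes but is stated here because profiles are compared across species.

Profiles over identical residue sets are compared by a two-sided t-test
across residues, paired by residue by default (the Welch unpaired variant
is available by flag, since the pairing assumption is a modelling choice).
A difference profile `a − b` follows the convention that positive values
mean greater mobility in `a`. A zero-variance difference (self-comparison)
yields `p = NaN` with a degenerate flag rather than a spurious verdict.
The type-I error of the paired test at α = 0.05 is verified by simulation
(1000 null replicates; the rejection rate must sit inside the binomial 99%
band [0.036, 0.065]).

## Salt-bridge networks

Charged groups default to Asp{OD1,OD2}/Glu{OE1,OE2} (acidic) versus
Lys{NZ}/Arg{NE,NH1,NH2} (basic). Histidine and terminal amino/carboxylate
groups are excluded by default — interface bridges in these systems are
dominated by Asp/Glu–Lys/Arg contacts — but the catalog is an argument, not
a constant.

Detection and counting are deliberately two passes with different
thresholds:

* **detection** (default 8 Å): a pair is a *candidate* if its minimum O–N
  member-atom distance comes within the cutoff in at least one frame;
* **counting** (default 3.2 Å, occupancy ≥ 0.5): a candidate *counts* as a
  salt bridge if the formed-contact criterion holds in at least half the
  frames. Both thresholds are configuration values.

The pair distance is the per-frame minimum over all member-atom
combinations, which is symmetric in the two guanidinium NH nitrogens of
arginine and is the standard operational convention.

The network is summarised as a weighted adjacency matrix over acidic (rows)
× basic (columns) residues with aᵢⱼ = (1/T)Σₜ 1/dᵢⱼ(t) in Å⁻¹ — the
electrostatic pair energy scales as 1/d, so these weights rank bridges by
interaction strength. A fully formed tight contact (~2.8–2.9 Å) weighs
≈ 0.35 Å⁻¹, which is the natural grey-scale cap for plotting; the optional
normalization divides by 1/2.8 Å⁻¹ (configurable) and records the constant.

**Pattern comparison.** The Frobenius inner product Tr(A·Bᵀ) = Σaᵢⱼbᵢⱼ is
exposed as-is, but it is a similarity, not a distance — it is large for
identical patterns. To obtain a dissimilarity with a zero diagonal and a
bounded scale, each matrix is normalized to unit Frobenius norm (zero
matrices stay zero, flagged degenerate) and the distance is
d(A,B) = ‖Â − B̂‖_F = √(2 − 2⟨Â,B̂⟩). This construction is
scale-invariant — patterns are compared by shape, not magnitude — bounded
by √2 for disjoint supports, and satisfies the metric axioms (verified on
1000 random triples). Matrices over different bridge sets are first aligned
on the union label set with zero padding, in deterministic chain/residue
order. Intermolecular submatrices zero every entry that does not span the
presenter/peptide side and the receptor side of the interface, using the
chain-role map of the topology.

## Quasi-harmonic entropy and the binding cycle

The mass-weighted covariance C = ⟨Δq Δqᵀ⟩ with q = √mᵢ·rᵢ is accumulated
(population normalisation, 1/T) after superposing frames on the fitted
average; superposition removes most of the six rigid-body degrees of
freedom, and the spectrum therefore drops the six smallest eigenvalues by
default plus anything below 1e-8 amu·Å² (both arguments). For benchmark
covariances built without fitting, `n_drop = 0` keeps all modes.

Each retained eigenvalue λᵢ (amu·Å²) defines an effective oscillator
ωᵢ = √(k_BT/λᵢ), and the entropy is the quantum harmonic-oscillator sum

S = k_B Σᵢ [ (ħωᵢ/k_BT)/(e^{ħωᵢ/k_BT} − 1) − ln(1 − e^{−ħωᵢ/k_BT}) ],

the standard quasi-harmonic estimator of MD analysis suites. It is
evaluated overflow-safely (a mode with ħω/k_BT > 700 contributes exactly
zero — quantum freeze-out), is additive over independent blocks, and is
strictly increasing in every eigenvalue. Physical constants are CODATA
2018; the unit chain (amu·Å² → kg·m², J → kJ/mol via Avogadro) is
documented in the source. The result is reported as −T·S in kJ/mol, the
sign convention of binding tables, with the temperature (default 298 K, an
argument everywhere) carried along and checked for consistency across
cycle inputs.

The binding cycle is pure arithmetic:
−TΔS_binding = −TΔS_ternary − (−TΔS_freeReceptor) − (−TΔS_binary), with
ΔΔ values relative to a reference species. Absolute single-species
quasi-harmonic entropies converge slowly with sampling and are not
comparable across codes; the cycle and ΔΔ arithmetic, however, is exact
given the per-species inputs, and that is what the acceptance suite pins
down (to 0.02 kJ/mol, the rounding of two-decimal inputs).

## The synthetic generator

The generator emulates exactly the statistical structure the analyses
assume, and nothing more:

* per-atom isotropic Gaussian displacements around a fixed mean structure,
  with per-residue amplitude σ (a number, a per-chain map, or a per-residue
  table) — so per-residue RMSF has the closed form √3·σ;
* scheduled two-state salt bridges: the basic group's member atoms are
  placed along the inter-group axis so the minimum O–N distance follows a
  formed/broken schedule (block pattern: the first round(f·T) frames are
  formed, realising the fraction exactly; Bernoulli pattern: seeded draws),
  optionally with Gaussian jitter along the axis. Moving only the basic
  member atoms keeps the schedule exactly realisable without a constraint
  solver; the acidic group stays harmonic. Closed forms: occupancy = f,
  adjacency weight = f/d_formed + (1−f)/d_broken;
* a miniature three-chain topology (presenter groove of two rails, peptide
  between them, receptor stacked above with sidechains facing down) with a
  seeded subset of residues assigned charged types cycling Asp, Lys, Glu,
  Arg.

The harmonic-noise and schedule random streams are seeded independently
(the schedule stream at seed + 10007), so altering schedules leaves the
harmonic displacements bit-identical; generation is fully reproducible per
seed.

What the generator does *not* emulate — and what passing tests therefore do
not show about real trajectories: anharmonicity and multi-well landscapes,
temporal autocorrelation (frames are independent draws), correlated motions
between residues, solvent and electrostatics, and bonded geometry (atoms
jitter independently). Conclusions about real MD data rest on the
correctness of the estimators, which is what the oracles establish, not on
the realism of the toy ensembles.

## Numerical choices and degenerate inputs

* Coordinates are Å, masses amu throughout; atom indexing is 1-based; the
  source residue numbering is preserved for reporting (bridge labels such
  as `ASP61.A` use author numbering).
* Kabsch superposition is unweighted over the fit selection (no mass
  weighting), matching the common default of trajectory-analysis suites;
  collinear fit selections are an error, not a silent pseudo-inverse.
* HETATM records and altlocs other than blank/'A' are dropped at parse
  time for deterministic topologies; masses come from the element, with a
  name-based fallback when the element column is absent.
* The drift unit conversion is ×10⁵ from Å/ps to pm·ns⁻¹.
* The iterative average-structure tolerance is 1e-6 Å RMS; non-convergence
  within 10 iterations is an error that reports the last shift.
* Zero O–N distances (non-physical) abort the adjacency computation; a
  distance table over zero matrices reports distance 0 with a degenerate
  flag rather than NaN.
* Pipeline outputs are formatted at fixed precision (`%.6g`), making
  repeated runs byte-identical; any stage failure removes partial outputs.

## Validation problem sizes

The test suite exercises every oracle at sizes chosen to bound the
statistical error well below the assertion tolerances: entropy convergence
on 50 000-frame independent-oscillator ensembles (sampling error of an
eigenvalue ≈ √(2/T) ≈ 0.6%, asserted at 1%); RMSF amplitude recovery at
10 000 frames across 50 seeds, asserted at 5% per residue (the rigid-body
fit bias on an 84-atom backbone is ≈ 6/(3N) ≈ 2% in variance, well inside
the band); occupancy recovery exact on noise-free schedules and within 2
percentage points under 0.1 Å schedule noise at 5 000 frames; t-test
calibration on 1000 null replicates. The demonstration pipeline uses
~25-residue toy complexes at a few hundred frames, which keeps a full
five-ensemble comparison in the tens of seconds on one core.

## Known limitations

* Quasi-harmonic entropy ignores mode anharmonicity and supralinear
  correlations; absolute values depend on sampling and mode retention, so
  only differences and cycles should be interpreted.
* The normalized Frobenius distance compares bridge-pattern *shapes*; two
  complexes whose bridges all weaken by a common factor are at distance
  zero by construction.
* The t-tests treat residues as independent observations; spatial
  correlation along the chain makes the effective sample size smaller than
  the residue count, so borderline p-values deserve caution.
* No mmCIF writer, no protonation assignment, no hydrogen-bond or π-cation
  detection, and no PCA/essential-dynamics clustering — the scope is the
  comparative descriptor set described above.
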