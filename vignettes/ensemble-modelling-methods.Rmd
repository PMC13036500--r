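---
title: "Methods: integrative ensemble modelling of tandem domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative ensemble modelling of tandem domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Two folded protein domains joined by a long flexible linker do not adopt a
single structure in solution: they populate a broad ensemble of relative
domain arrangements.  Two complementary experiments constrain that
ensemble.  DEER (double electron-electron resonance) yields the full
probability distribution P(r) of the distance between two spin labels in
the 15-100 Å range; PRE (paramagnetic relaxation enhancement) yields
per-residue transverse relaxation rate enhancements Γ₂ that scale as
r⁻⁶ with the electron-amide distance and are sensitive roughly between
12 and 25 Å.  `tandemens` implements the downstream modelling: forward
prediction of both observables from conformer pools, reweighting of
conformer populations against them, leave-one-out validation, descriptors
of the resulting ensembles, and an r⁻⁶ multi-state alternative that needs
only PRE data.

## Forward models

**Spin label.** A label is represented by a pluggable point cloud of
possible unpaired-electron positions.  The default `gauss_cloud` model
draws 64 points from an isotropic Gaussian (σ = 2.5 Å) centred 7 Å
from the attachment residue's Cα along the local outward direction (Cα
minus the domain centroid), with uniform point weights.  This is a
deliberately simple stand-in for a rotamer library; the registry
(`register_label_model`) accepts richer models with the same contract.
Cloud seeds are derived from the conformer geometry, so a conformer gets
the same cloud wherever it appears — the behaviour of a deterministic
rotamer library, and the property that makes noiseless synthetic
restraints exactly recoverable.

**Distance distributions.** For each conformer all cross-cloud point-pair
distances are accumulated with product point weights, binned onto a
uniform grid by first-moment-preserving linear splitting, and smoothed
with a Gaussian kernel (default σ = 1 Å).  The ensemble prediction is the
weight-linear mixture Σ w_c P_c.  Linear binning keeps the distribution
mean exact; the kernel sets the resolution floor of every fit, which is
why the recovery acceptance check uses "mean EMD below the kernel width"
as its success criterion.

**PRE rates.**  Per conformer and residue the effective electron-amide
distance is the r⁻⁶-weighted cloud average r_eff = (Σ p_k r_k⁻⁶)^(-1/6),
converted to a rate by the Solomon-Bloembergen expression
Γ₂ = K/r⁶ (4τ_c + 3τ_c/(1+ω_H²τ_c²)).  K defaults to
1.23·10⁻³² cm⁶ s⁻², the standard nitroxide-amide value — it is the only
value consistent with the detection-limit calibration below — and is a
configurable scalar.  Ensemble rates are the weighted mean over
conformers, clipped to the detection cap (170 s⁻¹) **after** averaging,
matching how back-computed values are treated in fitting.  A fast
internal-motion correction for the label is not modelled; the static
⟨r⁻⁶⟩ cloud average replaces it, and a richer label model can be plugged
in where that matters.

**Detection limit.** Amides bleached beyond detection are assigned
Γ₂ = 170 s⁻¹, which at τ_c = 11 ns and 700 MHz corresponds to ≈12 Å;
such residues carry only an upper distance limit.  PRE-derived distance
restraints carry first-order propagated errors from Γ₂ and τ_c (K's
uncertainty is excluded); restraints whose distance error exceeds 50 %
of the distance are dropped as unreliable.

## Reweighting

Both observables are linear in the conformer weights, so per-conformer
predictions are computed once and every fit is a deterministic convex
minimisation.  Weights live on the simplex via a softmax
parameterisation; L-BFGS-B runs from the uniform start with analytic
gradients (gradient tolerance 1e-8, at most 5000 iterations).  The EMD
(earth mover's distance, 1-D Wasserstein-1) is computed through the CDF
formulation, whose subgradients are well defined almost everywhere; the
PRE objective is the pooled mean chi-square with the cap rules above.

Balanced fitting first determines EMD_min and χ²_min by two
single-objective fits, then minimises the loss of merit
L = ½(EMD/EMD_min + χ²/χ²_min) − 1.  L near zero means the two restraint
sets are mutually consistent.  Two numerical conventions: denominators
are floored at 1e-8 during optimisation, and a figure of merit below that
floor is reported as a converged ratio of 1 — otherwise noiseless
fixtures, where both minima are numerically zero, would report
arbitrarily large or negative L.

Conformers with weights below 1 % of the largest weight are pruned and
one refit pass runs on the retained set (recomputing the single-objective
minima there, so the reported L is attributable to the reported
conformer set).  Pool-size sufficiency is checked by refitting on nested
pool prefixes in blocks of 100 conformers and flagging convergence when
the last two figures of merit agree within 2 % relative.

## Jackknife validation and the superensemble

With R distance distributions, R validation fits are run with R−1 of
them (the PRE set is never dropped), each pruned, and the omitted
distribution is backcalculated and scored against experiment.  The
superensemble pools the all-restraint ensemble with every validation
ensemble — here a union of conformer indices into one shared pool, since
the pool is not regenerated per omission — and is refit against all
restraints.  The superensemble refit reuses the all-restraint fit's
EMD_min and χ²_min as normalisation: L values stay comparable across the
two fits, and because the all-restraint solution is a feasible point of
the superensemble problem, the superensemble L can only improve.  This
nested-minimisation guarantee is asserted in the tests.  Descriptor
uncertainties are reported as mean ± 2·SD across the validation
ensembles, with the population SD (divide by R): the validation ensembles
are the complete ensemble-of-ensembles, not a sample from a larger one.

## Descriptors

The distance-RMSD D_kl between conformers (RMS difference of all
internal Cα-pair distances) is a Euclidean, superposition-free shape
metric.  Classical multidimensional scaling (double-centred squared
distances, eigendecomposition, negative eigenvalues truncated to zero)
embeds the conformers in abstract conformer space; the weighted radius
of gyration of the embedded points, R_g,ACS, measures shape diversity,
and δ = R_g,ACS/R_g is the dimensionless disorder parameter (≈0.1 for
rigid folded ensembles, 0.6-0.8 for random coils).  R_g is the weighted
RMS over per-conformer Cα radii, √(Σ w_c R_g,c²), and R_g,ACS uses the
same weights for consistency.  Contact maps count residue pairs with any
atom-atom distance ≤ 3 Å, weighted by conformer weight; binding-pose
checks pass when the shortest motif-domain atom distance is below
7.5 Å.  Merged-pool cluster analysis cuts an average-linkage dendrogram
of the combined D_kl matrix into round(C/12) clusters and classifies
each by member provenance (mixed / first-source-only /
second-source-only), with class fractions normalised per source; the
linkage choice and per-source normalisation are this package's choices
where several would be defensible.

## Multi-state modelling

When only PREs are available, N copies of the system are optimised
jointly and each restraint is satisfied by the effective distance
D* = (Σ d_i⁻⁶)^(-1/6) over states — dominated by the shortest state, so
a single close state can satisfy a strong PRE while other states roam.
All states have equal population.  The engine replaces torsion-angle
dynamics with rigid-body moves: domain 1 fixed, domain 2 of each state
carrying a rotation + translation, subject to linker closure (anchor gap
at most (n_linker+1) × 3.8 Å).  Spin-cloud centroids are pinned in the
domain frame beforehand (anchor distances reproducible within ±0.2 Å).
Simulated annealing (default 10⁴ steps, proposals: ≤15° rotation about
the domain centroid or ≤2 Å translation, geometric cooling 1.0 → 0.01 in
score units) minimises the quadratic violation score
Σ [max(0, D*−upl) + max(0, lol−D*)]², followed by a deterministic
Nelder-Mead quench of the best configuration, accepted only if it
improves the score without breaking closure.  States whose anchor gap
exceeds 0.8 × the closure bound are flagged elongated.  The state scan
(N = 1..10 by default) selects the smallest N whose best score is within
5 % of the overall minimum with no elongated states; this plateau rule
is the package's concrete reading of "best statistics without elongated
structures", which admits no single formula.

## The synthetic generator

Test systems are two rigid Cα-bead domains (default 70 residues each,
drawn once per system seed from a 10 Å ball) joined by a flexible linker
(default 30 beads, virtual bond 3.8 Å).  The linker is grown bead by
bead with a 3 Å self-avoidance rule applied to non-bonded pairs
(clashing steps are re-drawn; a conformer restarts if a step exhausts
its retries, and generation fails after 100 restarts).  Chain growth
rather than whole-chain rejection keeps the acceptance rate practical at
this bead density; it slightly stiffens the chain locally, which is
immaterial for the descriptors tested.  Amide positions are approximated
by the Cα beads — the descriptors in use (Cα R_g, D_kl, label clouds)
never need side-chain detail.  Distance grids default to 0-160 Å in
0.5 Å steps for the toy systems (wider than the experimental DEER
window, because Cα-bead labels reach shorter distances than labelled
side chains); the forward predictor refuses grids that miss more than
1 % of the distance mass.

Simulated restraints add zero-mean Gaussian noise: density noise with
σ = 5 % of the peak (clipped at zero, renormalised; confidence band
±2σ), PRE noise with σ = max(2 s⁻¹, 5 % of Γ₂), and rates at the cap
flagged vanished.  Noiseless copies are exactly the forward model output
on the truth ensemble, which is what makes the recovery tests sharp.
Bimodal systems can be produced by biasing linker growth towards one of
several preset directions (mixing two rigid-body arrangements of the
second domain).

What the generator does **not** emulate: real side-chain packing and
rotamer statistics, Ramachandran-weighted backbone sampling, RNA, label
chemistry, or correlated experimental noise.  Passing recovery tests
therefore demonstrates correctness of the fitting machinery under the
stated forward model, not performance on real spectrometer output.

## Problem sizes and determinism

The shipped tests run the recovery study on a 200-conformer pool
containing a 20-conformer truth ensemble (8 distance distributions, 2
PRE sites), the jackknife pipeline on a 30-conformer pool with the same
restraint layout, and the multi-state recovery on a planted 2-state
arrangement with 14 restraints over annealing seeds 1-5 — sizes chosen
so the whole suite runs on one CPU in minutes while every contract is
exercised at full fidelity.  All stochastic steps take explicit integer
seeds and restore the caller's RNG state; identical seeds give identical
results down to bytes on disk.

## Known limitations

- The EMD aggregation across restraints is an unweighted mean; no
  per-restraint uncertainty weighting is applied.
- Confidence bands on experimental distributions are carried for
  reporting only; fits use the point-estimate density.
- The label model is a single isotropic cloud; systematic rotamer
  effects (e.g. overly broad terminal-label distributions) are not
  corrected.
- Multi-state models never rebuild explicit linker coordinates; the
  linker enters only through the closure bound and elongation flag.
- Validation ensembles reweight one shared pool rather than regenerating
  pools per omission, so superensemble unions are exact index unions.
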