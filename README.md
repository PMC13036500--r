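# tandemens

Integrative ensemble modelling of flexibly linked tandem protein domains
against DEER distance-distribution and PRE restraints.

Multidomain proteins with long disordered linkers — tandem RNA
recognition motifs are the archetype — populate broad conformational
ensembles rather than single structures.  Two experiments constrain such
ensembles: DEER (double electron–electron resonance) measures the full
probability distribution P(r) of the distance between two spin labels
(≈15–100 Å), and PRE (paramagnetic relaxation enhancement) measures
per-residue rate enhancements Γ₂ that scale as r⁻⁶ with the
electron–amide distance.  `tandemens` provides, for structural
biologists working with such data:

- **Forward models** — pluggable spin-label point clouds, predicted
  distance distributions (Gaussian-kernel mixtures over cloud-pair
  distances) and PRE rates (Solomon–Bloembergen,
  Γ₂ = K/r⁶·(4τc + 3τc/(1+ωH²τc²)), with ⟨r⁻⁶⟩ cloud averaging and a
  170 s⁻¹ detection cap), plus the closed-form NMR relations:
  combined shift differences √(δHN² + (δN/6.51)²), correlation times
  √(6T₁/T₂ − 7)/(4πνN), and PRE→distance inversion with error
  propagation and restraint-derivation rules.
- **Ensemble reweighting** — conformer weights fitted on the simplex
  against the mean earth mover's distance (1-D Wasserstein) of the
  distance distributions, the mean PRE χ², or both balanced through the
  loss of merit L = ½(EMD/EMD_min + χ²/χ²_min) − 1; pruning at 1 % of
  the maximum weight; pool-size convergence curves.
- **Jackknife validation** — leave-one-distribution-out refits,
  backcalculation of the omitted restraint, superensemble pooling and
  refitting, and mean ± 2·SD uncertainty estimates for any ensemble
  descriptor.
- **Descriptors** — weighted radius of gyration √(Σ wc R²g,c),
  distance-RMSD matrices, the disorder parameter δ = R_g,ACS/R_g from
  multidimensional scaling of conformer shape differences, 3 Å contact
  maps, 7.5 Å binding-pose checks, and provenance-classified clustering
  of merged ensembles.
- **Multi-state modelling** — a rigid-body annealing engine in which N
  protein copies jointly satisfy PRE distance restraints through the
  effective distance D* = (Σ dᵢ⁻⁶)^(−1/6), with a 1–10-state selection
  scan, elongated-state rejection and splitting of the states into a
  conformer ensemble.
- **A synthetic generator** — seeded two-domain Cα-bead systems with a
  flexible self-avoiding linker, ground-truth ensembles with Dirichlet
  weights, and simulated noisy restraints, so the entire pipeline is
  testable end to end with known answers.

## Worked example

Simulate a two-domain system, fit conformer weights against noisy
restraints, and compare the fitted ensemble to the known truth:

```r
library(tandemens)

spec  <- toy_system_spec(seed = 3)              # 70 + 70 res, 30-res linker
pool  <- build_pool(spec, 60, seed = 7)
truth <- make_truth_ensemble(pool, 8, concentration = 2, seed = 9)
gt    <- simulate_restraints(truth, spec, seed = 11)

sites <- toy_label_sites(pool, spec, seed = 100)
cfg   <- gt$config
rd <- build_restraint_data(
  pool, sites,
  deer = lapply(gt$noisy$deer, function(e) list(pair = e$pair, obs = e$obs)),
  pre  = lapply(gt$noisy$pre,  function(e) list(site = e$site, obs = e$obs)),
  tau_c = cfg$tau_c, omega_h = cfg$omega_h, grid = cfg$grid,
  kernel_sigma = cfg$kernel_sigma, cap = cfg$cap)

fit    <- fit_weights(rd, "balanced")
pruned <- prune_weights(fit, rd)
fit; pruned
#> FitResult (balanced): 60 conformers, mean EMD 0.142 A, chi2 0.347, L 0.5706
#> FitResult (balanced): 10 conformers, mean EMD 0.147 A, chi2 0.350, L 0.1058

fitted <- subset_ensemble(pool, pruned$conformers, pruned$weights)
radius_of_gyration(truth)$rg;  radius_of_gyration(fitted)$rg
#> [1] 19.96939          [1] 19.96947
disorder_parameter(truth)$delta;  disorder_parameter(fitted)$delta
#> [1] 0.3650739         [1] 0.3652858
```

The mean EMD of ≈0.14 Å sits at the noise floor of the simulated
distributions; the pruned 10-conformer ensemble reproduces the truth
ensemble's radius of gyration and disorder parameter to within a
fraction of a percent.  The balanced loss of merit L near zero after
pruning indicates the DEER and PRE restraint sets are mutually
consistent, as they must be for data simulated from one ground truth.
`jackknife(rd)` then yields one validation ensemble per distance
restraint and `build_superensemble()` the pooled refit.

A useful single number: the PRE detection cap of 170 s⁻¹ at
τc = 11 ns on a 700 MHz spectrometer corresponds to

```r
gamma2_to_distance(170, tau_c = 11e-9, omega_h = 2 * pi * 700e6)
#> [1] 12.12558
```

so vanished amide signals mark residues within ≈12 Å of the label.

## Package layout

- `R/` — implementation: I/O and geometry (`ensemble.R`,
  `distributions.R`, `manifest.R`), NMR relations (`nmr.R`), label
  forward models (`label.R`), figures of merit (`metrics.R`),
  reweighting (`reweigh.R`), jackknife (`jackknife.R`), descriptors
  (`descriptors.R`), multi-state engine (`multistate.R`), synthetic
  systems (`synthetic.R`).
- `vignettes/ensemble-modelling-methods.Rmd` — the methods account:
  model assumptions, parameter choices, numerical conventions and
  limitations.
- `tests/testthat/` — unit, property and acceptance suites with
  fixtures generated in code.
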