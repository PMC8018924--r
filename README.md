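# solvens

Ensemble thermodynamics for solvation, tautomer and ionization equilibria.

## What problem this package addresses

Quantum-chemical solvation pipelines built on 3D reference interaction site
model (RISM) theory — in particular the embedded-cluster variant, EC-RISM —
produce, for every tautomer *t* and conformer *c* of a compound in a solvent,
a solution-phase electronic energy `E_sol`, a raw excess chemical potential
`mu_ex`, a partial molar volume `V_m` and a net charge `q`. Those raw numbers
are not yet observables: the excess chemical potential carries a systematic,
solvent-specific error that is empirically linear in `V_m` and `q`, and a
physical compound is an equilibrium population of many tautomer/conformer
states, not a single structure.

`solvens` is the thermodynamic post-processing layer that turns such
per-state records into physicochemical predictions, for computational
chemists who run (or consume the output of) these upstream calculations:

1. **Correction model** — per solvent, with adjustable parameters:

   `mu_corr(t,c) = c_mu * mu_ex(t,c) + c_V * V_m(t,c) + c_q * q + d`

   in five nested variants (`1-par`, `2-par`, `2-par-I`, `3-par`,
   `water-3-par-q`) that fix different subsets of `(c_mu, c_V, c_q, d)`.

2. **Partition-function Gibbs energy** of a species in solvent *i* at
   temperature *T* (25 °C by default):

   `G(i) = -RT ln Σ_tc exp[-(E_sol(t,c; i) + mu_corr(t,c; i)) / RT]`

   evaluated shift-stably (log-sum-exp), with per-state Boltzmann weights.
   Gas-phase ensembles use the uncorrected electronic energy `E_gas`.

3. **Observables** —
   `log P = (G(W) - G(C)) / (RT ln 10)` between water W and an organic
   phase C; `log D_7.4 = log P - log10(1 + 10^(pKa-7.4))` for bases and
   `log P - log10(1 + 10^(7.4-pKa))` for acids; a two-parameter linear pKa
   model `pKa = a * (G_deprot - G_prot) + b`; and tautomerization free
   energies `dG0 = G_b(W) - G_a(W)` by a direct route or via an explicit
   thermodynamic cycle with high-level gas-phase energies and thermal
   corrections.

4. **Conformer-ensemble reduction** — the protocol that selects the states
   entering the partition function: discard conformers ≥ 5 kcal/mol above
   the minimum, cluster greedily in energy order at a 0.5 Å Kabsch-RMSD
   radius, keep up to five lowest-energy representatives.

5. **Calibration** — ordinary least squares for the free parameters of any
   correction variant against reference solvation free energies (plus an
   ensemble-aware nonlinear mode), and for the pKa model.

6. **Evaluation** — blind-challenge statistics (RMSE, MAE, mean *signed*
   error, descriptive regression m′/b′/R², all errors calculated minus
   experimental, population convention), grouped/batch analysis, outlier
   exclusion with provenance, and cross-method consensus averaging.

7. **Synthetic data with known ground truth** — a generator that emulates
   per-state pipeline output whose reference observables follow the
   generating equations exactly, so calibration and clustering are
   validated by parameter recovery rather than by fixtures alone.

Benchmark fixture tables (a 53-compound cyclohexane/water distribution
coefficient set across three batches, a 20-reaction aqueous tautomerization
set, and the published correction-model parameters) ship as plain CSV under
`inst/extdata/` with loaders and `reproduce_*` helpers.

## Worked example

Four states (two tautomers × two conformers) of one compound in water and
cyclohexane, using the shipped `3-par` cyclohexane model:

```r
library(solvens)
const <- thermo_constants()          # R*T*ln(10) = 1.3643 kcal/mol at 298.15 K
p3 <- fixture_correction_params("3-par")           # c_mu 1.8516, c_V -0.14692, d -1.0842
pw <- correction_params("2-par-I", c_V = -0.11, d = -1.2, phase = "water")

st <- validate_states(data.frame(
  compound_id = "drug1",
  tautomer_id = rep(c("T1", "T2"), each = 2),
  conformer_id = rep(c("C1", "C2"), 2),
  phase = "water",
  E_sol = c(-101.2, -100.4, -99.8, -99.1),
  mu_ex = c(-12.3, -11.9, -13.4, -13.0),
  V_m = 210, q = 0))

gw <- ensemble_gibbs(species_ensemble(st, "drug1", "water"), pw, const)
gw
#> gibbs_result: G = -138.157655 kcal/mol over 4 state(s)
round(gw$weights, 4)
#> [1] 0.5468 0.0721 0.3296 0.0515
```

The Gibbs energy lies below every single-state value (the ensemble gains
mixing entropy) and the weights say the compound is ~55% in its best
tautomer-1 conformer with a 33% admixture of tautomer 2. With the analogous
cyclohexane ensemble (`G_C = -140.4325`):

```r
lp <- log_p(gw$G, gc$G, const)
lp
#> [1] 1.668
log_d(lp, "base", pKa = 8.9)
#> [1] 0.154
```

so the neutral species prefers cyclohexane by 1.7 log units, but at pH 7.4
most of this base is protonated and trapped in water, pulling the
distribution coefficient down to 0.15. Benchmark statistics come from the
same machinery:

```r
prediction_metrics(sampl5_prediction_table("2-par-I"))
#> metric_set (n = 52): RMSE 2.455, MAE 1.706, MSE -0.671, m' 1.686, b' -0.351, R2 0.665
```

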