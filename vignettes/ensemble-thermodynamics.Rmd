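---
title: "Ensemble thermodynamics for solvation and ionization equilibria: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble thermodynamics for solvation and ionization equilibria: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solvens)
```

This vignette documents the models implemented in `solvens`, the assumptions
behind them, the numerical choices that matter, and the design decisions
taken where the problem left room for interpretation. It states no empirical
result beyond what the package's tests and `scripts/acceptance.R` compute.

## The physical model

### Per-state records

The unit of input is one *state*: a (compound, tautomer, conformer, solvent
phase) combination with a solution-phase electronic energy `E_sol`
(kcal/mol), a raw excess chemical potential `mu_ex` (kcal/mol) from an
integral-equation solvation calculation, a partial molar volume `V_m`
(Å³), and a net charge `q` (elementary units, validated to be
integer-valued within 1e-6). Gas-phase electronic energies (`E_gas`),
thermal corrections (`G_thermal_gas`) and high-level gas energies
(`E_gas_highlevel`) are optional: how states missing them should be treated
is not defined globally, so they are required only by the operations that
actually consume them (solvation free energies and the thermodynamic-cycle
route, respectively). Energies are kept in kcal/mol internally; tables
declared in hartree are converted once at read time (1 hartree = 627.5095
kcal/mol), because upstream quantum-chemistry output and thermodynamic
reference data conventionally mix the two units.

### The correction model

Raw integral-equation excess chemical potentials carry a systematic error
that is, to good approximation, linear in the partial molar volume and the
net charge of the solute. The package therefore applies

$$\mu^{\mathrm{ex,corr}}_{tc} = c_\mu \mu^{\mathrm{ex}}_{tc}
  + c_V V_{\mathrm{m},tc} + c_q q + d$$

with solvent-specific parameters. Five variants fix different subsets:
`1-par` (only $c_V$ free), `2-par` ($c_\mu, c_V$), `2-par-I` ($c_V, d$;
$c_\mu = 1$), `3-par` ($c_\mu, c_V, d$), and `water-3-par-q`
($c_\mu, c_V, c_q$) — the charge term exists only for water, where ionic
reference data are available; consequently the package validates ions only
in aqueous models. Units: $c_\mu$ dimensionless, $c_V$ kcal/(mol Å³),
$c_q$ kcal/(mol e), $d$ kcal/mol. The constructor pins the fixed entries,
so a variant tag is sufficient to know which parameters were fitted.

### Partition-function Gibbs energies

A species is an equilibrium population over its states. Its Gibbs energy in
solvent $i$ is

$$G(i) = -RT \ln \sum_{tc}
  \exp\!\left[-\left(E^{\mathrm{sol}}_{tc}(i)
  + \mu^{\mathrm{ex,corr}}_{tc}(i)\right)/RT\right]$$

with $R = 1.987204\times10^{-3}$ kcal/(mol K) and $T = 298.15$ K by default
($RT\ln 10 \approx 1.3643$ kcal/mol). Two scopes of "species" are both
meaningful and are made explicit rather than inferred: a *single tautomer*
(the species entering pKa models and tautomerization reactions) and *all
tautomers of a compound* (the species entering log P and log D).
`species_ensemble()` carries the scope as metadata.

Standard-state subtleties are deliberately out of scope: calculations are
taken to represent infinite dilution at 1 bar, so no pressure or
concentration conversion terms appear anywhere.

### Gas phase and solvation free energies

The gas-phase ensemble uses the *uncorrected* electronic energy `E_gas` as
the per-state energy: the correction is solvent-specific, and the gas-phase
state of a compound is the same regardless of which solvent it will be
dissolved in. The solvation free energy is the difference of the two
partition-function Gibbs energies, ignoring thermal corrections — thermal
terms enter only the thermodynamic-cycle route below, where both legs treat
them consistently.

### Observables

* `log_p()` implements $\log P = (G(W) - G(C))/(RT\ln 10)$. Sign audit: a
  compound far more stable in water ($G_W \ll G_C$) gets a strongly
  negative log P, which matches the hydrophilic compounds of the shipped
  benchmark table (e.g. SAMPL5_074 is negative under every model).
* `log_d()` lowers log P by the ionized fraction:
  $\log D_{\mathrm{pH}} = \log P - \log_{10}(1 + 10^{\mathrm{p}K_a -
  \mathrm{pH}})$ for bases and $\log P - \log_{10}(1 +
  10^{\mathrm{pH} - \mathrm{p}K_a})$ for acids, with pH defaulting to 7.4
  but overridable. The ionized species is assumed unable to enter the
  organic phase, so log D ≤ log P always. Acid/base typing is an input
  annotation (`ionization_info()`), not perceived from structure, and one
  macroscopic pKa per compound is used — microstate-resolved multi-site
  titration is out of scope.
* `pka_from_gibbs()` is the two-parameter affine map
  $\mathrm{p}K_a = a\,(G_{\mathrm{deprot}} - G_{\mathrm{prot}}) + b$. The
  slope scales the deprotonation Gibbs energy difference; the intercept
  absorbs the free-proton contribution, whose absolute value the upstream
  calculation cannot provide. What exactly the proton term contains is
  thus never modelled explicitly — both parameters come from calibration.
* `tautomer_dg_direct()` is $\Delta G^0 = G_b(W) - G_a(W)$ over
  single-tautomer ensembles; `tautomer_dg_cycle()` adds a high-level
  gas-phase reaction free energy (partition-function averaged over
  rotamers using `E_gas_highlevel + G_thermal_gas`) to the difference of
  explicit solvation free energies. When the high-level energies equal the
  standard ones and thermal terms vanish, the cycle closes onto the direct
  route exactly — this closure is tested to 1e-9.

## Conformer-ensemble reduction

The reduction protocol mirrors common practice for preparing
quantum-chemistry conformer sets:

1. **Energy window**: conformers at least 5 kcal/mol above the minimum are
   discarded. The boundary is read strictly — "at least 5 higher is
   discarded" means a conformer exactly at +5.0 goes, one at +4.999 stays.
2. **Greedy clustering**: survivors are processed in ascending energy
   (ties stable in input order). The minimum seeds cluster 1; each
   subsequent conformer joins the *first* existing cluster whose
   representative is within 0.5 Å RMSD and seeds a new cluster only when
   it is ≥ 0.5 Å from *every* representative. The all-representative test
   (rather than only the nearest or the first) guarantees representatives
   are pairwise ≥ 0.5 Å apart, which makes re-clustering the
   representatives idempotent — both properties are tested.
3. **Selection**: up to five lowest-energy representatives are kept
   (`k = 1` reproduces single-structure workflows).

RMSD is plain heavy-atom Kabsch superposition (SVD with determinant-sign
correction, so reflections are excluded). Atom-symmetry permutations are
*not* searched; a symmetry-aware routine can merge symmetric duplicates
that this implementation keeps apart, which affects cluster counts on
symmetric molecules, not the correctness of the clustering contract.
Whether hydrogens belong in the RMSD is not standardized either; they are
excluded by default (they add noise from rotatable X–H groups) with an
`include_hydrogens` flag. Conformer generation and force-field or
continuum-solvent optimization are upstream concerns and out of scope; the
synthetic generator fabricates geometry sets instead.

## Calibration

`fit_correction()` solves ordinary least squares for the free parameters of
a variant, minimizing residuals of
$E_{\mathrm{sol}} - E_{\mathrm{gas}} + \mu^{\mathrm{ex,corr}}$ against
reference solvation free energies, one representative state per training
compound. This single-state linear fit is the default pathway because
reference training sets are conventionally built per structure. The
ensemble-aware `fit_correction_ensemble()` exists because *evaluation*
feeds multi-conformer ensembles into parameters trained per-structure;
keeping both modes explicit preserves that (historically real) asymmetry
instead of hiding it. The ensemble mode is genuinely nonlinear (parameters
sit inside the partition function), so it runs Levenberg–Marquardt
(`minpack.lm`), initialized from the linear fit, converging on a relative
parameter step below 1e-8, erroring with the last iterate on
non-convergence. No regularization is used anywhere: every variant has at
most four parameters against tens to hundreds of records, and ionic/neutral
subsets are weighted equally (no statement to the contrary being
available).

Degenerate designs fail loudly and name the offending column: fewer records
than free parameters, a spread-free column (e.g. all `V_m` equal when
fitting $c_V$, or an all-neutral set when fitting $c_q$), or collinearity.

`fit_pka()` is the analogous two-parameter OLS for the pKa model, requiring
at least two pairs with non-degenerate Gibbs-energy spread.

## Evaluation statistics

All error conventions were chosen once and used everywhere, because mixing
them silently changes signs and magnitudes:

* errors are **calculated minus experimental**; MSE is the mean *signed*
  error (bias), not a squared quantity;
* all means and variances use the population (divide-by-n) convention —
  required to reproduce printed benchmark statistics exactly;
* the descriptive regression fits calculated on experimental
  ($y_{\mathrm{calc}} = m' y_{\mathrm{exp}} + b'$), so over-spread
  predictions show $m' > 1$;
* $R^2$ is the squared Pearson correlation, always in [0, 1], used
  descriptively rather than as a model-selection criterion;
* missing predictions are flagged rows, excluded from metrics but never
  silently dropped; exclusions are recorded in table attributes
  (provenance), and excluding every row is an error;
* with zero variance in the experimental column the regression fields are
  returned as an explicit undefined marker (`NA` plus
  `regression_undefined`), not NaN propagation.

`grouped_metrics()` reports one metric set per group plus a pooled set over
the union. In the shipped tautomerization benchmark the two
high-experimental-uncertainty diketo reaction pairs form their own group:
they are part of every pooled analysis but of neither the obscure nor the
explanatory subset — the pooled mean signed error equals the n-weighted
mean of the group values to 1e-10, which is tested. For the shipped
distribution-coefficient benchmark, the pooled all-batch summary computed
from the per-compound table is the normative value of record wherever
rounded summaries disagree between sources.

`consensus_tables()` averages two methods' predictions over their common
ids and reports cross-method metrics (method a evaluated against method b),
quantifying inter-method agreement independently of experiment.

## Numerical choices

* **Log-sum-exp is a contract, not an optimization.** Naive
  $\sum\exp(-g/RT)$ overflows once $|g|$ exceeds a few hundred times $RT$
  (electronic energies are routinely in the tens of thousands of kcal/mol
  when absolute). `boltzmann_gibbs()` subtracts the maximum exponent, is
  exactly translation-covariant, and is tested against direct summation to
  1e-10 on small ensembles where the naive form is safe, and against the
  shifted form at offsets of 1e5 kcal/mol.
* **Tie-breaks** are stable everywhere: energy sorting keeps input order on
  ties (R's stable `order`), so clustering and selection are deterministic
  functions of the input.
* **Degenerate inputs**: empty ensembles, empty conformer sets, exhaustive
  exclusions and phase mismatches are errors, not warnings; duplicate state
  keys name the key; non-finite required fields name the column.
* **Typographic minus signs** (U+2212) are normalized to ASCII hyphens at
  ingestion of fixtures and state tables, a real-world nuisance with
  copy-pasted thermodynamic tables.

## The synthetic-data generator

The generator emulates the *shape* of per-state pipeline output, not real
chemistry. Energy scales are fixed at what practitioners see in drug-sized
solutes: excess chemical potentials in [−80, +20] kcal/mol, partial molar
volumes in [50, 400] Å³ (shared within ±2% across conformers of a species,
since PMV is a whole-molecule property), conformer spreads within
5 kcal/mol, gas-to-solution electronic shifts of a few kcal/mol. Reference
solvation free energies are computed through the *same* generating
equations the pipeline implements (ground-truth correction plus partition
functions) and only then perturbed with Gaussian noise of configurable sd —
so at zero noise every fit must recover the generating parameters to
numerical precision, and under noise the recovery error must scale as
$\sigma/\sqrt{n}$; both are tested. Titratable compounds are constructed
inversely: a true pKa is drawn (default range 2–12, roughly the
experimentally accessible window), and the protonated/deprotonated Gibbs
energies are built so the ground-truth pKa model maps their difference
exactly onto it.

Conformer sets are planted-cluster constructions: cluster centers displaced
from a base geometry to an exact target Kabsch RMSD (default 1.2 Å,
verified pairwise ≥ 0.8 of it), members within 0.15 Å of their center, so
the true clustering at the 0.5 Å radius is known and must be recovered
exactly. Randomness runs in a private stream per dataset (the caller's RNG
state is saved and restored), seeded explicitly, making every dataset
bit-reproducible.

What the generator does **not** emulate — and hence what passing recovery
tests do *not* show about real data: correlated errors between states of
one compound, heavy-tailed or systematic (non-Gaussian) deviations of the
upstream theory, tautomer enumeration mistakes, conformational sampling
gaps, and any structure–property relationship (geometries have controlled
RMSD topology but no chemistry). Real benchmark behaviour is represented
only by the shipped fixture tables.

## Problem sizes

The test suite and acceptance script use sizes chosen to make the
statistical assertions sharp while keeping runs interactive: 20 replicates
at n = 500 compounds for the noisy-recovery check (training RMSE within 10%
of the generating sd of 0.5 kcal/mol; parameters within three standard
errors), 60 replicates at n ∈ {50, 500} for the $1/\sqrt{n}$ scaling, up to
8 states for oracle-equivalence of the partition function, 4-atom toys for
the rotation-minimization RMSD oracle, and 2–4 planted clusters for
clustering recovery.

## Known limitations

* Ionization site typing and pKa assignment per compound are inputs; the
  package predicts a pKa from Gibbs energies but does not decide which site
  ionizes or enumerate microstates.
* The RMSD is not atom-symmetry aware (see above).
* The shipped correction-model parameter table is a fixture: its training
  data (curated experimental solvation free energies plus the upstream
  integral-equation raw output) are not distributable with the package, so
  those particular fits are consumed, never re-derived; calibration is
  validated on synthetic ground truth instead.
* No bootstrap or analytic confidence intervals on evaluation metrics; the
  benchmark sets are small and the field's convention is to report point
  statistics.
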