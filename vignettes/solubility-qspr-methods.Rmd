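---
title: "Modelling intrinsic aqueous solubility: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling intrinsic aqueous solubility: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Intrinsic aqueous solubility — the concentration of the neutral form of a
solute in a saturated aqueous solution at equilibrium, expressed here as
log(S) in log10 molar units at 298 K — is one of the properties that decides
whether a drug-like molecule is developable. Data-driven (QSPR) models
predict it from molecular structure alone: a table of molecules with
experimental log(S) values is curated, each molecule is converted to a
vector of 2D descriptors, and a regression model is trained and validated by
resampling. `solqspr` implements that pipeline end to end, together with the
two audits that decide how far such a model can be trusted: a
chemical-space comparison of training and test sets, and a counterfactual
attribution of the model's behaviour to molecular fragments.

Because public solubility compilations cannot be shipped with the package,
`solqspr` also contains a synthetic molecule-library generator with a known
structure-to-solubility ground truth, so that every stage of the pipeline is
testable offline and the statistical machinery can be checked against known
answers.

## Curation rules

`curate()` applies, in order:

1. **Standardization** (`standardize_set()`): each SMILES must parse;
   multi-component strings are treated as salts when all components but the
   highest-molecular-weight one are recognized counterions (Na, K, Li, Ca,
   Mg, Cl, Br, I, ammonium, acetate, sulfate, nitrate). The counterions —
   the lowest-MW salt components — are removed and residual plus/minus
   charges on the parent are neutralized. Any other multi-component string
   (solvates, mixtures) is rejected. The tautomer written in the input is
   preserved; single-component zwitterions keep their charges and are only
   flagged, since data sources typically record a deliberate protomer.
2. **Deduplication** (`deduplicate()`): exact standard-InChI equality; the
   first occurrence in input order is kept. Keeping the first (rather than
   averaging) makes the operation order-stable and auditable.
3. **Filters** (`apply_filters()`): molecules with fewer than 4 heavy atoms,
   molecular weight above 1400, or more than 20 rotatable bonds are
   excluded — strict inequalities, so boundary values are retained.
   Rotatable bonds are non-ring single bonds between two non-terminal heavy
   atoms, excluding amide C–N bonds (the common toolkit default).

The `curation_report` is conserved by construction: input = retained + all
rejection tallies + deduplicated removals, and this identity is asserted on
every report.

## Descriptors, scaling, fingerprints

`compute_descriptors()` offers a 2D-only panel assembled from OpenBabel
physicochemical properties (calculated logP, TPSA, molar refractivity, MW,
H-bond donor/acceptor counts) and structural/fragment counts computed on
the molecular graph or by SMARTS matching (ring and aromatic-ring counts,
rotatable bonds, halogens, and a 15-descriptor fragment vocabulary used by
the counterfactual module). Three cleanup rules run on every panel: any
descriptor whose name suggests it *is* a solubility estimate (substrings
"solubility", "logs", "esol", case-insensitive) is removed; non-numeric
(boolean/string) outputs are removed; and any descriptor that is missing or
non-finite for *any* molecule is removed for all molecules, so every
molecule is described by the same valid descriptor set. Removals are
recorded in the matrix's `drop_log` attribute rather than asserted as a
fixed column count, because panel composition is toolkit-version dependent.

Feature scaling (`fit_scaler()`/`apply_scaler()`) is mean-centering to unit
variance with the population (divide-by-N) SD convention. The scaler is fit
*inside each cross-validation training portion only* and applied to the
corresponding held-out data with training statistics; this is the only
reading of the protocol that cannot leak test information.

Morgan (circular) fingerprints — radius 2, 2048 bits — are computed by the
package itself on the canonical form of each molecule, using atom
invariants (element, degree, implicit hydrogens, charge, ring membership,
aromaticity) and iterative neighbourhood hashing. No installed R package
exposes Morgan/ECFP fingerprints, so the hash is the package's own: bit
positions are internally consistent and deterministic but not
interchangeable with other toolkits'. All similarity statistics in the
package are therefore *relative* quantities; cross-toolkit bit-level
comparisons are out of scope.

## Models and the validation protocol

Two regressor families stand behind `fit_model()`:

* **Random Forest** via `ranger` (single-threaded, seeded, impurity
  importance). Hyperparameters: `n_trees` (default 500), `max_features`
  ("sqrt", "third", "all"), `min_samples_leaf`, `max_depth`, and
  `bootstrap` (disabling it with `max_features = "all"` makes deep forests
  memorize separable data exactly, which the tests use as an oracle).
* **Feed-forward network**, implemented in plain R matrix algebra: three
  densely connected hidden layers of strictly decreasing width (default
  128/64/32), ReLU activations, Adam optimizer, mean-squared-error loss
  (the differentiable counterpart of tuning to RMSE), minibatch training
  with best-validation-epoch checkpointing over a default budget of 200
  epochs. A hand-rolled network is appropriate here because the data sizes
  (hundreds to a few thousand molecules, tens of descriptors) make a deep
  learning framework unnecessary, and none is assumed to be present.

`nested_cv()` is the experimental design used for every reported statistic:
50 outer resamples (default), each a fresh random 70%/30% train/test split;
on each training portion a 5-fold cross-validation scores every
hyperparameter grid point by mean RMSE (folds fixed per resample and shared
across grid points); the winner — ties broken by grid order — is refit on
the whole training portion and scored on the held-out 30%. Statistics are
reported as mean ± SD over resamples. Per-resample seeds are spawned
deterministically from the master seed, so reports are bit-reproducible.
`modal_params()` carries the most frequently selected grid point to
`final_fit()`, which retrains on 100% of the data before external
prediction. Default grids (RF: trees {100, 500} x mtry {sqrt, 1/3, all} x
leaf {1, 3}; NN: widths {(256,128,64), (128,64,32)} x lr {1e-3, 1e-4}) are
declared, overridable defaults — the choice of grid is a configuration, not
a result.

## Error decomposition

`evaluate()` reports, for a set of N predictions:

* R² — the coefficient of determination about the experimental mean, which
  is negative when predictions are worse than the null model;
* RMSE — root-mean-square of (calculated − experimental);
* bias (M) — the mean signed error; positive = solubility overpredicted;
* SDEP — the population SD of the error, the random component;
* % ± 0.5 log — the percentage of predictions within half a log unit
  (boundary inclusive).

With the population-SD convention, RMSE² = SDEP² + bias² holds exactly, and
the package asserts it (to 1e-9) on every `eval_stats` object ever
constructed. `rmse_from_components()` exposes the identity directly, which
is how published statistics tables can be cross-checked from their printed
components. `null_model_flag()` compares RMSE against the experimental SD
(strictly), and `range_restrict()` filters a prediction set to a strict
experimental-solubility window — defaulting to (−6.79, −1.18), the range of
the low-variance challenge test set — so that sets with different
experimental ranges can be scored comparably.

## Chemical-space audit

`set_to_set_distribution()` computes all pairwise Tanimoto similarities
between two sets (or within one), summarized with fixed 0.05-wide
histogram bins. `murcko_summary()` reduces each molecule to its
Bemis–Murcko scaffold (ring systems plus linkers, side chains removed,
exocyclic double-bonded atoms retained) and counts unique scaffolds per set
and overlaps between sets; acyclic molecules form a shared "empty-scaffold"
bucket reported separately, since counting them as distinct chemotypes
would inflate diversity. `build_similarity_graph()` connects molecules with
Tanimoto ≥ 0.5 (inclusive, configurable) and lays the graph out with a
seeded Fruchterman–Reingold algorithm in which edge weights act as spring
strengths; coordinates are advisory output for plotting, never asserted
beyond finiteness.

## Counterfactual attribution

The attribution procedure asks which fragments the model credits for
solubility changes: mutate a molecule slightly, keep mutants whose
*predicted* log(S) moves by at least 1 log unit, cluster the mutants by
fingerprint similarity (threshold 0.7, one representative per cluster — the
largest shift), pair each representative with its parent when *exactly one*
fragment descriptor changed, and per fragment report the fraction of pairs
in which adding it increased (f⁺) or decreased (f⁻) the prediction; the
effect f⁺ − f⁻ lies in [−1, 1].

Mutation requires an encoding in which arbitrary edits still decode to
valid molecules. The SELFIES encoding used for this purpose in the Python
ecosystem has no R counterpart, so `solqspr` uses the synthetic library's
own scaffold-decoration genotype — a scaffold token plus substituent tokens
at named sites — which has the same robustness guarantee: every
substitution, insertion or deletion of a substituent token is a valid
molecule by construction. The consequence is that mutation is defined for
genotype-bearing molecules (generated libraries), which is where the
attribution study runs in this package; attribution of arbitrary external
molecules would require a general robust encoder and is a known
limitation.

## The synthetic generator: what it emulates, and what it does not

`generate_library()` decorates five drug-like scaffolds (benzene, pyridine,
piperidine, cyclohexane, a biphenyl) with up to four substituents drawn
from twelve common groups (alkyls, hydroxyl, amine, carboxyl, methoxy,
halogens). The noiseless log(S) is linear in five structural counts with a
dominant lipophilicity-like term:

* aliphatic carbons: −0.45 per atom (dominant, the widest-varying count —
  a proxy for the calculated-logP dominance seen in descriptor-importance
  analyses of real solubility models);
* aromatic rings: −1.2; halogens: −0.70; H-bond donors: +0.60; acceptors:
  +0.30; intercept −0.30.

These values were chosen once, for realism: they place benzene at −1.5,
toluene at −1.95 and cyclohexane at −3.0 (close to the experimental
intrinsic solubilities of those solvents) and put the bulk of the library
between 0 and −5 log units, the interval where most published training data
lies. Truth values are clamped to a target range (default (−8.5, 0.5)) by
resampling, and an unreachable range fails loudly. Observed values add
i.i.d. Gaussian noise in log10 units at σ = 0.17 ("tight") or σ = 0.62
("loose"), the reported inter-laboratory SDs of the low- and high-variance
halves of the second solubility challenge; only SDs are published for those
sets, so a Gaussian law is an assumption.

What the generator does **not** emulate: real pharmaceutical chemistry
(fused heterocycles, stereochemistry, tautomerism), measurement error that
correlates with chemistry, melting-point/crystal-packing effects, and a
nonlinear structure–property map. Passing tests on synthetic libraries
therefore demonstrate that the *machinery* — curation bookkeeping,
resampling protocol, error decomposition, importance ranking, attribution
statistics — is correct and calibrated (e.g. validation RMSE approaches the
injected σ as n grows), not that any model generalizes to real chemical
space.

## Numerical choices and degenerate inputs

* All randomness flows from explicit integer seeds; per-resample and
  per-parent seeds are spawned from the master seed so components are
  independently reproducible. Seeded fits are bit-deterministic
  (single-threaded forests; fixed-order network updates).
* Grid-search ties break toward the first grid point; modal-parameter ties
  toward the earliest resample choice.
* Zero-variance descriptors are dropped by the scaler (recorded), not
  imputed; zero experimental variance makes R² undefined (`NA`) rather
  than an arbitrary number; an empty range-restricted prediction set is
  valid and flagged.
* Fingerprint hashing is an exact-integer polynomial hash below 2^31, so
  it is platform-independent in double arithmetic.
* Problem sizes used by the test-suite experiments: libraries of 200–500
  molecules for model checks, 2000 for the noise-floor calibration, 100000
  draws for the noise-SD oracle, 3–5 resamples where the protocol itself is
  not the quantity under test. These sizes make every property detectable
  at comfortable margins while keeping the suite quick to run.

## Known limitations

* Scaffold counts and Tanimoto distributions are toolkit-specific (own
  Morgan hash, OpenBabel aromaticity model); comparisons against numbers
  produced with other toolkits can differ by a few percent.
* The counterfactual stage covers generated libraries only (see above).
* The NN family has no importance measure; `gini_importances()` is
  deliberately undefined for it rather than substituting a different
  attribution method.
* Leave-cluster-out validation is not implemented; `split_fixture()`'s
  scaffold-disjoint mode provides the building block for it.
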