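---
title: "Predicting protein thermostability changes with ThermoShift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein thermostability changes with ThermoShift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ThermoShift)
```

# The problem

Point mutations change a protein's resistance to thermal unfolding. The
standard experimental summary is ddG, the change in the free energy of
thermal denaturation between mutant and wild type, in kcal/mol; under the
convention used throughout this package, **ddG > 0 means the mutation
stabilizes the protein**. Curated mutant collections are heavily skewed
toward destabilizing mutations (roughly 3:1), mix single- and multi-site
mutants (1 to 9 sites), and span proteins of very different sizes — all of
which the machinery here is built to accommodate.

ThermoShift implements a structure-based pipeline that, given a wild-type
structure and a mutation list, predicts both the **sign** of ddG
(classification) and its **value** (regression).

# The pipeline

For one mutant of one protein:

1. **Read the wild-type structure** (`readPDB()`); waters are removed, the
   first-listed alternate location wins, residue numbering is kept as in the
   file.
2. **Model the mutant** (`buildMutantEnsemble()`): k stochastic structural
   models are built (default k = 10; performance of the downstream learners
   is insensitive to k once it exceeds about 6).
3. **Summarise each model by 29 structural features** (`computeFeatures()`):
   13 energy-style terms (H-bond counts, van der Waals contacts and clashes,
   coarse electrostatics, solvation proxies, side-/main-chain entropy
   proxies, torsional and backbone clashes, a helix-dipole proxy, and their
   total), 3 stereochemical potential terms (bond, bond+angle, improper),
   and 13 distance-bin frequencies — the share of non-covalent heavy-atom
   pairs falling in 0.1-Angstrom bins from 2.1 to 3.3 A.
4. **Average the k feature vectors** into one summary vector N
   (`ensembleMean()`).
5. **Build the protein's own background** (`backgroundStats()`): every one
   of the l standard residues is mutated in silico to each of the 19 other
   amino acids (`enumerateSaturation()`, exactly l x 19 mutants), each
   background mutant is modelled and featurised, and the pool's per-feature
   mean U and population standard deviation S are retained together with the
   pooled matrix.
6. **Encode** (`encodeMutant()`): the input vector Z has 58 elements —
   V = (N - U) / S per feature (0 where S = 0), and Y = the midrank
   percentile of N within the background pool per feature. Both blocks
   express "where does this mutant sit relative to *all possible single
   mutants of this protein*", which makes vectors comparable across
   proteins of different sizes and compositions. V is invariant to common
   affine rescaling of a feature; Y to any strictly monotone transform.

Multi-site mutants are encoded against the same single-site saturation
background; no multi-site background is constructed.

`encodeDataset()` runs steps 2–6 for a table of mutants, computing each
protein's background once.

# Learners and imbalance handling

Four learners operate on Z (`trainClassifier()`, `trainRegressor()`):

* **rf** — a random forest whose every tree is grown on a bootstrap with
  *equal draws from both classes* (down-sampling to the minority size),
  countering the ~3:1 destabilizing excess. The score O is the fraction of
  trees voting "stabilizing".
* **svm** — an RBF-kernel soft-margin machine whose misclassification
  penalty on the stabilizing class is 3-fold that of the destabilizing
  class; O is a sigmoid (Platt-style) calibration of the decision value,
  fitted on the training decision values.
* **rfr** — forest regression (plain bootstrap, leaf-mean averaging).
* **svr** — epsilon-insensitive RBF support vector regression with
  gamma = 2 and cost = 8.

Defaults (`thermoParams()`): 1000 trees (performance is stable above ~500),
`mtry = round(sqrt(58)) = 8`, node size 1 (classification) / 5 (regression),
gamma = 2, cost = 8, epsilon = 0.1. Every stochastic step takes a seed and
is bit-reproducible.

The **reliability index** `RI = floor(20 * |O - 0.5|)` maps the classifier
score to an integer 0–10 confidence ("INTEGER(x)" is read as truncation,
which for these non-negative arguments equals floor). `riAccuracyCurve()`
reports, for each threshold t, the fraction of predictions with RI >= t and
the accuracy among them.

# Evaluation protocol

`crossValidate()` performs k-fold (default 10) cross-validation: each
mutant is scored exactly once by models not trained on it. Reported metrics
are Q2 (percent accuracy), MCC (with the standard MCC = 0 convention when a
marginal is empty), sensitivity, specificity, Pearson's r between
experimental and predicted ddG, and ROC/AUC (trapezoid rule, ties by
midrank — identical to the concordant-pair statistic). Reports are
stratified by mutation count (1, 2, 3, >=4, and the ">=1" whole-dataset
row) and by experimental |ddG| bin ([0,1), [1,2), [2,3), [3,14) kcal/mol).

Folds are class-stratified by default. The literature this protocol follows
does not state protein-grouped folds, so stratified assignment is the
default; because protein-identity leakage across folds is a known hazard, a
`group_by_protein = TRUE` mode is provided (documented, never silently
enabled). `permutationImportance()` measures each feature's contribution as
the drop in held-out accuracy when that feature's column is permuted
(mean of 10 seeded permutations).

# The synthetic world

`generateDataset()` produces encoded tables with known structure so the
whole pipeline is testable offline:

* **Class composition**: exactly `round(n * positive_fraction)` stabilizing
  mutants (default 836/3366). Per-class ddG is drawn from truncated normals
  (positive class > 0, negative class < 0) with the location parameter
  moment-matched so the post-truncation class means equal the configured
  1.50 and -1.77 kcal/mol; nominal sds 1.36 / 1.03; values clipped to the
  [-12.23, 13.7] envelope. Truncation makes the class-conditional signs
  correct by construction.
* **Site counts**: 1..9 with proportions 2765:441:93:67 for 1/2/3/>=4 (the
  >=4 mass spread 47/10/4/3/2/1 over 4..9). Counts are assigned by noisy
  ranking of |ddG| so that mean |ddG| increases with the number of sites,
  mirroring the reported 1.50 / 1.94 / 2.04 / 2.28 kcal/mol progression.
* **Signal**: the latent signal is `tanh(ddG / 4)` — monotone and
  saturating. The scale 4 was chosen a priori so the transform stays
  resolvable across the dataset's ddG spread (a steeper squash would make
  large |ddG| values indistinguishable and cap noiseless recovery below the
  r >= 0.95 the generator contract promises). It enters the configured
  V-block columns (default z1..z6) as the standardized sum of signal and
  Gaussian noise with sd `noise_scale` times the signal sd (so
  `noise_scale = 1` is signal-to-noise 1); each Y-block column is the
  midrank percentile of its V partner, preserving the V/Y coupling of real
  encodings; all other columns are pure noise.

What the generator does **not** emulate: real energy-function feature
distributions, inter-feature correlations of physical origin, protein
family structure, or measurement error in ddG. A green recovery test
establishes that the pipeline's statistics behave as designed — not that
the geometric feature backend approximates any particular energy model.

`generateToyStructure()` builds ideal alpha-helices (rise 1.5 A, twist 100
degrees per residue, N/CA/C/O/CB atoms) whose i -> i+4 backbone O..N
contacts are genuine geometric H-bonds; they serve as self-contained PDB
stand-ins.

# Numerical and design choices

* **Feature backend**: the built-in formulas are *declared stand-ins* for
  external energy calculators (which are licensed software and out of
  scope). They are pure functions of distances and angles, hence invariant
  under rigid motion, and the backend is pluggable: `loadFeatureTable()`
  accepts precomputed 29-feature TSVs, and `backgroundStats()` /
  `encodeDataset()` accept any `function(structure) -> numeric(29)`.
* **Distance-bin normalization**: the frequency denominator is all
  non-covalent heavy-atom pairs closer than 6 A (pairs in [3.3, 6) count
  only in the denominator). The cutoff keeps the 13 shares comparable
  across protein sizes; the upstream description does not fix a
  normalization, so this one is the package's own.
* **Covalency rule**: heavy-atom pairs closer than 1.9 A (2.2 A with
  sulfur) are treated as bonded and excluded from non-covalent counts.
* **Mutant stand-in geometry**: a mutated residue keeps backbone + CB (CB
  synthesized at ideal tetrahedral geometry when absent) and represents the
  new side chain as a single pseudo-atom at the residue-type mean
  side-chain length along CA -> CB; ensemble diversity is Gaussian jitter
  (sd 0.15 A) on mutated-residue atoms only. No rotamer optimization or
  energy minimization is attempted.
* **Encoding definitions**: the z-score (V) and midrank percentile (Y)
  against the saturation background are this package's definitions of the
  two 29-element blocks; they are the two natural inequivalent scale-free
  normalizations of "this mutant relative to all possible single mutants".
  Population (not sample) standard deviation is used — the pool is the full
  enumerated population — and S = 0 maps v to 0.
* **Background size**: `k_background = 1` model per background mutant by
  default; the background only estimates means, spreads and ranks, and
  l x 19 structures already pool hundreds of models for realistic l.
* **SVM probability**: the mapping from decision values to O is not fixed
  by the protocol this package follows; a logistic fit on training decision
  values was chosen as the simplest monotone calibration.
* **QP solvers**: SVM/SVR are solved exactly with an active-set QP solver;
  cost is O(n^3), so forests are preferred for thousands of mutants. Tests
  train SVMs on subsamples for runtime only.
* **Saturation count**: l x 19 single-site mutants per protein (19
  non-wild-type substitutions at each of l standard positions);
  non-standard residues are kept for geometry but never mutated.

# Known limitations

* The geometric feature backend claims only the pipeline contract
  (29 finite, rigid-invariant, deterministic features), not agreement with
  any physical energy function; headline accuracies published for
  energy-calculator-based features are not reproducible with it.
* With the default gamma = 2 on 58-dimensional inputs the RBF kernel is
  narrow; the SVM then behaves nearest-neighbour-like and its calibration
  can be extreme. The forests are the robust default.
* The toy helix generator produces idealized geometry; it exists for
  self-contained testing, not biophysical realism.

# A worked example

```{r example, eval = FALSE}
library(ThermoShift)

# a self-contained "wild type" and two mutants of it
wt <- generateToyStructure(30, seed = 1)
writePDB(wt, "wt.pdb")

records <- data.frame(
  protein_id = "toy",
  mutation_spec = c("A:M1A", "A:M1W"),   # adjust to the sampled sequence
  ddg = c(NA, NA))

# training world and model
world <- generateDataset(syntheticConfig(n_mutants = 2000, seed = 7))
model <- trainClassifier(world$data, world$data$ddg > 0,
                         thermoParams("rf", n_trees = 300, seed = 7))

# cross-validated quality of that model family on this world
cv <- crossValidate(world$data, thermoParams("rf", n_trees = 300, seed = 7),
                    folds = 10, seed = 7)
cv$metrics
cv$stratified$by_abs_ddg
```
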