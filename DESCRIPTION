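Package: ThermoShift
Title: Predicting Protein Thermostability Changes from Single- or
    Multi-Site Mutations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Structure-based prediction of the sign and magnitude of the
    change in free energy of thermal denaturation (ddG, kcal/mol) caused
    by single- or multi-site protein mutations. Mutant structures are
    modelled from a wild-type PDB file, summarised as 29 structural
    features, and normalised against an in-silico single-site saturation
    mutagenesis background of the same protein to give a 58-element input
    vector. Imbalance-aware random forests (down-sampling) and weighted
    RBF support vector machines classify the sign of ddG; random forest
    regression and support vector regression predict its value. Includes
    a reliability index for classifier confidence, a stratified
    cross-validation evaluation harness (Q2, MCC, sensitivity,
    specificity, Pearson r, ROC/AUC, permutation variable importance) and
    a synthetic data generator emulating the class imbalance of curated
    thermostability datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    quadprog,
    truncnorm,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'ThermoShift-package.R'
    'constants.R'
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'pdb.R'
    'mutations.R'
    'features.R'
    'encoding.R'
    'forest.R'
    'svm.R'
    'models.R'
    'evaluation.R'
    'synthetic.R'
    'RcppExports.R'
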