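Package: scAdvTrain
Title: Adversarial Training and Consensus Interpretability for Single-Cell
    Cell-Type Classifiers
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study how adversarial training changes the robustness
    and interpretability of neural-network cell-type classifiers for
    single-cell RNA-seq data. Provides a ground-truth expression simulator
    with designated key (master-regulator) genes per cell type, standard
    preprocessing (depth normalisation, log transform, per-gene scaling,
    highly variable gene selection, stratified splitting), a differentiable
    multilayer perceptron classifier exposing input gradients, FGSM and PGD
    adversarial attacks with epsilon selection by attacked accuracy and
    k-nearest-neighbour structure preservation, adversarial training, six
    gradient- and perturbation-based gene attribution methods (saliency,
    activation maximization, DeepLIFT rescale, expected gradients, kernel
    SHAP, LIME), a consensus importance vote across methods, key-gene
    recovery evaluation against the simulator's ground truth, and a
    Wilcoxon rank-sum differential-expression baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
biocViews: SingleCell, Classification, GeneExpression, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
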