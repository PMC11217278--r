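Package: subparc
Title: Connectivity-Based Nigrostriatal Parcellation and Diffusion Microstructure Biomarkers
Version: 0.1.0
Authors@R:
    person("subparc", "developers", email = "subparc@example.org", role = c("aut", "cre"))
Description: Tools for connectivity-based parcellation of subcortical structures
    (substantia nigra pars compacta, ventral tegmental area, striatum) and extraction
    of diffusion MRI microstructure biomarkers. Builds triangulated surfaces from
    probabilistic atlas volumes, assigns surface vertices to cortical-connectivity
    subregions by winner-take-all streamline voting, computes bundle and surface mean
    diffusivity (MD) and fractional anisotropy (FA) features, and evaluates them with a
    Levene-gated ANCOVA / Kruskal-Wallis battery with family-wise correction, BIC-based
    Bayesian equivalence tests, Spearman clinical correlations, and class-balanced
    random-forest single-subject classification with cross-validated hyperparameter
    search, bootstrap stability, and ROC analysis. A synthetic phantom and cohort
    generator with known ground truth makes every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
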