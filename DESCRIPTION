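Package: dosagecomp
Title: Evolution of Sex-Chromosome Dosage Compensation Under Sexually Antagonistic Selection
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Population-genetic models of the evolution of dosage compensation on X and
    Z chromosomes, where expression of a sex-linked gene evolves by the recurrent
    fixation of cis-regulatory mutations with sexually correlated effects under
    sex-specific Gaussian stabilizing selection. Provides the linearized sex-linked
    fixation probability, deterministic expected trajectories (closed form and
    numeric, with dominant-mutation and gradual-degradation variants), stochastic
    trajectories by Euler-Maruyama with harem-polygyny effective population sizes, and
    an individual-based Wright-Fisher simulator used as a brute-force oracle. Also
    implements a transcriptome analysis of dosage compensation: TMM normalization on
    autosomal genes, RPKM, expression filtering, negative-binomial biological
    coefficient of variation (BCV) with shrinkage, projection of sex-specific BCV onto
    concordant-selection and sex-bias axes, and linear models of male-to-female
    expression ratio, together with a negative-binomial synthetic count generator with
    planted ground truth for end-to-end positive and negative controls.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    edgeR,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
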