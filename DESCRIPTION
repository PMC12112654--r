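Package: famerv
Title: Endophenotype-Informed Variance-Component Linkage in Family Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Family-based quantitative-genetic analysis built around pedigree
    kinship: maximum-likelihood variance-component estimation of heritability,
    bivariate genetic correlation and the endophenotype ranking value (ERV),
    univariate and bivariate quantitative-trait-locus (QTL) linkage with LOD
    scoring on a centimorgan grid, and targeted measured-genotype association
    with dosage covariates inside the polygenic model. Includes a
    gene-dropping simulator that produces pedigrees, genotypes, exact
    identity-by-descent matrices and phenotypes with known variance
    components, so the whole pipeline can be exercised against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
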