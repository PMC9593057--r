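Package: droughtsel
Title: Seedling-Stage Drought Screening and Multi-Trait Selection for Wheat Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for seedling-stage drought screening of diverse
    wheat panels grown in randomized complete block designs. Provides trait
    scoring transforms (summed leaf-wilting scores, days to wilting, arctangent
    regrowth disposition, drought survival rate), RCBD and two-factor analyses
    of variance with variance components, entry-mean broad-sense heritability
    and least significant differences, Spearman phenotypic and mean-cross-product
    genotypic correlations, Smith-Hazel selection indices with a composite
    drought tolerance index, multi-trait top-k selection, drought-induced
    physiological change metrics, simple-matching SNP distances with UPGMA
    dendrograms, and synthetic-data generators that emulate the statistical
    structure of such experiments for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
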