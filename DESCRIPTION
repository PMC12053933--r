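Package: glycodiff
Title: Differential Proteomics and Site-Specific N-Glycoproteomics of
    Tumor Versus Adjacent Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for label-free differential
    proteomics and site-specific N-glycoproteomics of paired tumor and
    adjacent-normal tissue. Parses N-glycan compositions in F/H/N/S
    nomenclature, classifies them (high-mannose, paucimannose, hybrid,
    complex), and computes abundance-weighted sialylation,
    galactosylation and fucosylation metrics. Provides the glycopeptide
    filtering cascade (MS1/MS2 score cutoffs, sample-presence filter),
    an adaptive two-sample test (Student, Welch or Wilcoxon, gated by
    Shapiro and Levene pre-tests) with Benjamini-Hochberg FDR control,
    and a glycopeptide/protein fold-change overlay that attributes
    glycopeptide changes to expression or glycosylation. The proteomics
    arm implements Reverse/Contaminant and presence filtering,
    left-censored (QRILC-style) missing-value imputation,
    empirical-Bayes moderated t-statistics, and preranked gene set
    enrichment on the t-statistic ranking. A synthetic-data generator
    emulates search-engine output tables with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    fgsea,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
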