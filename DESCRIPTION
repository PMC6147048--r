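Package: molytrait
Title: Comparative Genomics of Molybdenum Utilization Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers molybdenum (Mo) and tungsten (W) utilization traits from
    tabular homology-search output and per-organism metadata. Filters hits by
    e-value and query coverage, assigns proteins to curated seed families via
    best and bidirectional best hits with exclusion seeds (NuoG, NifE), calls
    the molybdenum cofactor (Moco) biosynthetic pathway from the seven key
    genes (moaA, moaC, moaD, moaE, moeB, moeA, mogA) with a three-step rule,
    derives per-organism Mo-utilization categories, transporter repertoires
    (ModABC, WtpABC, TupABC, MOT1, MOT2), molybdoproteome sizes and
    tungstoprotein predictions, detects domain fusions on molybdoproteins,
    flags horizontal gene transfer by neighbor-joining gene-tree incongruence,
    and summarises trait-by-environment proportions with exact binomial
    confidence intervals. Includes a synthetic-community generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    phangorn,
    purrr,
    rlang,
    seqinr,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
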