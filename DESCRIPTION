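Package: eldar
Title: Latent DNA-Methylation Signatures of Aging, Passaging, and Reprogramming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds unsupervised latent DNA-methylation signatures (ELDAR)
    from pooled aging, serial-passaging, OSKM-reprogramming, and
    transformation cohorts; screens components against each cohort's time
    axis to separate a shared aging signal (reversed by reprogramming) from
    a refractory one (not reversed); projects the signatures onto new
    cohorts; and characterizes their CpGs through island-relation and
    chromatin-state fold enrichment and overlap with published epigenetic
    clock CpG sets. Includes a two-factor synthetic-cohort generator with a
    ground-truth ledger for recovery testing, population-doubling
    bookkeeping, and an end-to-end reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
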