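Package: absquant
Title: Absolute Microbiome Quantification by Integrated qPCR and Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts 16S rRNA amplicon relative abundances into per-taxon
    absolute abundances (copies per gram) by combining them with qPCR total
    bacterial quantities, the integrated high-throughput absolute abundance
    quantification (iHAAQ) approach. Includes qPCR standard-curve calibration
    with replicate and non-detect quality control, 16S copy-number correction
    to genome equivalents, spike-in internal-reference validation by log-log
    regression and a Levene/Tukey/Tamhane ANOVA chain, relative-versus-absolute
    trend-discordance analysis between time points, sample clustering for
    heatmaps, and a synthetic spike-in experiment generator with known ground
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    biomformat,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
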