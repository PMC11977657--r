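Package: seedscape
Title: MicroRNA Seed-Complementary-Region Enrichment Landscapes over Ranked
    Gene Lists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects microRNA target signatures in ranked differential
    expression experiments. Derives the DNA words complementary to elements of
    a microRNA 1-8 nt seed region (seed complementary regions, SCRs), scans a
    3'UTR universe for them, computes binned hypergeometric
    enrichment/depletion landscapes over ranked gene lists, integrates
    per-element curves into a single summed significance score (SSSS), and
    selects a leading-edge cut by change-point delta value (CPDV)
    maximisation. Companion tools build SCR-containing target gene lists with
    set-algebra summaries and hypergeometric over-representation analysis,
    prepare probe-level expression matrices (negative-control detection
    filtering, gene-level collapse and ranking, Benjamini-Hochberg
    adjustment, delta-delta-Ct relative quantification), and score
    bisulphite-pyrosequencing methylation cumulatively with beta/M-value
    conversion and region probe-count filtering. A seeded synthetic-data
    module generates 3'UTR universes with spiked words, ranked expression
    experiments, two-group methylation tables and qPCR Ct panels with known
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    fgsea,
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
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
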