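Package: onetubeSDM
Title: One-Tube Site-Directed Mutagenesis Design and Screening Statistics
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Design of standardized fixed-length (n+3+n) mutagenic primer pairs
    for whole-plasmid inverse-PCR site-directed mutagenesis, including
    alanine-scanning series and single-site multiple-substitution sets with
    minimal-mismatch codon choice, GC/Tm annotation (QuikChange convention) and
    restriction-site gain/loss diagnostics.  Plans one-tube reaction pools
    (template mixes, scanning pools, multisite pools) and predicts double-mutant
    feasibility from primer-window overlap.  Computes exact
    (inclusion-exclusion, multinomial and multivariate hypergeometric) and
    simulated coverage probabilities for colony screening, minimum-colony
    calculators, and evaluates screening outcomes (success rates,
    mismatch-class recovery, iterative-round unions) on bundled example
    datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
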