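Package: degenlib
Title: Design and Budgeting of Degenerate-Codon Saturation-Mutagenesis Libraries
Version: 0.1.0
Authors@R:
    person("Library", "Design Toolkit", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for planning single-position saturation-mutagenesis
    experiments with degenerate codons (NNN, NNK, NNM and any other IUPAC
    scheme): amino-acid variant distributions, library-completeness
    probabilities and minimum screening sizes, coupon-collector statistics
    with unequal variant probabilities, Monte Carlo simulation of random
    clone picking, cost-optimal switching between random screening and
    one-by-one site-directed mutagenesis, and QuikChange-style degenerate
    and completion primer design.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
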