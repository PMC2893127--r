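Package: peaktriad
Title: Control-Free ChIP-Seq Peak Calling from Three Lines of Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies transcription-factor binding regions from ChIP-Seq tag
    data without a matched input control. Genome-wide window counts are fitted
    to a zero-truncated Gamma-Poisson (negative binomial) background and
    thresholded by an empirical false discovery rate; candidate regions are
    then scored by the tag count at the regional peak, by wavelet-smoothed
    matching of the forward-minus-reverse strand-shift pattern against a
    simulated reference, and by de novo motif discovery (zero-or-one-occurrence
    EM) with exact position weight matrix p-values. The three scores are
    rescaled, averaged and used to re-rank regions under a two-step empirical
    FDR rule. A fully labelled synthetic-data generator (genome, tags, truth
    table, confounders) makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
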