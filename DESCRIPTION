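Package: hydroxyFA
Title: Bacterial 3-Hydroxy Fatty Acid Profiles and Temperature/pH Proxy Indices
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing 3-hydroxy fatty acid (3-OH FA) distributions
    in Gram-negative bacterial cultures and environmental samples. Parses the
    common fatty-acid naming dialects (iso/anteiso/normal branching, chain
    length, unsaturation, 3-hydroxylation), normalizes GC-MS peak areas to
    closed relative-abundance compositions, semi-quantifies compounds against
    a deuterated injection standard, and computes the branching-ratio proxy
    indices RIAN, RAN15 and RAN17 together with class totals. Includes
    replicate-level trend statistics (single linear regressions, Spearman
    correlations, one-way ANOVA with Tukey post-hoc tests, and inverse
    calibration), a synthetic culture-series generator with known injected
    branching-class trends for end-to-end validation, packaged reference
    tables for three soil Bacteroidetes strains grown across temperature and
    pH gradients, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
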