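Package: attnstate
Title: Attentional-Spotlight Decoding and Behavioral-State Analysis of
    Prefrontal Population Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis chain linking multi-unit prefrontal population
    activity to covert spatial attention and latent behavioral states.
    Provides a ridge-regression (regularized optimal linear estimator)
    decoder of the attentional spotlight with rolling train/test and
    target-to-attention distance summaries, per-unit attention and
    outcome modulation indices with mixed-selectivity classification,
    trial-type spike-count noise correlations, a from-scratch demixed
    principal component analysis (marginalization, regularized
    encoder/decoder estimation, explained variance, axis decoding with
    permutation chance, component overlap, and component-removal
    back-projection), and a Poisson population simulator with planted
    slowly drifting optimality and responsiveness states for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
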