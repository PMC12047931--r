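Package: camap
Title: Cellular Aging Maps from Masked-Token Models of Single-Cell Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies aging-related dissipation in single-cell
    transcriptomes with a compact masked-language model over expression-bin
    and metadata tokens. Provides a seeded synthetic corpus generator with
    planted conservative and dissipative gene dynamics, a transformer
    encoder trained by masked-token prediction, per-gene embedding-drift
    trajectories across age bins, percentile-threshold classification of
    genes into conservative and dissipative sets, healthy-versus-diseased
    drift contrasts, a masked-age-token aging clock with z-scored age gaps,
    and Shannon-entropy profiles of masked-token predictions conditioned on
    age.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
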