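Package: tonalEntropy
Title: Transitional Probabilities and Conditional Entropy of Melody and Bass Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Corpus analysis of symbolic music from an information-theoretic
    viewpoint. Extracts melody (highest-pitch) and bass (lowest-pitch) event
    sequences from MusicXML scores, encodes them as transposition-invariant
    interval patterns, estimates zeroth- to fifth-order Markov transitional
    probability distributions, and derives information content and conditional
    entropy per piece and voice. Includes correlation-matrix principal
    component analysis of transition-type profiles across pieces and voices,
    melody-bass and major-minor entropy correlation analyses, and a seeded
    synthetic two-voice corpus generator with analytically known entropies so
    the whole pipeline can be validated without external scores.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'score-io.R'
    'encoding.R'
    'markov.R'
    'components.R'
    'entropy-stats.R'
    'synthetic.R'
    'musicxml-write.R'
    'pipeline.R'
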