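Package: infoGEM
Title: Information-Theoretic Evaluation of Gene-Regulation Experiments with
    Thermodynamic Model Ensembles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds ensembles of GEMSTAT-style thermodynamic
    sequence-to-expression models that fit a target expression profile,
    places a cluster-balanced Gaussian-mixture probability distribution over
    the ensemble, and scores perturbation experiments (transcription-factor
    knockout, binding-site mutagenesis, variant enhancers) by the entropy
    reduction (information gain) they induce when models inconsistent with
    the experimental outcome are filtered out. Includes a synthetic-data
    generator emulating dorso-ventral patterning scenarios of the early
    Drosophila embryo so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    mclust,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: GeneRegulation, Transcription, MotifAnnotation, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
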