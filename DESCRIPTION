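Package: aadtrf
Title: Auditory Attention Decoding with Boosted Temporal Response Functions
Version: 1.0.0
Authors@R:
    person("Morgan", "Larsson", email = "aadtrf@posteo.net", role = c("aut", "cre"))
Description: Tools for modelling neural tracking of speech in multichannel
    EEG with temporal response functions (TRFs). Implements gammatone-based
    acoustic envelope and onset features, a deterministic FIR preprocessing
    chain (rereferencing, notch, zero-phase bandpass, resampling,
    normalization), sparse boosting estimation of forward (encoding) and
    backward (decoding) TRFs on a Hamming basis, leave-one-trial-out
    attention classification over decision windows, sliding optimal-lag
    analysis, and mass-univariate statistics with threshold-free cluster
    enhancement and permutation control. Includes a synthetic-session
    generator emulating sustained-, switching- and conversation-attention
    listening protocols so the full pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    data.table,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
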