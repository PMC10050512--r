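Package: thetagamma
Title: Neural Mass Model of Working Memory with a Theta-Gamma Code
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a four-layer network of oscillating neural masses that
    maintains items in working memory, reconstructs items from partial cues,
    segments several simultaneous items in the gamma band, and replays stored
    item sequences as gamma bursts nested in a theta rhythm. Each cortical
    column is a four-population mass model (pyramidal cells, excitatory
    interneurons, slow and fast GABAergic interneurons) with second-order
    synaptic kernels. Lateral synapses are formed by Hebbian and anti-Hebbian
    rules with incoming-sum normalization. Includes pattern generators for
    orthogonal and overlapping feature collections, declarative stimulation
    protocols (maintenance, sequence recovery, semantic segmentation,
    pathological perturbations, noise-driven "dreaming"), and a metrics suite
    (spectral peak frequencies, recognition events, trial batteries, sequence
    decoding, phase precession).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
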