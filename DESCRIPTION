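Package: repgenr
Title: Generative Modeling of V(D)J Recombination and Somatic Hypermutation
Version: 0.1.0
Authors@R:
    person("Repertoire", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A generative-probabilistic engine for immune receptor (TCR/BCR)
    repertoires. Learns V(D)J recombination statistics (gene usage, deletion
    and insertion profiles, insertion nucleotide bias) and context-dependent
    somatic hypermutation models from sequencing reads by sparse
    expectation-maximization over enumerated recombination scenarios;
    probabilistically annotates reads with ranked scenarios, read likelihoods
    and generation probabilities (Pgen); and simulates synthetic repertoires
    with ground-truth scenarios. Recombination models are Bayesian networks
    over elementary events (segment choices, deletions including P-nucleotide
    negative deletions, junctional insertions with Markovian nucleotide
    identity), configurable for VJ (e.g. TRA) and VDJ (e.g. TRB, IGH) loci.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
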