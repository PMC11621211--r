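Package: squigglecall
Title: Conformer-CTC Basecalling for Nanopore Direct RNA with a Squiggle Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Training and inference for a convolution-augmented Transformer
    (Conformer) basecaller for nanopore direct-RNA sequencing signals.
    The encoder combines a three-layer convolutional frontend with
    relative-position multi-head self-attention (Transformer-XL shift) and
    gated depthwise-separable convolution blocks, trained under a joint
    connectionist temporal classification (CTC) and Kullback-Leibler
    divergence objective with paired causal forward/reverse decoders.
    Includes a k-mer pore-model squiggle simulator emitting Taiyaki-style
    mapped-signal HDF5, med-MAD signal normalization and chunking, greedy and
    prefix-beam CTC decoding with overlap stitching, and alignment-based
    identity/mismatch/insertion/deletion evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    yaml,
    stats,
    utils,
    Biostrings
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: HDF5 (libhdf5)
Config/testthat/edition: 3
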