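Package: ldnspike
Title: Spiking Time-Series Classification with Legendre Delay Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Two spiking neural-network architectures for univariate
    time-series classification built on the Legendre Delay Network (LDN),
    a linear time-invariant system whose d-dimensional state optimally
    compresses the recent history of a scalar signal. The LSNN model feeds
    exactly computed LDN features through paired rate-encoding
    integrate-and-fire neurons, a spiking hidden layer, and leaky output
    integrators, and is trained by backpropagation through time with a
    fast-sigmoid surrogate spike derivative. The SLRC model implements the
    LDN itself with Neural Engineering Framework ensembles of
    integrate-and-fire neurons and learns an L2-regularized least-squares
    readout. Includes zero-order-hold discretization utilities, delay
    decoders, UCR-archive readers (.ts, TSV, ARFF), a synthetic fixture
    generator, a grid-search trainer with Max/Mean accuracy accounting,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    foreign
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
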