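Package: astroattention
Title: Neuron-Astrocyte Circuits That Compute Transformer Self-Attention
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a feed-forward neuron-astrocyte network with
    writing and reading phases that reproduces the softmax self-attention
    operation of a Transformer block. Hebbian outer-product plasticity
    stores value/key associations in tripartite synapses, presynaptic
    plasticity accumulates neuron-to-astrocyte weights, and the spatially
    averaged astrocyte calcium level divisively normalizes the readout.
    Includes random feature maps (cosine and positive exponential) that
    approximate the exponential dot-product kernel, an exact softmax
    attention reference, a shunting-inhibition control circuit, and
    desk-scale convergence and astrocyte-trace experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
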