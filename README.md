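# astroattention

Simulates a neuron–astrocyte circuit that computes the softmax
self-attention operation at the heart of Transformer networks, for
computational neuroscientists and machine-learning researchers studying
how attention-like computation could be realized by biological hardware.

Astrocytes — glial cells whose fine processes ensheathe most synapses,
forming *tripartite* synapses — signal via intracellular calcium rather
than spikes, and can multiplicatively scale the synapses they wrap. This
package implements a three-layer perceptron (`f`, `h`, `l`) in which the
hidden-to-output synapses `H` are tripartite, and shows by direct
simulation that its writing/reading dynamics reproduce a Transformer
attention block.

## The model

Softmax self-attention with residual, for tokens `X ∈ R^{d×N}` and
projections `K = W_K X`, `Q = W_Q X`, `V = W_V X`:

    L = V softmax(Kᵀ Q) + X,     α_i(t) = exp(k_iᵀ q_t) / Z_t,
    Z_t = Σ_j exp(k_jᵀ q_t).

The circuit computes this in two phases, gated by a binary signal `r`:

* **Writing (r = 0):** tokens stream in; Hebbian plasticity accumulates
  `H = η_H V φ(K)ᵀ` (default `η_H = 1/m`) and presynaptic plasticity
  accumulates the neuron-to-astrocyte weights `g = Σ_j φ(k_j)`.
* **Reading (r = 1):** the hidden layer carries `φ(q_t)`; the astrocyte
  processes spatially average to the scalar `p = (1/m) gᵀ φ(q_t)` and
  modulate every synapse in `H` by `1/p`, giving

      l_t = (1/p) H φ(q_t) + x_t
          = V φ(K)ᵀ φ(q_t) / (φ(q_t)ᵀ Σ_j φ(k_j)) + x_t.

That last expression is kernelized (linear-Transformer) attention — an
exact algebraic identity of the circuit. When the hidden nonlinearity is
a random feature map with `φ(x)ᵀφ(y) ≈ exp(xᵀy)` (a cosine
random-Fourier map or a positive exponential map, both provided), the
output converges to softmax attention as the hidden width `m` grows, and
`m·p_t` is an unbiased estimate of the normalizer `Z_t`. A
shunting-inhibition control circuit (an inhibitory neuron `R = gᵀh` in
place of the astrocyte) implements the identical forward pass.

## Worked example

The smallest instructive instance: two tokens `x1 = (1,0)`, `x2 = (0,1)`
with identity key/query/value weights. The logits for query 1 are
`(1, 0)`, so its attention weights are `(e, 1)/(1+e)`:

```r
library(astroattention)
demo_two_tokens(m = 4096, seed = 0)
#> Two-token worked example (identity weights, x1 = (1,0), x2 = (0,1))
#> exact attention weights, column 1: (0.7311, 0.2689)
#> exact output + residual, column 1: (1.7311, 0.2689)
#> circuit output (positive_exp, m = 4096),  column 1: (1.7022, 0.2978)
#> relative Frobenius error: 0.01812
```

The exact weights are `e/(1+e) = 0.7311` and `1/(1+e) = 0.2689`; the
first output column adds the residual `x1`. The circuit, run with 4096
positive-exponential random features, lands within about 2% of the exact
attention output — the gap is pure Monte-Carlo kernel error and shrinks
like `1/sqrt(m)`:

```r
sw <- error_sweep(d = 8, D = 8, N = 16, m_values = c(8, 64, 512),
                  n_seeds = 5, map_kind = "positive_exp", base_seed = 1)
aggregate(rel_error ~ m, sw, median)
#>     m rel_error
#> 1   8 0.2494260
#> 2  64 0.1710927
#> 3 512 0.1006319
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/astroattention` (subcommands `sweep`, `traces`, `demo`).

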