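---
title: "A neuron–astrocyte circuit that computes softmax self-attention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A neuron–astrocyte circuit that computes softmax self-attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astroattention)
```

## The model

A Transformer self-attention block maps a matrix of token embeddings
$X \in \mathbb{R}^{d \times N}$ (column $t$ is the token $x_t$) to

$$
L = V\,\mathrm{softmax}(K^\top Q) + X,
\qquad K = W_K X,\; Q = W_Q X,\; V = W_V X,
$$

where the softmax is taken down each column, so each output column is a
convex combination of value vectors plus a residual. The attention weight
of key $i$ for query $t$ is
$\alpha_i(t) = e^{k_i^\top q_t} / \sum_j e^{k_j^\top q_t}$; the denominator
$Z_t = \sum_j e^{k_j^\top q_t}$ is the softmax normalizer. No temperature
factor is applied inside the softmax; `softmax_self_attention()` matches
this form exactly (the feed-forward and layer-normalization stages that
complete a full Transformer block act per token and are out of scope here;
the modelled object is attention plus its residual).

This package simulates a three-layer neuronal circuit with an astrocyte
that computes the same quantity. The layers are `f` (input, dimension
$d$), `h` (hidden, width $m$), and `l` (output, dimension $d$). The
hidden-to-output synapses form a plastic matrix $H \in \mathbb{R}^{d\times m}$
whose every entry is a *tripartite* synapse: it is ensheathed by an
astrocyte process with calcium level $p_{i\alpha}$. A binary gate $r$
switches the circuit between a **writing phase** ($r = 0$) and a
**reading phase** ($r = 1$):

$$
f = x,\qquad
h = \phi\!\big[(1 - r)\,W_K f + r\,W_Q f\big],\qquad
l = r\,\tfrac{1}{p} H h + (1 - r)\,W_V f + r f .
$$

* **Writing** ($r=0$): tokens stream in one at a time. The output layer
  carries the value $v_t = W_V x_t$ and the hidden layer carries
  $\phi(k_t)$. Two local plasticity rules update the state: a Hebbian
  outer product $H \leftarrow H + \eta_H\, v_t\, \phi(k_t)^\top$ (default
  rate $\eta_H = 1/m$), and presynaptic plasticity on the
  neuron-to-astrocyte weights, $g \leftarrow g + \phi(k_t)$. Because the
  presynaptic increment does not depend on the postsynaptic neuron, the
  $d \times m$ astrocyte weights collapse to a single $m$-vector $g$.
  After $N$ tokens, $H = \eta_H V\,\phi(K)^\top$ and
  $g = \sum_j \phi(k_j)$ — both are order-invariant sums.
* **Reading** ($r=1$): the hidden layer carries $\phi(q_t)$. Each
  astrocyte process responds with $g_\alpha h_\alpha$, and spatial
  averaging across nearby processes makes them all equal to the scalar
  $p = \frac{1}{m} g^\top h = \frac{1}{m}\sum_j \phi(k_j)^\top \phi(q_t)$.
  The released gliotransmitter modulates every tripartite synapse by the
  common factor $1/p$, so the output is

$$
l_t = \frac{1}{p} H\,\phi(q_t) + x_t
    = \frac{V\,\phi(K)^\top \phi(q_t)}{\phi(q_t)^\top \sum_j \phi(k_j)} + x_t .
$$

This is **kernelized (linear-Transformer) attention plus residual** — an
algebraic identity, independent of what $\phi$ is. If additionally
$\phi(x)^\top\phi(y) \approx e^{x^\top y}$, the kernel weights approximate
the exponentiated logits and $L \approx \mathrm{SelfAttn}(X) + X$. The
circuit therefore approximates softmax attention with error that comes
*only* from the kernel approximation, and the rescaled astrocyte trace
$m\,p_t$ is an unbiased estimator of the softmax normalizer $Z_t$.

Weight tying ($W_Q = W_K$, $W_V = I$) is the simplest instructive case:
then writing is just $l_t = f_t = x_t$ and the same matrix projects both
phases. `make_weights(tied = TRUE)` constructs it; the forward equations
above cover tied and untied weights uniformly, with the tied case arising
purely from the weight values.

## Random feature maps

Two classical constructions give $\mathbb{E}\,\phi(x)^\top\phi(y) = e^{x^\top y}$:

* `cosine_rbf`:
  $\phi(x) = \sqrt{2/m}\; e^{\|x\|^2/2} \cos(\Pi x + b)$, with
  $\Pi_{\alpha j} \sim \mathcal{N}(0,1)$ and $b_\alpha \sim U[0, 2\pi)$
  (random Fourier features for the Gaussian kernel, rescaled by
  $e^{(\|x\|^2+\|y\|^2)/2}$ to turn the RBF kernel into the exponential
  dot-product kernel).
* `positive_exp`:
  $\phi(x) = m^{-1/2}\, e^{-\|x\|^2/2}\, e^{\Pi x}$, elementwise positive,
  so every induced attention weight is non-negative and the astrocyte
  scalar $p$ is strictly positive.

A third kind, `exact_kernel_oracle`, represents the $m \to \infty$ limit:
its kernel is $e^{x^\top y}$ exactly. It has no finite feature vector —
the circuit handles it by storing the written keys and values and
evaluating $H\phi(q)$ and $g^\top\phi(q)$ analytically — and exists so
that every approximation claim can be tested against an exact reference.

`prenormalize = TRUE` projects arguments to the unit sphere first and
drops the norm-dependent prefactors (legitimate because any constant
prefactor on $\phi$ cancels between numerator and denominator of the
attention ratio; the package tests this cancellation explicitly). The
default is off, matching the maps as written above.

**Estimator quality.** The relative variance of the `positive_exp`
estimate of $e^{k^\top q}$ scales like $(e^{\|k+q\|^2} - 1)/m$; the cosine
map's prefactor $e^{(\|k\|^2+\|q\|^2)/2}$ produces a comparable blow-up.
Both are strongly norm-sensitive: doubling the token scale can cost
orders of magnitude in effective sample size. This is the practical
reason attention-as-kernel methods keep logits small, and it drives the
fixture calibration below.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `m` | user-set | hidden width = number of random features; error shrinks like $1/\sqrt{m}$ |
| `eta_H` | `1/m` (astro), `1` (shunting) | Hebbian learning rate on `H` |
| `scale` (tokens) | 1 (generic), 0.5 in experiments | entry s.d. of token embeddings |
| `scale` (weights) | 1 | entries have s.d. `scale/sqrt(d)` (variance-preserving) |
| `prenormalize` | `FALSE` | spherical normalization before the random projection |
| `p_eps` | `1e-300` / `1e-12` | degenerate-normalization guard on `|p|` (or `|R|`) |

The experiment fixtures use token scale 0.5 with unit weight scale so
that key–query dot products stay within roughly $\pm 4$ at $d = D = 16$
($\mathrm{sd}(k^\top q) \approx \sqrt{D}\,\sigma_w^2 \sigma_x^2 = 1$),
keeping $e^{k^\top q}$ well conditioned. The degenerate-normalization
guard is `1e-12` for `cosine_rbf`, whose kernel estimates can cross zero
at small `m`, and `1e-300` (an underflow guard only) for the strictly
positive `positive_exp` and oracle kernels. Rather than clamping an
overflowing $e^{\Pi x}$, `apply_feature_map()` raises an error naming the
offending norm — silent clamping would corrupt the kernel.

## The shunting-inhibition control circuit

The same forward pass can be built without an astrocyte: a single
inhibitory neuron with activity $R = g^\top h$ divisively normalizes the
hidden-layer input to the output layer (shunting inhibition acting on the
dendritic path from `h` but not on the residual path from `f`):
$l = \frac{1}{R} H h + f$. One bookkeeping choice is forced: the
astrocyte circuit carries $1/m$ in both $\eta_H$ and $p$, while
$R = g^\top h$ carries none, so the shunting circuit's Hebbian rate
defaults to $\eta_H = 1$. Either convention (or folding $1/m$ into $R$)
gives identical outputs because the factor cancels in the ratio; the
package fixes $\eta_H = 1$ and verifies astro/shunting equality to
$10^{-12}$ relative on random instances.

## Phase schedule and other design choices

* **Schedule.** The circuit alternates writing and reading; the package
  runs one full writing pass over all $N$ tokens and then one full
  reading pass, which is the schedule under which $H$ and $g$ contain all
  tokens when any token is read, i.e. full (non-causal) attention.
  Interleaved per-token read/write (attention over a growing prefix)
  is deliberately not implemented.
* **Astrocyte relaxation.** Spatial averaging of process calcium is
  treated as instantaneous; no calcium ODE is simulated. The scalar $p$
  is recomputed per read token.
* **The modulation matrix.** Since averaging makes all process values
  equal, the $d \times m$ modulation matrix with entries $1/p_{i\alpha}$
  is represented by the single scalar $1/p$ — materializing the matrix
  would waste memory and invite drift.
* **Softmax stabilization.** The reference softmax subtracts each
  column's maximum logit before exponentiating, which leaves the weights
  exactly invariant (tested) and prevents overflow.
* **Determinism.** Every stochastic constructor takes an explicit seed
  and restores the caller's RNG state; feature maps serialize as a
  `{kind, m, D, prenormalize, seed}` descriptor from which $\Pi$ and $b$
  are regenerated, never stored.

## What the synthetic generator does and does not emulate

All inputs are synthetic: i.i.d. Gaussian tokens and
variance-preserving Gaussian projection weights, with optional spherical
normalization. This reproduces the *structural* conditions of the model
— matched shapes, controlled logit magnitudes, full-rank projections —
and is sufficient for every algebraic claim (circuit = kernelized
attention; astro = shunting; oracle = softmax), for Monte-Carlo
convergence in $m$, and for unbiasedness of the kernel estimates.

It does **not** emulate trained Transformer weights or natural token
statistics. Two consequences matter for interpreting results:

* Trained models produce softmax normalizers $Z_t$ that vary over orders
  of magnitude across tokens; i.i.d. Gaussian fixtures produce
  exchangeable tokens whose $Z_t$ cluster tightly. A Pearson correlation
  between the astrocyte trace $m\,p_t$ and $Z_t$ therefore compares two
  nearly constant series under synthetic fixtures, and its value is
  governed by the ratio of the estimator's noise to that small spread:
  at $d = D = 16$ the noise term $\sqrt{e^{\|k+q\|^2}/m}$ dominates until
  $m$ approaches $10^5$. With the `exact_kernel_oracle` map the
  correlation is identically 1 at any $m$ (tested); with random maps at
  moderate $m$ the package reports the correlation it actually measures
  rather than a figure-matching value.
* Passing tests show the *mechanism* is exact and the *approximation*
  converges; they do not show that desk-scale synthetic error magnitudes
  transfer to trained-weight regimes, where logit norms and hence
  estimator variance differ.

## Problem sizes

The test suite and experiments run at desk scale, chosen as the smallest
sizes at which each property is informative: random instances with
$d, D \in \{2..16\}$, $N \le 32$, $m \le 256$ for the algebraic
identities (which hold at machine precision regardless of size);
$d = D = 16$, $N = 32$, $m \in \{16, 800\}$ with 10 feature-map seeds for
the convergence sweep; $m = 10^3$ with 200 seeds for unbiasedness; and
$d = D = 16$, $N = 50$, $m = 10^4$ for the astrocyte-trace comparison.

## Known limitations

* Single-head attention only; no causal masking, positional encodings,
  feed-forward stage, or layer normalization.
* No biophysical calcium or gliotransmitter dynamics; the read gate `r`
  is an abstract phase switch, not a modelled neuromodulator.
* Only the two printed random feature constructions (plus the exact
  oracle) are provided; variance-reduced feature families (orthogonal
  random features, positive orthogonal features) are out of scope.
* Loading pretrained Transformer weights is out of scope; all claims are
  evaluated on synthetic fixtures.
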