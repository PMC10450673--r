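# Shared helpers: random small circuit instances and error metrics.

rel_frob <- function(A, B) norm(A - B, "F") / norm(B, "F")

max_rel_diff <- function(A, B) {
  max(abs(A - B)) / max(abs(B), .Machine$double.eps)
}

# One random instance of the whole pipeline: tokens, weights, feature map.
# Dimensions are drawn from the given ranges, deterministic in `seed`.
random_instance <- function(seed, kinds = c("cosine_rbf", "positive_exp"),
                            d_range = 2:16, N_range = 1:32,
                            m_range = c(4L, 256L)) {
  set.seed(seed)
  d <- sample(d_range, 1)
  D <- sample(d_range, 1)
  N <- sample(N_range, 1)
  m <- sample(seq(m_range[1], m_range[2]), 1)
  tied <- sample(c(TRUE, FALSE), 1)
  kind <- sample(kinds, 1)
  if (tied) D <- if (stats::runif(1) < 0.5) d else D
  list(
    X = make_tokens(d, N, scale = 0.5, seed = seed + 1L),
    W = make_weights(d, D, tied = tied, seed = seed + 2L),
    fm = sample_feature_map(kind, m = m, D = D, seed = seed + 3L),
    d = d, D = D, N = N, m = m, tied = tied, kind = kind
  )
}
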