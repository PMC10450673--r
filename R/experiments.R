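#' Default synthetic fixtures for the desk-scale experiments
#'
#' Tokens with entry standard deviation 0.5 and projection weights with
#' entry standard deviation `1/sqrt(d)` keep the key-query dot products
#' within a few units, so the exponential kernel stays well conditioned at
#' the dimensions used here.
#'
#' @param d,D,N Dimensions as in [make_tokens()] / [make_weights()].
#' @param base_seed Integer seed; tokens and weights use derived seeds.
#' @param tied Logical, passed to [make_weights()].
#' @param token_scale Entry standard deviation for tokens.
#' @return List with `X` and `W`.
#' @keywords internal
#' @export
default_fixtures <- function(d, D, N, base_seed = 0L, tied = FALSE,
                             token_scale = 0.5) {
  list(
    X = make_tokens(d, N, scale = token_scale, seed = base_seed),
    W = make_weights(d, D, tied = tied, seed = base_seed + 1L)
  )
}

#' Sweep the circuit's approximation error over hidden widths
#'
#' For one fixed set of tokens and weights, runs the neuron-astrocyte
#' block at each hidden width `m` with `n_seeds` independent feature maps
#' and records the relative Frobenius error
#' `||L_circuit - L_softmax||_F / ||L_softmax||_F` against the exact
#' softmax attention output (residual included). The median error over
#' seeds shrinks roughly as `1/sqrt(m)`; in practice the two networks
#' agree closely once `m` reaches 5-10 times the embedding dimension.
#'
#' @param d,D,N Fixture dimensions.
#' @param m_values Ascending integer vector of hidden widths.
#' @param n_seeds Feature-map seeds per width.
#' @param map_kind `"cosine_rbf"`, `"positive_exp"` or
#'   `"exact_kernel_oracle"` (the latter gives zero error at any `m`).
#' @param base_seed Integer seed for fixtures and derived map seeds.
#' @param tied Logical, passed to [make_weights()].
#' @param prenormalize Logical, passed to [sample_feature_map()].
#' @return A data.frame with columns `m`, `seed`, `rel_error` (`NA` with a
#'   message in `note` if a run failed numerically), carrying the fixture
#'   parameters in `attr(, "metadata")`.
#' @examples
#' sw <- error_sweep(d = 4, D = 4, N = 8, m_values = c(8, 64, 512),
#'                   n_seeds = 3, map_kind = "positive_exp", base_seed = 1)
#' stats::aggregate(rel_error ~ m, sw, stats::median)
#' @export
error_sweep <- function(d, D, N, m_values, n_seeds = 10,
                        map_kind = "positive_exp", base_seed = 0L,
                        tied = FALSE, prenormalize = FALSE) {
  if (length(m_values) == 0 || is.unsorted(m_values)) {
    stop("'m_values' must be a non-empty ascending vector", call. = FALSE)
  }
  fx <- default_fixtures(d, D, N, base_seed = base_seed, tied = tied)
  ref <- softmax_self_attention(project(fx$X, fx$W))
  ref_norm <- norm(ref$L, "F")
  rows <- vector("list", length(m_values) * n_seeds)
  idx <- 0L
  for (mi in seq_along(m_values)) {
    for (si in seq_len(n_seeds)) {
      idx <- idx + 1L
      fm_seed <- base_seed + 1000L + (mi - 1L) * n_seeds + si
      res <- tryCatch({
        fm <- sample_feature_map(map_kind, m = m_values[mi], D = D,
                                 prenormalize = prenormalize, seed = fm_seed)
        out <- run_block(fx$X, fx$W, fm)
        list(err = norm(out$L - ref$L, "F") / ref_norm, note = "")
      }, error = function(e) list(err = NA_real_, note = conditionMessage(e)))
      rows[[idx]] <- data.frame(m = m_values[mi], seed = fm_seed,
                                rel_error = res$err, note = res$note,
                                stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "metadata") <- list(d = d, D = D, N = N, map_kind = map_kind,
                                base_seed = base_seed, tied = tied,
                                n_seeds = n_seeds, token_scale = 0.5,
                                prenormalize = prenormalize)
  out
}

#' Compare astrocyte responses with the exact softmax normalizers
#'
#' Runs the circuit on default fixtures and pairs, for each read token
#' `t`, the rescaled astrocyte value `m * p_t` with the exact softmax
#' normalizer `Z_t = sum_j exp(k_j' q_t)` from the reference. Since
#' `m * p_t = sum_j phi(k_j)' phi(q_t)` is an unbiased kernel estimate of
#' `Z_t`, the two series track each other increasingly tightly as `m`
#' grows; with the `exact_kernel_oracle` map they coincide.
#'
#' @param d,D,N Fixture dimensions.
#' @param m Hidden width.
#' @param map_kind Feature-map kind.
#' @param seed Integer seed (fixtures and map).
#' @param tied Logical, passed to [make_weights()].
#' @return A data.frame with columns `token_index`, `astro_value`
#'   (`m * p_t`) and `exact_normalizer` (`Z_t`); attributes `pearson_r`
#'   (NaN when `N < 2`, flagged by attribute `degenerate = TRUE`) and
#'   `metadata`.
#' @export
trace_experiment <- function(d, D, N, m, map_kind = "positive_exp",
                             seed = 0L, tied = FALSE) {
  check_count(m, "m")
  fx <- default_fixtures(d, D, N, base_seed = seed, tied = tied)
  fm <- sample_feature_map(map_kind, m = m, D = D, seed = seed + 2L)
  out <- run_block(fx$X, fx$W, fm)
  ref <- softmax_self_attention(project(fx$X, fx$W))
  df <- data.frame(token_index = seq_len(N),
                   astro_value = out$m_times_p,
                   exact_normalizer = ref$Z)
  degenerate <- N < 2L
  r <- if (degenerate) NaN else
    stats::cor(df$astro_value, df$exact_normalizer)
  attr(df, "pearson_r") <- r
  attr(df, "degenerate") <- degenerate
  attr(df, "metadata") <- list(d = d, D = D, N = N, m = m,
                               map_kind = map_kind, seed = seed, tied = tied)
  df
}

#' Write an experiment result as CSV with a parameter header
#'
#' Prepends `#`-prefixed comment lines recording the full parameters and
#' seeds, then the CSV body. Read back with
#' `read.csv(path, comment.char = "#")`.
#'
#' @param df An [error_sweep()] or [trace_experiment()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_experiment_csv <- function(df, path) {
  meta <- attr(df, "metadata")
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta)) {
    writeLines(sprintf("# %s = %s", nm, format(meta[[nm]])), con)
  }
  r <- attr(df, "pearson_r")
  if (!is.null(r)) writeLines(sprintf("# pearson_r = %s", format(r)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Print the two-token worked example
#'
#' The smallest instructive instance: `d = D = 2`, identity key/query/value
#' weights, tokens `x1 = (1, 0)` and `x2 = (0, 1)`. The logits for the
#' first query are `(1, 0)`, so its attention weights are
#' `(e, 1) / (1 + e) ~ (0.7311, 0.2689)` and the first output column is
#' approximately `(1.7311, 0.2689)` after the residual. Prints the exact
#' softmax values and the circuit's approximation at the requested width.
#'
#' @param m Hidden width for the circuit run.
#' @param map_kind Feature-map kind.
#' @param seed Integer seed.
#' @return Invisibly, a list with `reference` (exact output matrix) and
#'   `circuit` (the circuit's `L`).
#' @export
demo_two_tokens <- function(m = 4096, map_kind = "positive_exp", seed = 0L) {
  X <- diag(2)
  W <- list(W_K = diag(2), W_Q = diag(2), W_V = diag(2))
  ref <- softmax_self_attention(project(X, W))
  fm <- sample_feature_map(map_kind, m = m, D = 2, seed = seed)
  out <- run_block(X, W, fm)
  cat("Two-token worked example (identity weights, x1 = (1,0), x2 = (0,1))\n")
  cat(sprintf("exact attention weights, column 1: (%.4f, %.4f)\n",
              ref$A[1, 1], ref$A[2, 1]))
  cat(sprintf("exact output + residual, column 1: (%.4f, %.4f)\n",
              ref$L[1, 1], ref$L[2, 1]))
  cat(sprintf("circuit output (%s, m = %d),  column 1: (%.4f, %.4f)\n",
              map_kind, m, out$L[1, 1], out$L[2, 1]))
  cat(sprintf("relative Frobenius error: %.4g\n",
              norm(out$L - ref$L, "F") / norm(ref$L, "F")))
  invisible(list(reference = ref$L, circuit = out$L))
}
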