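#' Generate a synthetic token-embedding matrix
#'
#' Draws a `d x N` matrix of token embeddings with i.i.d. Gaussian entries.
#' Column `t` plays the role of the embedded token `x_t` streamed into the
#' circuit at time `t`. With `normalize = TRUE` each column is rescaled to
#' Euclidean norm `scale` ("spherical normalization"), which simplifies the
#' random feature maps because the norm-dependent prefactors become constants.
#'
#' @param d Positive integer, embedding dimension (rows).
#' @param N Positive integer, number of tokens (columns).
#' @param scale Positive numeric. Standard deviation of the entries, or the
#'   common column norm when `normalize = TRUE`. Keep `scale` modest so that
#'   key-query dot products stay within a few units and the exponential
#'   kernel remains well conditioned.
#' @param normalize Logical; rescale every column to norm `scale`.
#' @param seed Integer seed. The generator is a pure function of its
#'   arguments: the same seed gives a bit-identical matrix and the caller's
#'   RNG state is left untouched.
#'
#' @return A numeric `d x N` matrix.
#' @examples
#' X <- make_tokens(4, 8, scale = 0.5, seed = 1)
#' Xs <- make_tokens(4, 8, normalize = TRUE, seed = 1)
#' apply(Xs, 2, function(x) sqrt(sum(x^2)))  # all 1
#' @export
make_tokens <- function(d, N, scale = 1, normalize = FALSE, seed = 0L) {
  check_count(d, "d")
  check_count(N, "N")
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0) {
    stop("'scale' must be a single positive finite number", call. = FALSE)
  }
  X <- withr::with_seed(as.integer(seed), {
    matrix(stats::rnorm(d * N, sd = scale), nrow = d, ncol = N)
  })
  if (isTRUE(normalize)) {
    nrm <- sqrt(colSums(X^2))
    if (any(nrm == 0)) stop("cannot normalize a zero column", call. = FALSE)
    X <- sweep(X, 2, nrm / scale, "/")
  }
  X
}

#' Generate projection weights for keys, queries and values
#'
#' Samples the linear maps that turn a token into its key, query and value
#' vectors: `W_K`, `W_Q` (both `D x d`) and `W_V` (`d x d`). Entries are
#' Gaussian with standard deviation `scale / sqrt(d)` so that the projected
#' vectors have entry variance comparable to the tokens regardless of `d`.
#'
#' In tied mode a single matrix `W` is sampled and used for both `W_K` and
#' `W_Q`, while `W_V` is the `d x d` identity, so values equal the tokens.
#' Tying constrains nothing about `D`: the shared key/query map may still be
#' rectangular.
#'
#' @param d Positive integer, token embedding dimension.
#' @param D Positive integer, internal attention dimension (rows of
#'   `W_K`/`W_Q`).
#' @param tied Logical; tie `W_Q = W_K` and set `W_V = I`.
#' @param scale Positive numeric; entry standard deviation is
#'   `scale / sqrt(d)`.
#' @param seed Integer seed; deterministic, leaves the global RNG untouched.
#'
#' @return An object of class `projection_weights`: a list with elements
#'   `W_K`, `W_Q`, `W_V`, `tied`, `d`, `D`.
#' @examples
#' W <- make_weights(d = 4, D = 6, tied = TRUE, seed = 0)
#' identical(W$W_K, W$W_Q)
#' all(W$W_V == diag(4))
#' @export
make_weights <- function(d, D = d, tied = FALSE, scale = 1, seed = 0L) {
  check_count(d, "d")
  check_count(D, "D")
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0) {
    stop("'scale' must be a single positive finite number", call. = FALSE)
  }
  sd_w <- scale / sqrt(d)
  w <- withr::with_seed(as.integer(seed), {
    if (isTRUE(tied)) {
      W <- matrix(stats::rnorm(D * d, sd = sd_w), nrow = D, ncol = d)
      list(W_K = W, W_Q = W, W_V = diag(d))
    } else {
      list(
        W_K = matrix(stats::rnorm(D * d, sd = sd_w), nrow = D, ncol = d),
        W_Q = matrix(stats::rnorm(D * d, sd = sd_w), nrow = D, ncol = d),
        W_V = matrix(stats::rnorm(d * d, sd = sd_w), nrow = d, ncol = d)
      )
    }
  })
  structure(
    c(w, list(tied = isTRUE(tied), d = as.integer(d), D = as.integer(D))),
    class = "projection_weights"
  )
}

#' @export
print.projection_weights <- function(x, ...) {
  cat(sprintf(
    "projection_weights: d = %d, D = %d, %s\n", x$d, x$D,
    if (x$tied) "tied (W_Q = W_K, W_V = I)" else "untied"
  ))
  invisible(x)
}

#' Round-trip a matrix through delimited text
#'
#' Small fixtures can be written to and read from CSV/TSV, row-major, with a
#' header naming the column index. Intended for inspection and for feeding
#' externally prepared small matrices into the circuit.
#'
#' @param x Numeric matrix.
#' @param path File path.
#' @param sep Field separator, `","` or `"\t"`.
#' @return `write_matrix_txt` returns `path` invisibly; `read_matrix_txt`
#'   returns a numeric matrix.
#' @export
write_matrix_txt <- function(x, path, sep = ",") {
  stopifnot(is.matrix(x), is.numeric(x))
  df <- as.data.frame(x)
  names(df) <- paste0("c", seq_len(ncol(x)))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_txt
#' @export
read_matrix_txt <- function(path, sep = ",") {
  df <- utils::read.table(path, sep = sep, header = TRUE)
  as.matrix(df)
}

# shared argument checks ----------------------------------------------------

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < 1 || x != round(x)) {
    stop(sprintf("'%s' must be a positive integer", name), call. = FALSE)
  }
  invisible(TRUE)
}

check_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x) || !all(is.finite(x))) {
    stop(sprintf("'%s' must be a finite numeric matrix", name), call. = FALSE)
  }
  invisible(TRUE)
}
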