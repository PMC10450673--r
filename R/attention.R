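#' Project tokens into key, query and value vectors
#'
#' Computes `K = W_K X`, `Q = W_Q X` (both `D x N`) and `V = W_V X`
#' (`d x N`). In tied mode `K == Q` and `V == X`.
#'
#' @param X Numeric `d x N` token matrix (see [make_tokens()]).
#' @param W A [make_weights()] object, or any list with conformable
#'   `W_K`, `W_Q`, `W_V`.
#' @return An object of class `kqv_projection`: list with `K`, `Q`, `V`
#'   and the original `X`.
#' @export
project <- function(X, W) {
  check_matrix(X, "X")
  if (ncol(W$W_K) != nrow(X) || ncol(W$W_Q) != nrow(X) ||
      ncol(W$W_V) != nrow(X)) {
    stop(sprintf("weights expect tokens of dimension %d, got %d",
                 ncol(W$W_K), nrow(X)), call. = FALSE)
  }
  structure(
    list(K = W$W_K %*% X, Q = W$W_Q %*% X, V = W$W_V %*% X, X = X),
    class = "kqv_projection"
  )
}

#' Exact softmax self-attention with residual
#'
#' The ground truth the neuron-astrocyte circuit approximates. Attention
#' weights are `A[i, t] = exp(k_i' q_t) / sum_j exp(k_j' q_t)` (columnwise
#' softmax of `K'Q`, no temperature scaling) and the output stacks
#' `L[, t] = V A[, t] + x_t`, i.e. a convex combination of value vectors
#' plus the residual connection. The softmax subtracts the per-column
#' maximum logit before exponentiating, which leaves `A` exactly invariant
#' while preventing overflow.
#'
#' @param P A [project()] result.
#' @return An object of class `attention_output`: list with `L` (`d x N`),
#'   the column-stochastic attention matrix `A` (`N x N`), and the softmax
#'   normalizers `Z` (length `N`, computed from the raw logits).
#' @examples
#' X <- diag(2)  # x1 = (1,0), x2 = (0,1)
#' W <- list(W_K = diag(2), W_Q = diag(2), W_V = diag(2))
#' out <- softmax_self_attention(project(X, W))
#' out$A[, 1]  # c(e, 1) / (e + 1)
#' @export
softmax_self_attention <- function(P) {
  stopifnot(inherits(P, "kqv_projection"))
  logits <- crossprod(P$K, P$Q)  # N x N, [i, t] = k_i' q_t
  mx <- apply(logits, 2, max)
  E <- exp(sweep(logits, 2, mx, "-"))
  if (!all(is.finite(E))) stop("non-finite attention logits", call. = FALSE)
  Z_shift <- colSums(E)
  A <- sweep(E, 2, Z_shift, "/")
  structure(
    list(L = P$V %*% A + P$X, A = A, Z = Z_shift * exp(mx)),
    class = "attention_output"
  )
}

#' Kernelized (linear-Transformer) attention: the circuit's closed form
#'
#' Brute-force batch evaluation of
#' `out_t = V phi(K)' phi(q_t) / (phi(q_t)' sum_j phi(k_j)) + x_t`.
#' The streaming neuron-astrocyte circuit ([run_block()]) computes exactly
#' this quantity token by token; this one-shot matrix form is the oracle it
#' must agree with to machine precision. With the `exact_kernel_oracle`
#' map the kernel weights are `exp(k_i' q_t)` and the output equals the
#' softmax reference exactly.
#'
#' @param P A [project()] result.
#' @param fm A [sample_feature_map()] object with `D` matching `nrow(K)`.
#' @return An `attention_output` with `L`, the (kernel-induced)
#'   column-stochastic weight matrix `A`, and the unnormalized kernel row
#'   sums `Z` (`Z[t] = sum_j phi(k_j)' phi(q_t)`).
#' @export
linear_attention <- function(P, fm) {
  stopifnot(inherits(P, "kqv_projection"), inherits(fm, "feature_map"))
  if (fm$D != nrow(P$K)) {
    stop(sprintf("feature map expects D = %d but keys have dimension %d",
                 fm$D, nrow(P$K)), call. = FALSE)
  }
  Wgt <- if (fm$kind == "exact_kernel_oracle") {
    K <- P$K; Q <- P$Q
    if (fm$prenormalize) {
      K <- normalize_columns(K)
      Q <- normalize_columns(Q)
    }
    exp(crossprod(K, Q))  # [i, t] = exp(k_i' q_t)
  } else {
    crossprod(apply_feature_map(fm, P$K), apply_feature_map(fm, P$Q))
  }
  Z <- colSums(Wgt)
  if (any(abs(Z) < 1e-300)) {
    stop("degenerate normalization: kernel denominator is zero",
         call. = FALSE)
  }
  A <- sweep(Wgt, 2, Z, "/")
  structure(list(L = P$V %*% A + P$X, A = A, Z = Z),
            class = "attention_output")
}

#' @export
print.attention_output <- function(x, ...) {
  cat(sprintf("attention_output: %d tokens of dimension %d\n",
              ncol(x$L), nrow(x$L)))
  invisible(x)
}

normalize_columns <- function(M) {
  nrm <- sqrt(colSums(M^2))
  nz <- nrm > 0
  M[, nz] <- sweep(M[, nz, drop = FALSE], 2, nrm[nz], "/")
  M
}
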