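#' Shunting-inhibition control circuit (no astrocyte)
#'
#' A purely neuronal alternative to the astrocyte mechanism: a single
#' inhibitory neuron with activity `R = g' h` divisively normalizes the
#' feed-forward input arriving from the hidden layer (but not the residual
#' input), so the reading-phase output is `ell = (1/R) H h + x`. The
#' writing phase is identical to the astrocyte circuit's except that the
#' Hebbian rate defaults to 1, so `H = V phi(K)'` without the `1/m`
#' prefactor. Because the astrocyte circuit scales both `H` (through
#' `eta_H = 1/m`) and its normalizer `p = (1/m) g' h` by `1/m`, the two
#' bookkeepings cancel identically and the two circuits implement the same
#' forward pass; see the methods vignette for the scale convention.
#'
#' @inheritParams run_block
#' @param eta_H Hebbian learning rate for the shunting circuit; default 1.
#' @param R_eps Degenerate-normalization guard on `|R|`; defaults as in
#'   [read_token()] (`1e-12` for `cosine_rbf`, else `1e-300`).
#' @return An `attention_output` with `L` (`d x N`) and the inhibitory
#'   neuron trace `R` (length `N`).
#' @examples
#' X <- make_tokens(3, 5, scale = 0.5, seed = 1)
#' W <- make_weights(3, 3, tied = TRUE, seed = 2)
#' fm <- sample_feature_map("positive_exp", m = 64, D = 3, seed = 3)
#' a <- run_block(X, W, fm)
#' s <- shunting_run_block(X, W, fm)
#' max(abs(a$L - s$L))  # same forward pass
#' @export
shunting_run_block <- function(X, W, fm, eta_H = 1, R_eps = NULL) {
  check_matrix(X, "X")
  stopifnot(inherits(fm, "feature_map"))
  if (is.null(R_eps)) {
    R_eps <- if (fm$kind == "cosine_rbf") 1e-12 else 1e-300
  }
  state <- new_circuit_state(nrow(X), fm, eta_H = eta_H)
  state <- write_sequence(X, W, fm, state)
  N <- ncol(X)
  L <- matrix(0, nrow = nrow(X), ncol = N)
  R_trace <- numeric(N)
  for (t in seq_len(N)) {
    x_t <- X[, t]
    q_t <- drop(W$W_Q %*% x_t)
    if (fm$kind == "exact_kernel_oracle") {
      K <- state$K_written
      if (fm$prenormalize) {
        K <- normalize_columns(K)
        nq <- sqrt(sum(q_t^2))
        if (nq > 0) q_t <- q_t / nq
      }
      w <- drop(exp(crossprod(K, q_t)))
      R <- sum(w)
      if (abs(R) < R_eps) {
        stop("degenerate normalization: inhibitory response R is zero",
             call. = FALSE)
      }
      L[, t] <- drop(state$eta_H * (state$V_written %*% w)) / R + x_t
    } else {
      h <- apply_feature_map(fm, q_t)
      R <- sum(state$g * h)
      if (abs(R) < R_eps) {
        stop("degenerate normalization: inhibitory response R is zero",
             call. = FALSE)
      }
      L[, t] <- drop(state$H %*% h) / R + x_t
    }
    R_trace[t] <- R
  }
  structure(list(L = L, R = R_trace, state = state),
            class = c("shunting_output", "attention_output"))
}
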