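#' Initialize a blank neuron-astrocyte circuit state
#'
#' The plastic state of the network before any token has been written:
#' the tripartite synaptic matrix `H` (`d x m`) and the neuron-to-astrocyte
#' weight vector `g` (length `m`) are zero. Hebbian updates use learning
#' rate `eta_H` (default `1/m`). For the `exact_kernel_oracle` feature map
#' the hidden layer is infinite-dimensional, so the state instead stores
#' the written keys and values, from which `H phi(q)` and `g' phi(q)` are
#' evaluated analytically.
#'
#' @param d Positive integer, token dimension (rows of `H`).
#' @param fm A [sample_feature_map()] object fixing the hidden width `m`.
#' @param eta_H Positive Hebbian learning rate; default `1/m`.
#' @return An object of class `circuit_state`.
#' @export
new_circuit_state <- function(d, fm, eta_H = 1 / fm$m) {
  check_count(d, "d")
  stopifnot(inherits(fm, "feature_map"))
  if (!is.numeric(eta_H) || length(eta_H) != 1L || eta_H <= 0) {
    stop("'eta_H' must be a single positive number", call. = FALSE)
  }
  st <- list(d = as.integer(d), m = fm$m, kind = fm$kind,
             eta_H = eta_H, n_written = 0L)
  if (fm$kind == "exact_kernel_oracle") {
    st$K_written <- matrix(numeric(0), nrow = fm$D, ncol = 0)
    st$V_written <- matrix(numeric(0), nrow = d, ncol = 0)
  } else {
    st$H <- matrix(0, nrow = d, ncol = fm$m)
    st$g <- numeric(fm$m)
  }
  structure(st, class = "circuit_state")
}

#' @export
print.circuit_state <- function(x, ...) {
  cat(sprintf(
    "circuit_state: d = %d, m = %d, kind = %s, eta_H = %.4g, %d token%s written\n",
    x$d, x$m, x$kind, x$eta_H, x$n_written, if (x$n_written == 1) "" else "s"))
  invisible(x)
}

#' Writing phase: stream tokens through the circuit with the read gate off
#'
#' With the read gate `r = 0` the forward pass is `f_t = x_t`,
#' `h_t = phi(W_K x_t) = phi(k_t)`, `ell_t = W_V x_t = v_t` (in tied mode
#' `ell_t = f_t`). Each presented token updates the plastic weights:
#'
#' * Hebbian outer product on the tripartite synapses,
#'   `H <- H + eta_H * ell_t h_t'`, so after `N` tokens
#'   `H = eta_H * V phi(K)'`;
#' * presynaptic plasticity on the neuron-to-astrocyte weights,
#'   `g <- g + h_t`, so `g = sum_j phi(k_j)`. The increment does not depend
#'   on the postsynaptic index, which is why `g` is a single `m`-vector
#'   shared by all `d x m` astrocyte processes.
#'
#' Both updates are sums over tokens, so the final `H` and `g` are
#' invariant to the order in which tokens are presented.
#'
#' @param X `d x N` token matrix; columns are streamed one at a time.
#' @param W A [make_weights()] object (or conformable list).
#' @param fm A [sample_feature_map()] object.
#' @param state A [new_circuit_state()] to extend; `NULL` starts from the
#'   zero state.
#' @return The updated `circuit_state`.
#' @export
write_sequence <- function(X, W, fm, state = NULL) {
  check_matrix(X, "X")
  stopifnot(inherits(fm, "feature_map"))
  if (is.null(state)) state <- new_circuit_state(nrow(X), fm)
  stopifnot(inherits(state, "circuit_state"))
  if (nrow(X) != state$d) {
    stop("token dimension does not match circuit state", call. = FALSE)
  }
  if (fm$kind != state$kind || fm$m != state$m) {
    stop("feature map does not match circuit state", call. = FALSE)
  }
  if (ncol(W$W_K) != nrow(X)) {
    stop("weight/token dimension mismatch", call. = FALSE)
  }
  for (t in seq_len(ncol(X))) {
    x_t <- X[, t]
    ell_t <- drop(W$W_V %*% x_t)  # r = 0: output layer carries the value
    k_t <- drop(W$W_K %*% x_t)
    if (fm$kind == "exact_kernel_oracle") {
      state$K_written <- cbind(state$K_written, k_t, deparse.level = 0)
      state$V_written <- cbind(state$V_written, ell_t, deparse.level = 0)
    } else {
      h_t <- apply_feature_map(fm, k_t)
      state$H <- state$H + state$eta_H * tcrossprod(ell_t, h_t)
      state$g <- state$g + h_t
    }
    state$n_written <- state$n_written + 1L
  }
  state
}

#' Reading phase: forward one token through the written circuit
#'
#' With the read gate `r = 1` the forward pass is `f = x`,
#' `h = phi(W_Q x) = phi(q_t)`, and the astrocyte processes respond to the
#' hidden activity through their plastic weights. Spatial averaging of the
#' per-process calcium levels makes them all equal to the scalar
#' `p = (1/m) g' h = (1/m) sum_j phi(k_j)' phi(q_t)`, and the released
#' gliotransmitter modulates every tripartite synapse by the common factor
#' `1/p`, giving the divisively normalized output
#' `ell = (1/p) H h + x`. Because `phi(k)' phi(q)` estimates
#' `exp(k'q)`, this is softmax attention plus the residual; with the
#' default `eta_H = 1/m` the identity
#' `ell = V phi(K)' phi(q) / (phi(q)' sum_j phi(k_j)) + x` is exact
#' (only the softmax itself is approximated).
#'
#' @param x Numeric length-`d` token to read.
#' @param W,fm,state As in [write_sequence()]; the state must have been
#'   written (at least one token).
#' @param p_eps Degenerate-normalization guard: an error is raised when
#'   `|p|` falls below it. Defaults to `1e-300` for the strictly positive
#'   `positive_exp` and oracle kernels and `1e-12` for `cosine_rbf`, whose
#'   kernel estimates can cross zero.
#' @return A `forward_trace` list: `f` (= `x`), hidden activity `h`
#'   (`NULL` for the oracle kind), output `ell`, and astrocyte value `p`.
#' @export
read_token <- function(x, W, fm, state, p_eps = NULL) {
  stopifnot(inherits(state, "circuit_state"), inherits(fm, "feature_map"))
  if (state$n_written == 0L) {
    stop("cannot read from an unwritten circuit: write tokens first",
         call. = FALSE)
  }
  if (length(x) != state$d || !all(is.finite(x))) {
    stop("'x' must be a finite vector of the circuit's token dimension",
         call. = FALSE)
  }
  if (is.null(p_eps)) {
    p_eps <- if (fm$kind == "cosine_rbf") 1e-12 else 1e-300
  }
  q_t <- drop(W$W_Q %*% x)
  if (fm$kind == "exact_kernel_oracle") {
    K <- state$K_written
    if (fm$prenormalize) {
      K <- normalize_columns(K)
      nq <- sqrt(sum(q_t^2))
      if (nq > 0) q_t <- q_t / nq
    }
    w <- drop(exp(crossprod(K, q_t)))  # exp(k_j' q_t), exact kernel
    p <- sum(w) / state$m
    if (abs(p) < p_eps) {
      stop("degenerate normalization: astrocyte response p is zero",
           call. = FALSE)
    }
    ell <- drop(state$eta_H * (state$V_written %*% w)) / p + x
    h <- NULL
  } else {
    h <- apply_feature_map(fm, q_t)
    p <- sum(state$g * h) / state$m
    if (abs(p) < p_eps) {
      stop("degenerate normalization: astrocyte response p is zero",
           call. = FALSE)
    }
    ell <- drop(state$H %*% h) / p + x
  }
  structure(list(f = x, h = h, ell = ell, p = p), class = "forward_trace")
}

#' Run a full write-then-read block over a token sequence
#'
#' The circuit's analog of one Transformer self-attention block: starting
#' from the zero state, all `N` tokens are streamed through the writing
#' phase, the read gate is switched on, and each token is read in turn.
#' The per-token outputs `ell_t` are stacked into `L`, which equals
#' [linear_attention()] on the same inputs (an algebraic identity of the
#' circuit, exact up to floating-point round-off) and approximates
#' `SelfAttn(X) + X` with error vanishing as the hidden width `m` grows.
#'
#' @inheritParams write_sequence
#' @param eta_H Hebbian learning rate; default `1/m`.
#' @param p_eps Passed to [read_token()].
#' @return An `attention_output` with `L` (`d x N`) plus the recorded
#'   astrocyte trace `p` (length `N`) and its rescaling
#'   `m_times_p = m * p`, the circuit's estimate of the softmax
#'   normalizers `Z_t = sum_j exp(k_j' q_t)`.
#' @examples
#' X <- make_tokens(3, 5, scale = 0.5, seed = 1)
#' W <- make_weights(3, 3, tied = TRUE, seed = 2)
#' fm <- sample_feature_map("positive_exp", m = 256, D = 3, seed = 3)
#' out <- run_block(X, W, fm)
#' ref <- softmax_self_attention(project(X, W))
#' norm(out$L - ref$L, "F") / norm(ref$L, "F")  # shrinks as m grows
#' @export
run_block <- function(X, W, fm, eta_H = 1 / fm$m, p_eps = NULL) {
  check_matrix(X, "X")
  state <- new_circuit_state(nrow(X), fm, eta_H = eta_H)
  state <- write_sequence(X, W, fm, state)
  N <- ncol(X)
  L <- matrix(0, nrow = nrow(X), ncol = N)
  p_trace <- numeric(N)
  for (t in seq_len(N)) {
    tr <- read_token(X[, t], W, fm, state, p_eps = p_eps)
    L[, t] <- tr$ell
    p_trace[t] <- tr$p
  }
  structure(
    list(L = L, p = p_trace, m_times_p = fm$m * p_trace, state = state),
    class = c("astro_output", "attention_output")
  )
}

#' Export an astrocyte (or inhibitory-neuron) trace as CSV
#'
#' Writes columns `token_index, p, m_times_p` for a [run_block()] result
#' (or `token_index, R` for [shunting_run_block()]).
#'
#' @param out A `run_block`/`shunting_run_block` result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(out, path) {
  df <- if (!is.null(out$p)) {
    data.frame(token_index = seq_along(out$p), p = out$p,
               m_times_p = out$m_times_p)
  } else {
    data.frame(token_index = seq_along(out$R), R = out$R)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a circuit state to a JSON + delimited-matrix bundle
#'
#' Writes `state.json` (scalars) plus `H.csv`/`g.csv` (or the written
#' key/value matrices for the oracle kind) into `dir`, for inspection.
#'
#' @param state A `circuit_state`.
#' @param dir Directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_circuit_state <- function(state, dir) {
  stopifnot(inherits(state, "circuit_state"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- state[c("d", "m", "kind", "eta_H", "n_written")]
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE),
             file.path(dir, "state.json"))
  if (state$kind == "exact_kernel_oracle") {
    write_matrix_txt(state$K_written, file.path(dir, "K_written.csv"))
    write_matrix_txt(state$V_written, file.path(dir, "V_written.csv"))
  } else {
    write_matrix_txt(state$H, file.path(dir, "H.csv"))
    write_matrix_txt(matrix(state$g, nrow = 1), file.path(dir, "g.csv"))
  }
  invisible(dir)
}

#' @rdname write_circuit_state
#' @export
read_circuit_state <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "state.json"))
  st <- list(d = meta$d, m = meta$m, kind = meta$kind, eta_H = meta$eta_H,
             n_written = meta$n_written)
  if (meta$kind == "exact_kernel_oracle") {
    st$K_written <- unname(read_matrix_txt(file.path(dir, "K_written.csv")))
    st$V_written <- unname(read_matrix_txt(file.path(dir, "V_written.csv")))
  } else {
    st$H <- unname(read_matrix_txt(file.path(dir, "H.csv")))
    st$g <- drop(unname(read_matrix_txt(file.path(dir, "g.csv"))))
  }
  structure(st, class = "circuit_state")
}
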