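test_that("writing accumulates the Hebbian closed form", {
  # streaming updates must match the one-shot matrix products
  # H = eta_H * V phi(K)', g = sum_j phi(k_j)
  d <- 2; D <- 2; N <- 3; m <- 8
  X <- make_tokens(d, N, seed = 50)
  W <- make_weights(d, D, seed = 51)
  fm <- sample_feature_map("positive_exp", m = m, D = D, seed = 52)
  st <- write_sequence(X, W, fm)
  PhiK <- apply_feature_map(fm, W$W_K %*% X)
  V <- W$W_V %*% X
  expect_equal(st$H, (1 / m) * tcrossprod(V, PhiK), tolerance = 1e-12)
  expect_equal(st$g, rowSums(PhiK), tolerance = 1e-12)
  expect_identical(st$n_written, as.integer(N))

  # single-token tied case: H = (1/m) x1 phi(x1)', g = phi(x1)
  Wt <- list(W_K = diag(2), W_Q = diag(2), W_V = diag(2))
  x1 <- c(1, 0)
  st1 <- write_sequence(matrix(x1), Wt, fm)
  phi1 <- apply_feature_map(fm, x1)
  expect_equal(st1$H, (1 / m) * tcrossprod(x1, phi1), tolerance = 1e-14)
  expect_equal(st1$g, phi1, tolerance = 1e-14)
})

test_that("H and g do not depend on token presentation order", {
  inst <- random_instance(60, N_range = 3:10)
  perm <- rev(seq_len(inst$N))
  st_fwd <- write_sequence(inst$X, inst$W, inst$fm)
  st_rev <- write_sequence(inst$X[, perm, drop = FALSE], inst$W, inst$fm)
  expect_equal(st_rev$H, st_fwd$H, tolerance = 1e-13)
  expect_equal(st_rev$g, st_fwd$g, tolerance = 1e-13)
})

test_that("reading requires a written state and guards degenerate p", {
  fm <- sample_feature_map("positive_exp", m = 16, D = 3, seed = 70)
  W <- make_weights(3, 3, seed = 71)
  st0 <- new_circuit_state(3, fm)
  expect_error(read_token(c(1, 0, 0), W, fm, st0), "unwritten")

  # cosine features with a zeroed g give p = 0
  fc <- sample_feature_map("cosine_rbf", m = 16, D = 3, seed = 72)
  st <- write_sequence(make_tokens(3, 2, seed = 73), W, fc)
  st$g[] <- 0
  expect_error(read_token(c(1, 0, 0), W, fc, st), "degenerate")
})

test_that("reading back a single written token returns value + residual", {
  x1 <- c(0.4, -0.7, 0.2)
  W <- make_weights(3, 4, seed = 80)
  for (kind in c("cosine_rbf", "positive_exp", "exact_kernel_oracle")) {
    fm <- sample_feature_map(kind, m = 32, D = 4, seed = 81)
    st <- write_sequence(matrix(x1), W, fm)
    tr <- read_token(x1, W, fm, st)
    expect_equal(tr$ell, drop(W$W_V %*% x1) + x1, tolerance = 1e-10,
                 info = kind)
    expect_identical(tr$f, x1)
  }
})

test_that("the full block is an exact mechanization of linear attention", {
  # algebraic identity, not an approximation: holds for every map kind,
  # tied and untied, at machine precision
  for (s in 1:12) {
    inst <- random_instance(100 + s)
    out <- run_block(inst$X, inst$W, inst$fm)
    la <- linear_attention(project(inst$X, inst$W), inst$fm)
    expect_lt(max_rel_diff(out$L, la$L), 1e-10)
  }
})

test_that("the oracle-map circuit reproduces exact softmax attention", {
  for (s in 1:6) {
    inst <- random_instance(130 + s)
    fo <- sample_feature_map("exact_kernel_oracle", m = 1, D = inst$D)
    out <- run_block(inst$X, inst$W, fo)
    ref <- softmax_self_attention(project(inst$X, inst$W))
    expect_lt(max_rel_diff(out$L, ref$L), 1e-10)
    # the astrocyte trace then equals the softmax normalizers / m
    expect_equal(out$m_times_p, ref$Z, tolerance = 1e-10)
  }
})

test_that("constant prefactors on phi cancel in the circuit output", {
  inst <- random_instance(140, N_range = 3:10)
  out <- run_block(inst$X, inst$W, inst$fm)
  # replacing phi by c * phi scales numerator and denominator of the
  # attention ratio by c^2; the block output must not move
  P <- project(inst$X, inst$W)
  PhiK <- apply_feature_map(inst$fm, P$K)
  PhiQ <- apply_feature_map(inst$fm, P$Q)
  for (c_pref in c(0.01, 7, 1234)) {
    Wgt <- crossprod(c_pref * PhiK, c_pref * PhiQ)
    A <- sweep(Wgt, 2, colSums(Wgt), "/")
    L_scaled <- P$V %*% A + inst$X
    expect_equal(L_scaled, out$L, tolerance = 1e-12)
  }
})

test_that("circuit output converges to softmax attention as m grows", {
  d <- 4; D <- 4; N <- 8
  X <- make_tokens(d, N, scale = 0.5, seed = 150)
  W <- make_weights(d, D, seed = 151)
  ref <- softmax_self_attention(project(X, W))
  for (kind in c("cosine_rbf", "positive_exp")) {
    med <- sapply(c(d, 50 * d), function(m) {
      errs <- sapply(1:10, function(s) {
        fm <- sample_feature_map(kind, m = m, D = D, seed = 160 + s)
        rel_frob(run_block(X, W, fm)$L, ref$L)
      })
      stats::median(errs)
    })
    expect_lt(med[2], med[1])
  }
})

test_that("tied weights and an equal untied weight list give identical runs", {
  d <- 3; D <- 5
  X <- make_tokens(d, 6, seed = 170)
  Wt <- make_weights(d, D, tied = TRUE, seed = 171)
  W_untied <- list(W_K = Wt$W_K, W_Q = Wt$W_K, W_V = diag(d),
                   tied = FALSE, d = d, D = D)
  fm <- sample_feature_map("positive_exp", m = 64, D = D, seed = 172)
  expect_identical(run_block(X, Wt, fm)$L, run_block(X, W_untied, fm)$L)
})

test_that("astrocyte values are positive for positive features", {
  inst <- random_instance(180, kinds = "positive_exp", N_range = 2:10)
  out <- run_block(inst$X, inst$W, inst$fm)
  expect_true(all(out$p > 0))
  expect_equal(out$m_times_p, inst$m * out$p, tolerance = 1e-15)
})

test_that("m * p_t is an unbiased estimate of the softmax normalizer", {
  d <- 4; D <- 4; N <- 6
  X <- make_tokens(d, N, scale = 0.5, seed = 190)
  W <- make_weights(d, D, seed = 191)
  Z <- softmax_self_attention(project(X, W))$Z
  traces <- sapply(1:200, function(s) {
    fm <- sample_feature_map("positive_exp", m = 500, D = D, seed = 200 + s)
    run_block(X, W, fm)$m_times_p
  })  # N x 200
  means <- rowMeans(traces)
  ses <- apply(traces, 1, stats::sd) / sqrt(ncol(traces))
  expect_true(all(abs(means - Z) < 4 * ses))
})

test_that("circuit state round-trips through its serialization bundle", {
  inst <- random_instance(210, N_range = 3:6)
  st <- write_sequence(inst$X, inst$W, inst$fm)
  dir <- withr::local_tempdir()
  write_circuit_state(st, dir)
  st2 <- read_circuit_state(dir)
  expect_equal(st2$H, st$H, tolerance = 1e-12)
  expect_equal(st2$g, st$g, tolerance = 1e-12)
  expect_identical(st2$n_written, st$n_written)

  out <- run_block(inst$X, inst$W, inst$fm)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(out, csv)
  df <- utils::read.csv(csv)
  expect_named(df, c("token_index", "p", "m_times_p"))
  expect_equal(df$p, out$p, tolerance = 1e-12)
})
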