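#' Sample a random feature map for the exponential dot-product kernel
#'
#' The circuit's hidden-layer nonlinearity `phi` must satisfy
#' `phi(x)' phi(y) ~ exp(x' y)` so that divisively normalized readout
#' reproduces softmax attention weights. Two classical random-feature
#' constructions achieve this with high probability as the hidden width `m`
#' grows:
#'
#' * `cosine_rbf`: `phi(x) = sqrt(2/m) * exp(||x||^2 / 2) * cos(Pi x + b)`
#'   with `Pi` an `m x D` standard-normal projection and phases `b` uniform
#'   on `[0, 2*pi)` (random Fourier features for the RBF kernel, rescaled).
#' * `positive_exp`: `phi(x) = (1/sqrt(m)) * exp(-||x||^2 / 2) * exp(Pi x)`,
#'   elementwise strictly positive, so every attention weight it induces is
#'   non-negative.
#'
#' A third kind, `exact_kernel_oracle`, represents the infinite-width limit:
#' its kernel is exactly `exp(x' y)`. It has no finite feature vector and
#' exists as a test oracle; `m` and `Pi` are ignored.
#'
#' With `prenormalize = TRUE` arguments are first rescaled to the unit
#' sphere and the norm-dependent prefactors are dropped (they are then
#' constants that cancel in the attention ratio), giving the simplified
#' forms `cos(Pi x + b)` and `exp(Pi x)`.
#'
#' @param kind One of `"cosine_rbf"`, `"positive_exp"`,
#'   `"exact_kernel_oracle"`.
#' @param m Positive integer hidden width (number of random features).
#' @param D Positive integer input dimension.
#' @param prenormalize Logical; spherically normalize arguments and drop the
#'   exponential prefactors.
#' @param seed Integer seed; `Pi` and `b` are deterministic in it.
#'
#' @return An object of class `feature_map`: a list with `kind`, `m`, `D`,
#'   `prenormalize`, `seed`, and (for the random kinds) the projection `Pi`
#'   and, for `cosine_rbf`, the phase vector `b`.
#' @examples
#' fm <- sample_feature_map("positive_exp", m = 64, D = 3, seed = 1)
#' x <- c(0.3, -0.2, 0.5); y <- c(0.1, 0.4, -0.3)
#' kernel_estimate(fm, x, y)   # approximates exp(sum(x * y))
#' exp(sum(x * y))
#' @export
sample_feature_map <- function(kind = c("cosine_rbf", "positive_exp",
                                        "exact_kernel_oracle"),
                               m, D, prenormalize = FALSE, seed = 0L) {
  kind <- match.arg(kind)
  check_count(m, "m")
  check_count(D, "D")
  fm <- list(kind = kind, m = as.integer(m), D = as.integer(D),
             prenormalize = isTRUE(prenormalize), seed = as.integer(seed))
  if (kind != "exact_kernel_oracle") {
    draws <- withr::with_seed(as.integer(seed), {
      Pi <- matrix(stats::rnorm(m * D), nrow = m, ncol = D)
      b <- if (kind == "cosine_rbf") stats::runif(m, 0, 2 * pi) else NULL
      list(Pi = Pi, b = b)
    })
    fm$Pi <- draws$Pi
    fm$b <- draws$b
  }
  structure(fm, class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  cat(sprintf("feature_map '%s': m = %d, D = %d, prenormalize = %s, seed = %d\n",
              x$kind, x$m, x$D, x$prenormalize, x$seed))
  invisible(x)
}

#' Apply a feature map to one vector or columnwise to a matrix
#'
#' Evaluates `phi(x)` for the map's kind. The `exact_kernel_oracle` kind has
#' no finite feature vector and cannot be applied; use [kernel_estimate()]
#' or the circuit functions, which handle it analytically.
#'
#' @param fm A [sample_feature_map()] object of a random kind.
#' @param x Numeric vector of length `D`, or a `D x N` matrix applied
#'   columnwise.
#' @return An `m`-vector, or an `m x N` matrix for matrix input.
#' @export
apply_feature_map <- function(fm, x) {
  stopifnot(inherits(fm, "feature_map"))
  if (fm$kind == "exact_kernel_oracle") {
    stop("the exact kernel oracle has no finite feature vector; ",
         "use kernel_estimate() or the circuit functions", call. = FALSE)
  }
  xm <- if (is.matrix(x)) x else matrix(x, ncol = 1L)
  if (nrow(xm) != fm$D) {
    stop(sprintf("input has length %d but the feature map expects D = %d",
                 nrow(xm), fm$D), call. = FALSE)
  }
  if (!all(is.finite(xm))) stop("input must be finite", call. = FALSE)
  nrm2 <- colSums(xm^2)
  if (fm$prenormalize) {
    nz <- nrm2 > 0
    xm[, nz] <- sweep(xm[, nz, drop = FALSE], 2, sqrt(nrm2[nz]), "/")
  }
  proj <- fm$Pi %*% xm  # m x N
  out <- if (fm$kind == "cosine_rbf") {
    pref <- if (fm$prenormalize) rep(1, ncol(xm)) else
      sqrt(2 / fm$m) * exp(nrm2 / 2)
    sweep(cos(proj + fm$b), 2, pref, "*")
  } else {  # positive_exp
    pref <- if (fm$prenormalize) rep(1, ncol(xm)) else
      (1 / sqrt(fm$m)) * exp(-nrm2 / 2)
    sweep(exp(proj), 2, pref, "*")
  }
  if (!all(is.finite(out))) {
    bad <- which(!apply(is.finite(out), 2, all))[1L]
    stop(sprintf(
      paste0("feature map overflow: non-finite phi for input column %d ",
             "(norm %.4g); use prenormalize = TRUE or a smaller token scale"),
      bad, sqrt(nrm2[bad])), call. = FALSE)
  }
  if (is.matrix(x)) out else drop(out)
}

#' Estimate the exponential dot-product kernel with a feature map
#'
#' Returns `phi(x)' phi(y)`. For the `exact_kernel_oracle` kind this is
#' `exp(x' y)` exactly (with prenormalization applied first if the map
#' requests it); for the random kinds it is an unbiased Monte-Carlo
#' estimator whose variance shrinks as `1/m`.
#'
#' @param fm A [sample_feature_map()] object.
#' @param x,y Numeric vectors of length `D`.
#' @return A scalar kernel estimate.
#' @export
kernel_estimate <- function(fm, x, y) {
  stopifnot(inherits(fm, "feature_map"))
  if (fm$kind == "exact_kernel_oracle") {
    if (length(x) != fm$D || length(y) != fm$D) {
      stop(sprintf("inputs must have length D = %d", fm$D), call. = FALSE)
    }
    if (!all(is.finite(x)) || !all(is.finite(y))) {
      stop("inputs must be finite", call. = FALSE)
    }
    if (fm$prenormalize) {
      nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
      if (nx > 0) x <- x / nx
      if (ny > 0) y <- y / ny
    }
    return(exp(sum(x * y)))
  }
  sum(apply_feature_map(fm, x) * apply_feature_map(fm, y))
}

#' Serialize a feature map to a JSON descriptor
#'
#' Only the descriptor `{kind, m, D, prenormalize, seed}` is stored; the
#' projection `Pi` and phases `b` are regenerated from the seed on load,
#' never written out.
#'
#' @param fm A [sample_feature_map()] object.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, if written to `path`).
#' @export
feature_map_to_json <- function(fm, path = NULL) {
  stopifnot(inherits(fm, "feature_map"))
  desc <- fm[c("kind", "m", "D", "prenormalize", "seed")]
  js <- jsonlite::toJSON(desc, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname feature_map_to_json
#' @param json JSON string or file path produced by [feature_map_to_json()].
#' @export
feature_map_from_json <- function(json) {
  desc <- jsonlite::fromJSON(json)
  sample_feature_map(desc$kind, m = desc$m, D = desc$D,
                     prenormalize = isTRUE(desc$prenormalize),
                     seed = desc$seed)
}
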