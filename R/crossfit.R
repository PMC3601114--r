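#' Fixed-factor cross-reconstruction
#'
#' Reconstructs an envelope matrix while holding one NMF factor fixed:
#' with fixed muscle weightings the activation signals are free to vary, and
#' vice versa. The free factor is initialized from a seeded uniform draw and
#' refined by exactly `iterations` multiplicative updates (no early
#' stopping), the procedure used to test whether factors extracted in one
#' condition can explain data from another. The fixed factor is never
#' modified.
#'
#' @param X nonnegative M x K envelope matrix to reconstruct.
#' @param fixed the fixed nonnegative factor: M x N weightings or N x K
#'   activation matrix.
#' @param which which factor `fixed` is: `"weightings"` or `"activations"`.
#' @param iterations number of multiplicative updates for the free factor
#'   (default 1000). `iterations = 0` scores the random initialization and
#'   serves as a null reference.
#' @param seed integer seed for the free-factor initialization.
#' @return a `cross_recon`: `fixed_factor` (label), `free_factor_estimate`,
#'   `reconstruction`, `vaf` (a `vaf_result`) and `iterations`.
#' @export
fixed_factor_fit <- function(X, fixed, which = c("weightings", "activations"),
                             iterations = 1000, seed = 1L) {
  which <- match.arg(which)
  X <- as.matrix(X); fixed <- as.matrix(fixed)
  if (any(X < 0) || any(fixed < 0)) stop("inputs must be nonnegative")
  set.seed(as.integer(seed))
  if (which == "weightings") {
    if (nrow(fixed) != nrow(X))
      stop("fixed weightings must have one row per muscle of X")
    N <- ncol(fixed)
    free0 <- matrix(runif(N * ncol(X), min = 1e-6), N) * mean(X)
    fit <- .nmf_mu_cpp(X, fixed, free0, max(iterations, 0L), -1, 2L)
    free <- fit$H
    rec <- fixed %*% free
  } else {
    if (ncol(fixed) != ncol(X))
      stop("fixed activations must have one column per time point of X")
    N <- nrow(fixed)
    free0 <- matrix(runif(nrow(X) * N, min = 1e-6), nrow(X)) * mean(X)
    fit <- .nmf_mu_cpp(X, free0, fixed, max(iterations, 0L), -1, 1L)
    free <- fit$W
    rec <- free %*% fixed
  }
  structure(list(fixed_factor = which, free_factor_estimate = free,
                 reconstruction = rec, vaf = vaf(X, rec),
                 iterations = as.integer(iterations),
                 error_trace = fit$error, seed = as.integer(seed)),
            class = "cross_recon")
}

#' @export
print.cross_recon <- function(x, ...) {
  cat(sprintf("Cross-reconstruction (fixed %s, %d updates): VAF %.2f%%\n",
              x$fixed_factor, x$iterations, 100 * x$vaf$global_vaf))
  invisible(x)
}

#' Random baseline matrix for cross-reconstruction
#'
#' A seeded uniform (0, 1] matrix matched in shape to the factor it stands in
#' for; fixing it in [fixed_factor_fit()] gives the "free-to-vary" reference
#' against which true-factor reconstructions are compared.
#'
#' @param n_rows,n_cols shape of the replaced factor.
#' @param seed integer seed.
#' @return nonnegative matrix.
#' @export
random_factor <- function(n_rows, n_cols, seed = 1L) {
  set.seed(as.integer(seed))
  matrix(runif(n_rows * n_cols, min = 1e-6), n_rows, n_cols)
}
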