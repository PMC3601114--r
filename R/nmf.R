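#' Extract motor modules by non-negative matrix factorization
#'
#' Factorizes a nonnegative envelope matrix `X` (M muscles x K time points)
#' as `X ~ S P` with `S` the M x N muscle-weighting matrix (motor modules)
#' and `P` the N x K activation signals, by multiplicative updates minimizing
#' the Frobenius reconstruction error. The best of `n_restarts` random
#' restarts is returned, canonicalized so each weighting column has unit
#' Euclidean norm (the scale is absorbed into the matching activation row)
#' and modules are ordered by activation peak time.
#'
#' @param X nonnegative M x K matrix (muscles in rows).
#' @param n_modules number of modules N, `1 <= N <= min(M, K)`.
#' @param seed integer seed; restart r uses `seed + r - 1`.
#' @param n_restarts independent random initializations (default 20).
#' @param max_iter maximum multiplicative updates per restart.
#' @param tol stop when the relative Frobenius-error change falls below this.
#' @param init optional list with matrices `W` (M x N) and `H` (N x K) used
#'   as an additional warm-start candidate.
#' @param sort_modules order modules by activation peak time (default TRUE).
#' @return An object of class `synergy_nmf` with elements `weightings`,
#'   `activations`, `reconstruction`, `n_modules`, `vaf` (a `vaf_result`),
#'   `fit` (error trace of the winning restart, iterations, restart index,
#'   seed) and `X` (the data).
#' @seealso [vaf()], [vaf_curve()], [select_dimensionality()],
#'   [fixed_factor_fit()]
#' @export
synergy_nmf <- function(X, n_modules, seed = 1L, n_restarts = 20,
                        max_iter = 1000, tol = 1e-6, init = NULL,
                        sort_modules = TRUE) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("X must be nonnegative")
  if (all(X == 0)) stop("X is all zero; nothing to factorize")
  M <- nrow(X); K <- ncol(X)
  if (n_modules < 1 || n_modules > min(M, K))
    stop("n_modules must be between 1 and min(M, K) = ", min(M, K))
  seed <- as.integer(seed)

  scale0 <- sqrt(4 * mean(X) / n_modules)  # so E[W0 H0] ~ mean(X)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    W0 <- matrix(runif(M * n_modules, min = 1e-6), M) * scale0
    H0 <- matrix(runif(n_modules * K, min = 1e-6), n_modules) * scale0
    fit <- .nmf_mu_cpp(X, W0, H0, max_iter, tol, 0L)
    fit$restart <- r
    e <- fit$error[length(fit$error)]
    if (is.null(best) || e < best$error[length(best$error)]) best <- fit
  }
  if (!is.null(init)) {
    fit <- .nmf_mu_cpp(X, init$W, init$H, max_iter, tol, 0L)
    fit$restart <- 0L
    if (fit$error[length(fit$error)] < best$error[length(best$error)])
      best <- fit
  }

  W <- best$W; H <- best$H
  # canonicalize: unit-norm weighting columns, scale into activations
  nrm <- sqrt(colSums(W^2))
  nrm[nrm == 0] <- 1
  W <- sweep(W, 2, nrm, "/")
  H <- sweep(H, 1, nrm, "*")
  if (sort_modules && n_modules > 1) {
    ord <- order(apply(H, 1, which.max))
    W <- W[, ord, drop = FALSE]
    H <- H[ord, , drop = FALSE]
  }
  dimnames(W) <- list(rownames(X), paste0("M", seq_len(n_modules)))
  rownames(H) <- colnames(W)
  rec <- W %*% H

  structure(list(weightings = W, activations = H, reconstruction = rec,
                 n_modules = n_modules, vaf = vaf(X, rec),
                 fit = list(error = best$error[length(best$error)],
                            error_trace = best$error,
                            iterations = best$iterations,
                            restart = best$restart, seed = seed,
                            n_restarts = n_restarts, tol = tol,
                            max_iter = max_iter),
                 X = X),
            class = "synergy_nmf")
}

#' @export
print.synergy_nmf <- function(x, digits = 3, ...) {
  cat(sprintf("Motor module set: %d modules, %d muscles x %d time points\n",
              x$n_modules, nrow(x$weightings), ncol(x$activations)))
  cat(sprintf("  VAF %.1f%% (SSE %.4g / SST %.4g), %d iterations, restart %d\n",
              100 * x$vaf$global_vaf, x$vaf$sse, x$vaf$sst,
              x$fit$iterations, x$fit$restart))
  cat("  activation peak times (% cycle): ",
      paste(format(peak_timing(x$activations), digits = digits),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.synergy_nmf <- function(object, ...) {
  out <- list(n_modules = object$n_modules,
              global_vaf = object$vaf$global_vaf,
              per_muscle_vaf = object$vaf$per_muscle_vaf,
              peak_pct = peak_timing(object$activations),
              fit = object$fit)
  class(out) <- "summary.synergy_nmf"
  out
}

#' @export
print.summary.synergy_nmf <- function(x, ...) {
  cat(sprintf("%d motor modules; global VAF %.2f%%\n",
              x$n_modules, 100 * x$global_vaf))
  cat("Activation peak times (% cycle):\n")
  print(round(x$peak_pct, 1))
  cat("Per-muscle VAF:\n")
  print(round(x$per_muscle_vaf, 3))
  invisible(x)
}

#' @export
coef.synergy_nmf <- function(object,
                             which = c("weightings", "activations"), ...) {
  switch(match.arg(which),
         weightings = object$weightings,
         activations = object$activations)
}

#' @export
fitted.synergy_nmf <- function(object, ...) object$reconstruction

#' @export
residuals.synergy_nmf <- function(object, ...) object$X - object$reconstruction

#' Reconstruct new data from a fitted module set
#'
#' With `newdata` supplied, estimates activation signals for the new
#' envelopes while holding the fitted muscle weightings fixed (see
#' [fixed_factor_fit()]); without, returns the in-sample reconstruction.
#'
#' @param object a [synergy_nmf()] fit.
#' @param newdata optional nonnegative M x K' envelope matrix.
#' @param iterations multiplicative updates for the free factor.
#' @param seed seed for the free-factor initialization.
#' @param ... unused.
#' @return reconstruction matrix; with `newdata`, the `cross_recon` object is
#'   attached as attribute `fit`.
#' @export
predict.synergy_nmf <- function(object, newdata = NULL, iterations = 1000,
                                seed = 1L, ...) {
  if (is.null(newdata)) return(object$reconstruction)
  cr <- fixed_factor_fit(newdata, object$weightings, "weightings",
                         iterations = iterations, seed = seed)
  rec <- object$weightings %*% cr$free_factor_estimate
  attr(rec, "fit") <- cr
  rec
}

#' @export
plot.synergy_nmf <- function(x, ...) {
  N <- x$n_modules
  op <- par(mfrow = c(N, 2), mar = c(2.5, 3, 1.5, 0.5), mgp = c(1.6, 0.5, 0))
  on.exit(par(op))
  K <- ncol(x$activations)
  pct <- 100 * (seq_len(K) - 1) / (K - 1)
  for (n in seq_len(N)) {
    barplot(x$weightings[, n], las = 2, cex.names = 0.6,
            main = paste0("M", n, " weightings"), border = NA)
    plot(pct, x$activations[n, ], type = "l", xlab = "% cycle",
         ylab = "activation", main = paste0("M", n, " activation"))
  }
  invisible(x)
}

#' Simulate envelope trials from a fitted module set
#'
#' Treats the fitted weightings and activations as generative ground truth
#' and draws noisy nonnegative trials from them (see [synthesize_trials()]).
#'
#' @param object a [synergy_nmf()] fit.
#' @param nsim number of trials.
#' @param seed integer seed.
#' @param noise_level relative noise sd (default: residual sd of the fit
#'   relative to the reconstruction RMS).
#' @param ... unused.
#' @return list of M x K matrices.
#' @export
simulate.synergy_nmf <- function(object, nsim = 1, seed = 1L,
                                 noise_level = NULL, ...) {
  if (is.null(noise_level)) {
    noise_level <- sd(object$X - object$reconstruction) /
      sqrt(mean(object$reconstruction^2))
  }
  truth <- planted_truth(object$weightings, object$activations,
                         noise_level = noise_level, seed = seed)
  synthesize_trials(truth, nsim, "UPT", seed = seed)$trials
}

#' Variance accounted for by a reconstruction
#'
#' `VAF = 1 - SSE/SST`, with `SSE = sum((X - Xr)^2)` and, by default, the
#' uncentered total sum of squares `SST = sum(X^2)` (the dominant convention
#' in the synergy literature; it makes the zero reconstruction score 0).
#' Per-muscle VAF uses row-wise sums.
#'
#' @param X data matrix; `Xr` reconstruction of the same shape.
#' @param Xr reconstruction matrix.
#' @param centered use the mean-centered SST instead (default FALSE).
#' @return a `vaf_result`: `global_vaf`, `per_muscle_vaf`, `sse`, `sst`.
#' @export
vaf <- function(X, Xr, centered = FALSE) {
  X <- as.matrix(X); Xr <- as.matrix(Xr)
  if (!all(dim(X) == dim(Xr))) stop("X and Xr must have the same shape")
  E <- X - Xr
  sse <- sum(E^2)
  ctr <- if (centered) rowMeans(X) else 0
  Xc <- X - ctr
  sst <- sum(Xc^2)
  if (sst == 0) stop("SST is zero; VAF undefined")
  row_sst <- rowSums(Xc^2)
  per <- ifelse(row_sst > 0, 1 - rowSums(E^2) / row_sst, NA_real_)
  names(per) <- rownames(X)
  structure(list(global_vaf = 1 - sse / sst, per_muscle_vaf = per,
                 sse = sse, sst = sst),
            class = "vaf_result")
}

#' @export
print.vaf_result <- function(x, ...) {
  cat(sprintf("VAF %.2f%% (SSE %.4g, SST %.4g)\n",
              100 * x$global_vaf, x$sse, x$sst))
  invisible(x)
}

#' Reconstruction quality as a function of the number of modules
#'
#' Fits one [synergy_nmf()] per module count in `n_range` and collects the
#' global VAF. Monotone non-decreasing VAF is guaranteed structurally: the
#' fit at N+1 modules also tries a warm start built from the N-module
#' solution plus one random module, which can only improve the error.
#'
#' @param X nonnegative envelope matrix.
#' @param n_range increasing vector of module counts (start at 1 for use with
#'   [select_dimensionality()]).
#' @param seed integer seed.
#' @param n_restarts restarts per module count.
#' @param ... passed to [synergy_nmf()].
#' @return a `vaf_curve`: `n_values`, `vaf_values`, and the list of fits.
#' @export
vaf_curve <- function(X, n_range = 1:8, seed = 1L, n_restarts = 5, ...) {
  if (is.unsorted(n_range, strictly = TRUE))
    stop("n_range must be strictly increasing")
  fits <- vector("list", length(n_range))
  vafs <- numeric(length(n_range))
  prev <- NULL
  for (i in seq_along(n_range)) {
    N <- n_range[i]
    init <- NULL
    if (!is.null(prev) && N == prev$n_modules + 1) {
      set.seed(seed + 7000L + N)
      init <- list(W = cbind(prev$weightings,
                             runif(nrow(X), min = 1e-6) * mean(X)),
                   H = rbind(prev$activations,
                             runif(ncol(X), min = 1e-6)))
    }
    fits[[i]] <- synergy_nmf(X, N, seed = seed + 100L * N,
                             n_restarts = n_restarts, init = init, ...)
    vafs[i] <- fits[[i]]$vaf$global_vaf
    prev <- fits[[i]]
  }
  structure(list(n_values = n_range, vaf_values = vafs, fits = fits),
            class = "vaf_curve")
}

#' @export
print.vaf_curve <- function(x, ...) {
  cat("VAF curve:\n")
  print(data.frame(n_modules = x$n_values,
                   vaf_pct = round(100 * x$vaf_values, 2)),
        row.names = FALSE)
  invisible(x)
}

#' @export
plot.vaf_curve <- function(x, floor = 0.80, ...) {
  plot(x$n_values, 100 * x$vaf_values, type = "b", xlab = "number of modules",
       ylab = "VAF (%)", ylim = c(0, 100), ...)
  abline(h = 100 * floor, lty = 2)
  invisible(x)
}

#' Select the number of motor modules from a VAF curve
#'
#' Returns the smallest N whose VAF reaches the quality floor (default 80%)
#' and after which the curve has pronouncedly flattened: the gain from adding
#' the (N+1)-th module is below `gain_eps` percentage points. If the floor is
#' reached but the flattening condition never holds, the smallest N above the
#' floor is returned with attribute `flagged = TRUE`.
#'
#' @param curve a [vaf_curve()] covering contiguous counts starting at 1.
#' @param floor minimum acceptable VAF, as a fraction (default 0.80).
#' @param gain_eps slope-change threshold in VAF percentage points
#'   (default 3).
#' @return integer module count, with attribute `flagged`.
#' @export
select_dimensionality <- function(curve, floor = 0.80, gain_eps = 3) {
  n <- curve$n_values
  v <- curve$vaf_values
  if (n[1] != 1 || any(diff(n) != 1))
    stop("curve must cover contiguous module counts starting at 1")
  if (max(v) < floor)
    stop(sprintf("insufficient dimensionality: maximum VAF %.3f below floor %.2f",
                 max(v), floor))
  gains <- c(diff(v), NA)
  ok <- v >= floor & !is.na(gains) & gains < gain_eps / 100
  if (any(ok)) {
    res <- n[which(ok)[1]]
    attr(res, "flagged") <- FALSE
  } else {
    res <- n[which(v >= floor)[1]]
    attr(res, "flagged") <- TRUE
  }
  res
}

#' Concatenate envelope trials along time
#'
#' @param trials list of M x K matrices sharing the muscle ordering.
#' @return M x (K1 + K2 + ...) matrix with attribute `boundaries`, the
#'   cumulative end column of each trial.
#' @export
concatenate_trials <- function(trials) {
  if (is.matrix(trials)) trials <- list(trials)
  M <- vapply(trials, nrow, 1L)
  if (length(unique(M)) != 1)
    stop("all trials must share the number of muscles")
  out <- do.call(cbind, trials)
  attr(out, "boundaries") <- cumsum(vapply(trials, ncol, 1L))
  out
}

#' Average concatenated activation signals over cycles
#'
#' Folds an N x (K * n_trials) activation matrix from a concatenated fit back
#' onto one cycle by averaging across trials, giving the N x K mean
#' activation signals (used e.g. as the fixed factor when reconstructing a
#' single-cycle trial).
#'
#' @param H N x (K * n_trials) activation matrix.
#' @param n_points cycle length K.
#' @return N x `n_points` matrix.
#' @export
cycle_average_activations <- function(H, n_points) {
  if (ncol(H) %% n_points != 0)
    stop("ncol(H) is not a multiple of n_points")
  n_tr <- ncol(H) / n_points
  out <- matrix(0, nrow(H), n_points, dimnames = list(rownames(H), NULL))
  for (t in seq_len(n_tr))
    out <- out + H[, ((t - 1) * n_points + 1):(t * n_points), drop = FALSE]
  out / n_tr
}
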