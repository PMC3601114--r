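#' Planted ground truth for synthetic EMG envelopes
#'
#' Bundles the generative quantities of the synergy model `X = S P`:
#' a nonnegative muscle-weighting matrix `S` (M muscles x N modules, unit
#' Euclidean norm per column), nonnegative activation signals `P`
#' (N x K cycle points), the relative noise level, and an optional
#' perturbation specification that rescales chosen activation signals inside
#' a window of the cycle (the condition effect applied to perturbed trials).
#'
#' @param weightings nonnegative M x N matrix; columns are normalized to unit
#'   Euclidean norm.
#' @param activations nonnegative N x K matrix of activation signals.
#' @param noise_level nonnegative scalar; additive noise standard deviation
#'   as a fraction of the clean mixture's RMS.
#' @param perturb_spec list of perturbation entries, each a list/vector with
#'   fields `module`, `start_pct`, `end_pct`, `gain` (gain >= 0; window in
#'   percent of cycle, 0 <= start < end <= 100).
#' @param seed integer seed recorded with the truth (used by
#'   [synthesize_trials()] unless overridden).
#' @return An object of class `planted_truth`.
#' @export
planted_truth <- function(weightings, activations, noise_level = 0.05,
                          perturb_spec = list(), seed = 1L) {
  weightings <- as.matrix(weightings)
  activations <- as.matrix(activations)
  if (any(weightings < 0) || any(activations < 0))
    stop("weightings and activations must be nonnegative")
  if (ncol(weightings) != nrow(activations))
    stop("ncol(weightings) must equal nrow(activations)")
  nrm <- sqrt(colSums(weightings^2))
  if (any(nrm == 0)) stop("all-zero weighting column")
  weightings <- sweep(weightings, 2, nrm, "/")
  if (noise_level < 0) stop("noise_level must be >= 0")
  perturb_spec <- lapply(perturb_spec, function(p) {
    p <- as.list(p)
    names(p) <- c("module", "start_pct", "end_pct", "gain")[seq_along(p)]
    if (p$start_pct < 0 || p$end_pct > 100 || p$start_pct >= p$end_pct)
      stop("perturbation window must satisfy 0 <= start < end <= 100")
    if (p$gain < 0) stop("perturbation gain must be >= 0")
    if (p$module < 1 || p$module > nrow(activations))
      stop("perturbed module index out of range")
    p
  })
  structure(list(weightings = weightings, activations = activations,
                 noise_level = noise_level, perturb_spec = perturb_spec,
                 seed = as.integer(seed)),
            class = "planted_truth")
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf("Planted ground truth: %d muscles, %d modules, %d cycle points\n",
              nrow(x$weightings), ncol(x$weightings), ncol(x$activations)))
  cat(sprintf("  noise level: %.3f x clean RMS; %d perturbation(s); seed %d\n",
              x$noise_level, length(x$perturb_spec), x$seed))
  invisible(x)
}

#' Generate a random sparse nonnegative weighting matrix
#'
#' Draws uniform(0,1] entries, zeroes approximately `sparsity` of them, and
#' rescales each column to unit Euclidean norm. Columns or rows that end up
#' all-zero are redrawn, so every muscle loads on at least one module.
#'
#' @param n_muscles,n_modules matrix dimensions (modules <= muscles).
#' @param sparsity fraction of entries zeroed, in `[0, 1)`.
#' @param seed integer seed (mandatory; generation is reproducible).
#' @param max_overlap cap on the pairwise cosine similarity between planted
#'   columns (default 0.6); columns exceeding it are redrawn so the planted
#'   modules are genuinely distinct, comfortably below the r > 0.80
#'   same-module criterion.
#' @return nonnegative `n_muscles` x `n_modules` matrix with unit-norm columns.
#' @export
generate_module_set <- function(n_muscles, n_modules, sparsity = 0.4, seed,
                                max_overlap = 0.6) {
  if (missing(seed)) stop("seed is required")
  if (n_modules > n_muscles)
    stop("n_modules must not exceed n_muscles")
  if (sparsity < 0 || sparsity >= 1) stop("sparsity must be in [0, 1)")
  set.seed(as.integer(seed))
  draw_col <- function() {
    for (a in 1:500) {
      v <- runif(n_muscles, min = 1e-3, max = 1)
      v[runif(n_muscles) < sparsity] <- 0
      if (any(v > 0)) return(v / sqrt(sum(v^2)))
    }
    stop("sparsity too high: could not draw a non-zero column")
  }
  for (attempt in 1:100) {
    S <- matrix(0, n_muscles, n_modules)
    ok <- TRUE
    for (j in seq_len(n_modules)) {
      for (a in 1:500) {
        v <- draw_col()
        if (j == 1 ||
            max(crossprod(S[, seq_len(j - 1), drop = FALSE], v)) <=
              max_overlap) break
        if (a == 500) ok <- FALSE
      }
      S[, j] <- v
    }
    if (ok && all(rowSums(S) > 0)) return(S)
  }
  stop("could not draw a weighting matrix satisfying the sparsity and ",
       "overlap constraints")
}

#' Generate Gaussian-bump activation signals
#'
#' One row per module: a Gaussian bump in cycle-percentage space centred at
#' `peak_pcts[n]` with standard deviation `width_pct`, sitting on a small
#' tonic baseline, rescaled so each row's maximum is 1. The baseline reflects
#' that rectified EMG envelopes never rest at exactly zero.
#'
#' @param n_modules number of modules (rows).
#' @param n_points number of cycle samples K (columns), >= 2.
#' @param peak_pcts numeric vector, length `n_modules`, of peak positions in
#'   percent of the cycle (0-100).
#' @param width_pct bump standard deviation, percent of cycle (default 6,
#'   of the order of the inter-trial peak-timing spread reported for cutting).
#' @param baseline tonic activity level relative to the bump peak (default
#'   0.04).
#' @param seed integer seed (kept for interface symmetry; the signal itself
#'   is deterministic).
#' @return nonnegative `n_modules` x `n_points` matrix, each row max = 1.
#' @export
generate_activation_signals <- function(n_modules, n_points, peak_pcts,
                                        width_pct = 6, baseline = 0.04,
                                        seed = 0L) {
  if (length(peak_pcts) != n_modules)
    stop("peak_pcts must have length n_modules")
  if (n_points < 2) stop("n_points must be >= 2")
  if (any(peak_pcts < 0 | peak_pcts > 100))
    stop("peak_pcts must lie in [0, 100]")
  if (baseline < 0 || baseline >= 1) stop("baseline must be in [0, 1)")
  pct <- 100 * (seq_len(n_points) - 1) / (n_points - 1)
  P <- t(vapply(seq_len(n_modules), function(n) {
    bump <- exp(-0.5 * ((pct - peak_pcts[n]) / width_pct)^2)
    row <- baseline + (1 - baseline) * bump
    row / max(row)
  }, numeric(n_points)))
  dimnames(P) <- list(paste0("M", seq_len(n_modules)), NULL)
  P
}

#' Planted weightings in amplitude-normalized coordinates
#'
#' Amplitude normalization divides every muscle's envelope by its pooled
#' peak, which rescales the rows of the generative weighting matrix. To
#' compare weightings fitted on normalized envelopes against the planted
#' truth, the truth must be mapped into the same coordinates: rows divided
#' by the per-muscle normalization factors, columns re-normalized to unit
#' Euclidean norm.
#'
#' @param weightings planted M x N weighting matrix.
#' @param norm_factors per-muscle factors, e.g. the `norm_factors` attribute
#'   of [normalize_amplitude()].
#' @return rescaled M x N matrix with unit-norm columns.
#' @export
normalized_truth_weightings <- function(weightings, norm_factors) {
  S <- weightings / norm_factors
  sweep(S, 2, sqrt(colSums(S^2)), "/")
}

#' Cutting-manoeuvre preset ground truth
#'
#' A five-module ground truth shaped like the modular organization reported
#' for cutting manoeuvres: M1 pre-contact dorsiflexor/quadriceps activity,
#' M2 hamstrings/hip extensors around initial contact, M3 knee extensors in
#' load acceptance, M4 plantar flexors in propulsion, M5 trunk/late-cycle
#' muscles. Peak timings default to 8, 37.2, 64.1, 82.9 and 96 percent of
#' the cycle (M2-M4 at the timings reported for cutting; M1/M5 placed in
#' the pre-contact and late-propulsion parts of the cycle).
#'
#' @param n_points cycle samples (default 200).
#' @param noise_level relative noise sd passed to [planted_truth()].
#' @param perturb_spec perturbation list passed to [planted_truth()].
#' @param peak_pcts,width_pct activation-bump geometry.
#' @param seed integer seed recorded with the truth.
#' @return A [planted_truth()] object with muscle row names
#'   [muscle_labels_16].
#' @export
cutting_truth_preset <- function(n_points = 200, noise_level = 0.05,
                                 perturb_spec = list(),
                                 peak_pcts = c(8, 37.2, 64.1, 82.9, 96),
                                 width_pct = 6, seed = 1L) {
  groups <- list(
    M1 = c(TA = 1, PER = 0.6, VM = 0.5, VL = 0.5, RF = 0.4),
    M2 = c(BF = 1, ST = 0.9, GMA = 0.7, GME = 0.5, ESP = 0.3),
    M3 = c(VM = 1, VL = 0.9, RF = 0.7, GME = 0.4, ADD = 0.3),
    M4 = c(SOL = 1, GM = 0.9, PER = 0.5, GMA = 0.3),
    M5 = c(TA = 0.8, ADD = 0.7, TFL = 1, ESP = 0.5, RAB = 0.4, EOB = 0.4)
  )
  S <- matrix(0, length(muscle_labels_16), length(groups),
              dimnames = list(muscle_labels_16, names(groups)))
  for (j in seq_along(groups)) S[names(groups[[j]]), j] <- groups[[j]]
  P <- generate_activation_signals(length(groups), n_points, peak_pcts,
                                   width_pct = width_pct)
  planted_truth(S, P, noise_level = noise_level,
                perturb_spec = perturb_spec, seed = seed)
}
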