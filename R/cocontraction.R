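#' Epoch windows for the co-contraction analysis
#'
#' Three epochs on a common sample base: `pre`, the 10 ms before initial
#' contact; `la` (load acceptance), from initial contact to the negative
#' peak of CoM power; `prp` (propulsion), a 50 ms window centred on the
#' positive CoM-power peak. Windows must be in order and non-overlapping.
#'
#' @param pre,la,prp integer length-2 vectors of inclusive sample bounds.
#' @return an `epoch_set` (named list of windows).
#' @export
epoch_set <- function(pre, la, prp) {
  w <- list(pre = as.integer(pre), la = as.integer(la),
            prp = as.integer(prp))
  for (nm in names(w)) {
    if (length(w[[nm]]) != 2 || w[[nm]][1] > w[[nm]][2])
      stop("epoch '", nm, "' must be an increasing length-2 sample range")
  }
  if (w$pre[2] >= w$la[1] || w$la[2] >= w$prp[1])
    stop("epochs must be non-overlapping and ordered pre < la < prp")
  structure(w, class = "epoch_set")
}

#' Build epoch windows from gait events and CoM-power peaks
#'
#' Converts event times on the force-plate time base into windows on the
#' normalized cycle's sample base: the cycle spans from contralateral initial
#' contact (at `ic_frac` of the cycle before right initial contact) to
#' toe-off.
#'
#' @param events a `gait_events` object (samples at `rate`), see
#'   [detect_stance()].
#' @param power a `power_summary` from [com_power()] on the same base.
#' @param rate force sampling rate in Hz.
#' @param ic_frac fraction of the cycle at which initial contact occurs.
#' @param n_points cycle length in samples.
#' @return list with `epochs` (an [epoch_set()] in cycle samples) and
#'   `stance` (cycle-sample bounds of the stance phase).
#' @export
cycle_epochs <- function(events, power, rate, ic_frac = 0.3,
                         n_points = 200) {
  t_ic <- events$ic / rate
  t_to <- events$toe_off / rate
  stance_s <- t_to - t_ic
  cycle_s <- stance_s / (1 - ic_frac)
  t0 <- t_ic - ic_frac * cycle_s
  samp <- function(t) {
    s <- 1 + round((t - t0) / cycle_s * (n_points - 1))
    min(max(s, 1L), n_points)
  }
  t_neg <- power$neg_peak_sample / rate
  t_pos <- power$pos_peak_sample / rate
  ep <- epoch_set(pre = c(samp(t_ic - 0.010), samp(t_ic) - 1L),
                  la  = c(samp(t_ic), samp(t_neg)),
                  prp = c(samp(t_pos - 0.025), samp(t_pos + 0.025)))
  list(epochs = ep, stance = c(samp(t_ic), samp(t_to)))
}

#' Mean EMG amplitude per muscle and epoch
#'
#' Arithmetic mean of the (stance-normalized) envelope over each epoch
#' window, per muscle; the quantity reported as percent of the stance-period
#' maximum.
#'
#' @param env M x K stance-normalized envelope matrix (see
#'   [epoch_normalize_amplitude()]).
#' @param epochs an [epoch_set()] in the envelope's sample base.
#' @return M x 3 matrix (columns `pre`, `la`, `prp`).
#' @export
epoch_mean_amplitude <- function(env, epochs) {
  env <- as.matrix(env)
  cols <- lapply(names(epochs), function(nm) {
    w <- epochs[[nm]]
    if (w[1] < 1 || w[2] > ncol(env) || w[2] < w[1])
      stop("epoch '", nm, "' is empty or outside the envelope")
    rowMeans(env[, w[1]:w[2], drop = FALSE])
  })
  out <- matrix(unlist(cols), nrow(env), length(epochs),
                dimnames = list(rownames(env), names(epochs)))
  out
}

# pull the five knee muscles from a named mean vector
knee_means <- function(means) {
  need <- c(knee_flexors, knee_extensors)
  if (!all(need %in% names(means)))
    stop("means must be named and include ", paste(need, collapse = ", "))
  means[need]
}

#' Knee co-contraction ratio
#'
#' `CCR = ((BF + ST) / 2) / ((VM + VL + RF) / 3)`: mean knee-flexor EMG over
#' mean knee-extensor EMG in an epoch. Invariant to a common rescaling of
#' all five muscles.
#'
#' @param means named per-muscle mean amplitudes for one epoch (one column
#'   of [epoch_mean_amplitude()]).
#' @return scalar ratio.
#' @export
ccr <- function(means) {
  m <- knee_means(means)
  ext <- mean(m[knee_extensors])
  if (ext <= 0) stop("zero knee-extensor activity: CCR undefined")
  mean(m[knee_flexors]) / ext
}

#' Knee co-contraction index
#'
#' `CCI = mean(BF, ST, VM, VL, RF) x CCR`: the overall activation level of
#' the five knee muscles times the co-contraction ratio, so the index is
#' homogeneous of degree 1 in a common rescaling while CCR is invariant.
#' `method = "sum"` uses the sum of the five means instead of their mean.
#'
#' @param means named per-muscle mean amplitudes for one epoch.
#' @param method `"mean"` (default) or `"sum"` aggregation of the five
#'   muscles.
#' @return scalar index.
#' @export
cci <- function(means, method = c("mean", "sum")) {
  method <- match.arg(method)
  m <- knee_means(means)
  level <- if (method == "mean") mean(m) else sum(m)
  level * ccr(means)
}
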