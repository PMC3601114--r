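#' Detect stance from the vertical ground reaction force
#'
#' Initial contact is the first sample where `Fz` exceeds the threshold
#' (default 20 N) and stays above it for the debounce window; toe-off is the
#' first subsequent sample where `Fz` drops to or below the threshold and
#' stays there for the debounce window. Sub-debounce spikes are ignored.
#'
#' @param fz vertical force series in newtons (nonnegative baseline noise
#'   below the threshold).
#' @param rate sampling rate in Hz.
#' @param threshold contact threshold in newtons (default 20).
#' @param debounce_ms minimum hold time in milliseconds (default 5).
#' @return a `gait_events` list: `ic`, `toe_off` (sample indices), `rate`.
#' @export
detect_stance <- function(fz, rate = 1024, threshold = 20,
                          debounce_ms = 5) {
  deb <- max(1L, round(debounce_ms / 1000 * rate))
  above <- fz > threshold
  if (!any(above)) stop("no contact: Fz never exceeds ", threshold, " N")
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ic_runs <- which(r$values & r$lengths >= deb)
  if (length(ic_runs) == 0)
    stop("no contact longer than the debounce window")
  ic_run <- ic_runs[1]
  ic <- starts[ic_run]
  # toe-off: first sustained below-threshold run after initial contact
  off_runs <- which(!r$values & r$lengths >= deb &
                      starts > ic)
  toe_off <- if (length(off_runs) > 0) starts[off_runs[1]] else length(fz)
  structure(list(ic = ic, toe_off = toe_off, rate = rate,
                 threshold = threshold),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("Gait events: IC at sample %d, toe-off at %d (%.1f ms stance)\n",
              x$ic, x$toe_off, 1000 * (x$toe_off - x$ic) / x$rate))
  invisible(x)
}

# linear resampling of a channel matrix (rows = channels) between rates
resample_rows <- function(x, from_rate, to_n, to_rate) {
  t_from <- (seq_len(ncol(x)) - 1) / from_rate
  t_to <- (seq_len(to_n) - 1) / to_rate
  out <- t(vapply(seq_len(nrow(x)), function(i)
    approx(t_from, x[i, ], t_to, rule = 2)$y, numeric(to_n)))
  rownames(out) <- rownames(x)
  out
}

#' Centre-of-mass power and external work phases
#'
#' `P(t) = F(t) . v(t) / mass` in watts per kilogram of body mass (the
#' per-body-weight convention; `normalize = "weight"` divides by `mass * g`
#' instead). The load-acceptance phase is the contiguous negative-power span
#' (the longest one before the longest positive span when the trace changes
#' sign more than once, which is logged); propulsion is the positive span.
#' Phase works are trapezoidal time-integrals of the power, in J/kg.
#'
#' @param x a `cycle_kinetics` object, or a 3 x T GRF matrix (rows
#'   Fx/Fy/Fz).
#' @param com_v 3 x Tk CoM velocity matrix (m/s); resampled to the force
#'   base when `kin_rate` differs from `rate`. Required unless `x` is a
#'   `cycle_kinetics`.
#' @param body_mass body mass in kg.
#' @param rate force sampling rate in Hz.
#' @param kin_rate velocity sampling rate in Hz; required when the velocity
#'   length differs from the force length.
#' @param normalize `"mass"` (W/kg, default) or `"weight"` (W/N).
#' @return a `power_summary`: `com_power` (T values), `w_lac`, `w_prp`
#'   (J/kg), `neg_peak_sample`, `pos_peak_sample`, `la_window`,
#'   `prp_window`, `rate`.
#' @export
com_power <- function(x, com_v = NULL, body_mass = NULL, rate = NULL,
                      kin_rate = NULL, normalize = c("mass", "weight")) {
  normalize <- match.arg(normalize)
  if (inherits(x, "cycle_kinetics")) {
    grf <- x$grf
    com_v <- x$com_velocity
    body_mass <- x$body_mass
    rate <- x$rate
    kin_rate <- x$kin_rate
  } else grf <- as.matrix(x)
  if (is.null(com_v) || is.null(body_mass) || is.null(rate))
    stop("com_v, body_mass and rate are required")
  if (ncol(com_v) != ncol(grf)) {
    if (is.null(kin_rate))
      stop("velocity and force lengths differ; supply kin_rate to resample")
    com_v <- resample_rows(com_v, kin_rate, ncol(grf), rate)
  }
  denom <- if (normalize == "mass") body_mass else body_mass * 9.81
  p <- colSums(grf * com_v) / denom
  tt <- (seq_along(p) - 1) / rate

  neg <- p < 0; pos <- p > 0
  r <- rle(pos - neg)  # -1 negative, 0 zero, 1 positive
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  pos_runs <- which(r$values == 1)
  neg_runs <- which(r$values == -1)
  if (length(pos_runs) == 0 || length(neg_runs) == 0)
    stop("CoM power must have both a negative and a positive phase")
  if (length(pos_runs) > 1 || length(neg_runs) > 1)
    message("CoM power changes sign more than once; using the longest ",
            "negative span before the longest positive span")
  main_pos <- pos_runs[which.max(r$lengths[pos_runs])]
  cand_neg <- neg_runs[starts[neg_runs] < starts[main_pos]]
  if (length(cand_neg) == 0) cand_neg <- neg_runs
  main_neg <- cand_neg[which.max(r$lengths[cand_neg])]
  la <- starts[main_neg]:ends[main_neg]
  prp <- starts[main_pos]:ends[main_pos]

  # extend each phase by one sample and clip the power to its sign, so the
  # trapezoids across the zero crossings are split exactly between phases
  ext <- function(w) max(1L, w[1] - 1L):min(length(p), w[length(w)] + 1L)
  w_lac <- pracma::trapz(tt[ext(la)], pmin(p[ext(la)], 0))
  w_prp <- pracma::trapz(tt[ext(prp)], pmax(p[ext(prp)], 0))
  structure(list(com_power = p,
                 w_lac = w_lac, w_prp = w_prp,
                 neg_peak_sample = la[which.min(p[la])],
                 pos_peak_sample = prp[which.max(p[prp])],
                 la_window = range(la), prp_window = range(prp),
                 rate = rate, normalize = normalize),
            class = "power_summary")
}

#' @export
print.power_summary <- function(x, ...) {
  cat(sprintf(
    "CoM power: W_LAC %.2f J/kg, W_PRP %.2f J/kg; peaks at samples %d / %d\n",
    x$w_lac, x$w_prp, x$neg_peak_sample, x$pos_peak_sample))
  invisible(x)
}

#' CoM approach speed before initial contact
#'
#' Mean magnitude of the CoM velocity over a window before initial contact
#' (default 200 to 100 ms prior). Velocity is obtained from position by
#' second-order central differences after a zero-phase 10 Hz low-pass.
#'
#' @param com_position 3 x T CoM position matrix in metres.
#' @param rate kinematic sampling rate in Hz.
#' @param ic_time time of initial contact in seconds on the same base.
#' @param window length-2 numeric, seconds relative to `ic_time` (default
#'   `c(-0.2, -0.1)`).
#' @param lp low-pass cutoff in Hz (default 10; `NULL` to skip filtering).
#' @return mean speed in m/s.
#' @export
com_speed <- function(com_position, rate, ic_time,
                      window = c(-0.2, -0.1), lp = 10) {
  pos <- as.matrix(com_position)
  tt <- (seq_len(ncol(pos)) - 1) / rate
  if (!is.null(lp)) {
    bf <- signal::butter(2, lp / (rate / 2), type = "low")
    pos <- t(apply(pos, 1, function(x) filtfilt_refl(bf$b, bf$a, x)))
  }
  vel <- t(apply(pos, 1, function(x) pracma::gradient(x, 1 / rate)))
  sel <- tt >= ic_time + window[1] & tt <= ic_time + window[2]
  if (!any(sel) || ic_time + window[1] < 0)
    stop("speed window lies outside the recording")
  mean(sqrt(colSums(vel[, sel, drop = FALSE]^2)))
}

#' Peak horizontal forces in the first half of stance
#'
#' Maximum absolute anterior-posterior (`Fy`) and medial-lateral (`Fx`)
#' force over the first half of the stance phase, normalized by body mass.
#'
#' @param grf 3 x T force matrix with rows `Fx`, `Fy`, `Fz` (newtons).
#' @param events a `gait_events` object from [detect_stance()].
#' @param body_mass body mass in kg.
#' @return named vector `c(hf_ap = , hf_ml = )` in N/kg.
#' @export
horizontal_force_peaks <- function(grf, events, body_mass) {
  half <- events$ic:(events$ic + (events$toe_off - events$ic) %/% 2)
  if (length(half) < 1) stop("empty first-half-of-stance window")
  c(hf_ap = max(abs(grf["Fy", half])) / body_mass,
    hf_ml = max(abs(grf["Fx", half])) / body_mass)
}

#' Phase-wise peaks and timings of a stance-aligned series
#'
#' Extracts the extremum of a joint-angle or joint-moment series within the
#' load-acceptance and propulsion phases, with timing as percent of stance.
#'
#' @param series numeric vector on the force sample base.
#' @param phases a `power_summary` providing the phase windows.
#' @param events a `gait_events` giving the stance bounds.
#' @param mode `"max"`, `"min"` or `"absmax"`.
#' @return 2 x 2 matrix: rows `la`, `prp`; columns `peak`, `timing_pct`.
#' @export
series_peaks <- function(series, phases, events,
                         mode = c("max", "min", "absmax")) {
  mode <- match.arg(mode)
  stance_len <- events$toe_off - events$ic
  pick <- function(w) {
    w <- w[1]:w[2]
    w <- w[w >= 1 & w <= length(series)]
    if (length(w) == 0) stop("empty phase window")
    v <- series[w]
    i <- switch(mode, max = which.max(v), min = which.min(v),
                absmax = which.max(abs(v)))
    c(peak = v[i], timing_pct = 100 * (w[i] - events$ic) / stance_len)
  }
  out <- rbind(la = pick(phases$la_window), prp = pick(phases$prp_window))
  out
}
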