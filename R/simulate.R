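#' Support-surface perturbation parameters
#'
#' The perturbed condition emulated by the generator: an unexpected
#' translation of the force platform delivered at initial contact, 10 cm
#' over 150 ms in the original running direction. The implied average
#' platform speed (10 cm / 0.150 s = 66.7 cm/s) is the scale of the balance
#' disturbance.
#'
#' @param translation_cm platform translation in centimetres.
#' @param duration_ms translation duration in milliseconds.
#' @return list with the parameters and `speed_cm_s`, the average speed.
#' @export
platform_perturbation <- function(translation_cm = 10, duration_ms = 150) {
  if (translation_cm <= 0 || duration_ms <= 0)
    stop("translation and duration must be positive")
  list(translation_cm = translation_cm, duration_ms = duration_ms,
       speed_cm_s = translation_cm / (duration_ms / 1000))
}

#' Apply a perturbation specification to activation signals
#'
#' Each entry of `perturb_spec` multiplies one module's activation signal by
#' `gain` inside a window of the cycle given in percent. Samples outside the
#' window, and all other modules, are untouched.
#'
#' @param activations nonnegative N x K matrix.
#' @param perturb_spec list of entries with fields `module`, `start_pct`,
#'   `end_pct`, `gain` (see [planted_truth()]).
#' @return the modulated N x K matrix.
#' @export
apply_perturbation <- function(activations, perturb_spec) {
  K <- ncol(activations)
  pct <- 100 * (seq_len(K) - 1) / (K - 1)
  for (p in perturb_spec) {
    sel <- pct >= p$start_pct & pct <= p$end_pct
    activations[p$module, sel] <- p$gain * activations[p$module, sel]
  }
  activations
}

#' Synthesize EMG-envelope trials from planted ground truth
#'
#' Each trial is `S %*% P` plus additive Gaussian noise clipped at zero, with
#' noise standard deviation `noise_level * RMS(S %*% P)`. For perturbed
#' trials (`condition = "PTB"`) the truth's `perturb_spec` is applied to the
#' activation signals before mixing. Optional peak jitter shifts each
#' module's activation signal by a random percentage of the cycle per trial.
#'
#' @param truth a [planted_truth()] object.
#' @param n_trials number of trials (>= 1).
#' @param condition `"UPT"` (unperturbed) or `"PTB"` (perturbed).
#' @param seed integer seed; defaults to the truth's seed.
#' @param jitter_pct sd of the per-trial, per-module peak-time jitter in
#'   percent of cycle (default 0, i.e. trials differ only by noise).
#' @return A `trial_set`: list with `trials` (list of M x K matrices),
#'   `conditions` (character vector) and `truth`.
#' @export
synthesize_trials <- function(truth, n_trials, condition = c("UPT", "PTB"),
                              seed = truth$seed, jitter_pct = 0) {
  condition <- match.arg(condition)
  if (n_trials < 1) stop("n_trials must be >= 1")
  set.seed(as.integer(seed))
  S <- truth$weightings
  P0 <- truth$activations
  if (condition == "PTB") P0 <- apply_perturbation(P0, truth$perturb_spec)
  K <- ncol(P0)
  pct <- 100 * (seq_len(K) - 1) / (K - 1)
  trials <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    P <- P0
    if (jitter_pct > 0) {
      for (n in seq_len(nrow(P))) {
        shift <- rnorm(1, 0, jitter_pct)
        P[n, ] <- approx(pct + shift, P[n, ], xout = pct, rule = 2)$y
      }
    }
    clean <- S %*% P
    if (truth$noise_level > 0) {
      sigma <- truth$noise_level * sqrt(mean(clean^2))
      noisy <- clean + matrix(rnorm(length(clean), 0, sigma),
                              nrow(clean), ncol(clean))
      clean <- pmax(noisy, 0)
    }
    rownames(clean) <- rownames(S)
    trials[[t]] <- clean
  }
  structure(list(trials = trials,
                 conditions = rep(condition, n_trials),
                 truth = truth),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$trials[[1]])
  cat(sprintf("Trial set: %d trial(s) (%s), %d muscles x %d points\n",
              length(x$trials), paste(unique(x$conditions), collapse = "/"),
              d[1], d[2]))
  invisible(x)
}

#' Synthesize force-plate and centre-of-mass traces for one stance
#'
#' Builds a cutting-like kinetic trial: vertical GRF rising through the 20 N
#' contact threshold as a half-sine of amplitude `peak_fz`; a braking
#' (anterior-posterior) and a medial-lateral force bump peaking in the first
#' half of stance; CoM velocity with constant approach speed before contact,
#' decelerating forward motion, and a vertical component that makes the CoM
#' power (F.v per kg) strictly negative during load acceptance and strictly
#' positive during propulsion, with a single sign change mid-stance. Forces
#' are sampled at `rate` (default 1024 Hz), CoM kinematics at `kin_rate`
#' (default 256 Hz).
#'
#' @param stance_ms stance duration in milliseconds (> 0).
#' @param body_mass body mass in kg.
#' @param peak_fz peak vertical force in newtons.
#' @param com_speed approach speed of the CoM in m/s.
#' @param seed integer seed for the (small) force baseline noise.
#' @param rate,kin_rate force and kinematic sampling rates in Hz.
#' @param lead_in_ms,tail_ms unloaded time before contact and after toe-off.
#' @param crossing_frac fraction of stance at which CoM power changes sign.
#' @param fz_noise_sd sd of additive vertical-force noise in newtons
#'   (default 0: the trace is clean, so the negative-then-positive CoM-power
#'   profile holds strictly; add noise to probe detection robustness).
#' @return A `cycle_kinetics` object: `grf` (3 x T, rows Fx/Fy/Fz), `time`,
#'   `rate`, `body_mass`, `com_velocity`/`com_position` (3 x Tk at
#'   `kin_rate`), `kin_time`, and `events_true` (planted ic/toe-off samples
#'   at the force rate).
#' @export
synthesize_kinetics <- function(stance_ms, body_mass = 71, peak_fz = 1500,
                                com_speed = 2.67, seed = 1L, rate = 1024,
                                kin_rate = 256, lead_in_ms = 300,
                                tail_ms = 100, crossing_frac = 0.5,
                                fz_noise_sd = 0) {
  if (stance_ms <= 0) stop("stance_ms must be > 0")
  set.seed(as.integer(seed))
  total_s <- (lead_in_ms + stance_ms + tail_ms) / 1000
  time <- seq(0, total_s, by = 1 / rate)
  t_ic <- lead_in_ms / 1000
  t_to <- (lead_in_ms + stance_ms) / 1000
  s <- (time - t_ic) / (t_to - t_ic)          # stance fraction; <0 pre, >1 post
  on <- s > 0 & s < 1

  fz <- numeric(length(time))
  fz[on] <- peak_fz * sin(pi * s[on])
  fy <- numeric(length(time))                 # braking bump (negative, AP)
  fy[on] <- -0.47 * peak_fz * exp(-0.5 * ((s[on] - 0.20) / 0.08)^2)
  fx <- numeric(length(time))                 # medial-lateral bump
  fx[on] <- 0.33 * peak_fz * exp(-0.5 * ((s[on] - 0.25) / 0.08)^2)

  # planted events from the clean vertical force
  ic_true <- which(fz > 20)[1]
  to_true <- ic_true + max(which(fz[ic_true:length(fz)] > 20)) - 1L
  if (fz_noise_sd > 0) fz <- pmax(fz + rnorm(length(fz), 0, fz_noise_sd), 0)

  # CoM velocity on the force time base, then sampled at kin_rate
  sc <- pmin(pmax(s, 0), 1)
  vy <- com_speed * (1 - 0.55 * sc)           # forward speed decays in stance
  vx <- 0.6 * sc * (sc > 0)                   # lateral speed builds in the turn
  vz <- numeric(length(time))
  lo <- on & s <= crossing_frac
  hi <- on & s > crossing_frac
  vz[lo] <- -0.8 * sin(pi * s[lo] / crossing_frac)
  vz[hi] <- 0.8 * sin(pi * (s[hi] - crossing_frac) / (1 - crossing_frac))

  kin_time <- seq(0, total_s, by = 1 / kin_rate)
  vk <- rbind(approx(time, vx, kin_time)$y,
              approx(time, vy, kin_time)$y,
              approx(time, vz, kin_time)$y)
  pk <- t(apply(vk, 1, function(v) cumsum(v) / kin_rate))
  rownames(vk) <- rownames(pk) <- c("x", "y", "z")

  grf <- rbind(Fx = fx, Fy = fy, Fz = fz)
  structure(list(grf = grf, time = time, rate = rate, body_mass = body_mass,
                 com_velocity = vk, com_position = pk, kin_time = kin_time,
                 kin_rate = kin_rate,
                 events_true = list(ic = ic_true, toe_off = to_true),
                 stance_ms = stance_ms, com_speed = com_speed),
            class = "cycle_kinetics")
}

#' @export
print.cycle_kinetics <- function(x, ...) {
  cat(sprintf(
    "Cycle kinetics: %.0f ms stance, %.0f kg, %d force samples @ %g Hz\n",
    x$stance_ms, x$body_mass, ncol(x$grf), x$rate))
  invisible(x)
}

#' Simulate a full synthetic subject (UPT + PTB trials with kinetics)
#'
#' Emulates the study layout: `n_upt` unperturbed cutting trials, one (or
#' more) perturbed trial in which the hamstrings/hip-extensor module's
#' activation is down-scaled from initial contact through load acceptance,
#' plus per-trial force-plate/CoM traces. Initial contact sits at
#' `ic_frac` of the normalized cycle (the cycle runs from contralateral
#' initial contact to ipsilateral toe-off).
#'
#' @param n_upt,n_ptb trial counts per condition.
#' @param noise_level relative envelope noise sd.
#' @param perturb_spec perturbation entries; default down-scales module 2 by
#'   0.6 over 30-60 percent of the cycle.
#' @param stance_ms,body_mass,peak_fz,com_speed kinetic parameters.
#' @param ic_frac fraction of the cycle at which right initial contact occurs.
#' @param n_points envelope cycle samples.
#' @param seed integer master seed.
#' @return A `synthetic_subject`: `trials` (combined `trial_set`), `kinetics`
#'   (per-trial `cycle_kinetics`), `truth`, and `cycle` metadata.
#' @export
simulate_subject <- function(n_upt = 10, n_ptb = 1, noise_level = 0.05,
                             perturb_spec = list(list(module = 2,
                                                      start_pct = 30,
                                                      end_pct = 60,
                                                      gain = 0.85)),
                             stance_ms = 330, body_mass = 71,
                             peak_fz = 1500, com_speed = 2.67,
                             ic_frac = 0.3, n_points = 200, seed = 1L) {
  if (n_upt < 1) stop("at least one unperturbed trial is required")
  seed <- as.integer(seed)
  truth <- cutting_truth_preset(n_points = n_points,
                                noise_level = noise_level,
                                perturb_spec = perturb_spec, seed = seed)
  upt <- synthesize_trials(truth, n_upt, "UPT", seed = seed)
  ptb <- synthesize_trials(truth, n_ptb, "PTB", seed = seed + 1000L)
  trials <- structure(list(trials = c(upt$trials, ptb$trials),
                           conditions = c(upt$conditions, ptb$conditions),
                           truth = truth),
                      class = "trial_set")
  kin <- lapply(seq_len(n_upt + n_ptb), function(i)
    synthesize_kinetics(stance_ms, body_mass, peak_fz, com_speed,
                        seed = seed + 2000L + i))
  structure(list(trials = trials, kinetics = kin, truth = truth,
                 cycle = list(ic_frac = ic_frac, stance_ms = stance_ms,
                              n_points = n_points)),
            class = "synthetic_subject")
}

# ---------------------------------------------------------------------------
# Plain-text interchange: EMG CSV dialect, truth JSON sidecar, kinetics TSV.

#' Write / read an envelope matrix in the package's EMG CSV dialect
#'
#' One row per muscle; the first column holds the muscle label, remaining
#' columns the samples.
#'
#' @param x M x K matrix with muscle row names.
#' @param path file path.
#' @export
write_emg_csv <- function(x, path) {
  df <- data.frame(muscle = rownames(x), x, check.names = FALSE)
  colnames(df) <- c("muscle", paste0("s", seq_len(ncol(x))))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_emg_csv
#' @export
read_emg_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  colnames(m) <- NULL
  m
}

#' Write / read planted ground truth as a JSON sidecar
#' @param truth a [planted_truth()] object.
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(list(weightings = truth$weightings,
                            activations = truth$activations,
                            noise_level = truth$noise_level,
                            perturb_spec = truth$perturb_spec,
                            seed = truth$seed,
                            muscles = rownames(truth$weightings)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  S <- as.matrix(j$weightings)
  if (!is.null(j$muscles)) rownames(S) <- j$muscles
  ps <- j$perturb_spec
  if (is.data.frame(ps)) ps <- lapply(seq_len(nrow(ps)), function(i) as.list(ps[i, ]))
  if (is.null(ps)) ps <- list()
  planted_truth(S, as.matrix(j$activations), j$noise_level, ps, j$seed)
}

#' Write / read kinetic traces as TSV
#'
#' Columns `time_s, Fx, Fy, Fz, CoM_vx, CoM_vy, CoM_vz` on the force time
#' base; CoM velocity is linearly resampled to the force rate for writing and
#' kept there on reading.
#'
#' @param kin a `cycle_kinetics` object.
#' @param path file path.
#' @export
write_kinetics_tsv <- function(kin, path) {
  vk <- t(vapply(1:3, function(i)
    approx(kin$kin_time, kin$com_velocity[i, ], kin$time, rule = 2)$y,
    numeric(length(kin$time))))
  df <- data.frame(time_s = kin$time,
                   Fx = kin$grf["Fx", ], Fy = kin$grf["Fy", ],
                   Fz = kin$grf["Fz", ],
                   CoM_vx = vk[1, ], CoM_vy = vk[2, ], CoM_vz = vk[3, ])
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_kinetics_tsv
#' @param body_mass body mass in kg attached to the returned object.
#' @export
read_kinetics_tsv <- function(path, body_mass = NA_real_) {
  df <- read.delim(path)
  need <- c("time_s", "Fx", "Fy", "Fz", "CoM_vx", "CoM_vy", "CoM_vz")
  if (!all(need %in% names(df)))
    stop("kinetics TSV must contain columns: ", paste(need, collapse = ", "))
  rate <- round(1 / median(diff(df$time_s)))
  grf <- rbind(Fx = df$Fx, Fy = df$Fy, Fz = df$Fz)
  vk <- rbind(x = df$CoM_vx, y = df$CoM_vy, z = df$CoM_vz)
  pk <- t(apply(vk, 1, function(v) cumsum(v) / rate))
  structure(list(grf = grf, time = df$time_s, rate = rate,
                 body_mass = body_mass, com_velocity = vk,
                 com_position = pk, kin_time = df$time_s, kin_rate = rate,
                 events_true = NULL, stance_ms = NA_real_,
                 com_speed = NA_real_),
            class = "cycle_kinetics")
}
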