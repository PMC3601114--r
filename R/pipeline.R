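#' Run the full per-subject analysis workflow
#'
#' Orchestrates the study pipeline on one subject: amplitude normalization,
#' concatenated unperturbed NMF with VAF dimensionality selection, perturbed
#' fits at the selected dimensionality, module similarity between conditions,
#' fixed-factor cross-reconstructions with random baselines, activation peak
#' timings, stance-normalized epoch/co-contraction metrics, and kinetic
#' summaries. Deterministic for a given seed.
#'
#' @param subject a `synthetic_subject` from [simulate_subject()], or a
#'   subject assembled by [load_study_config()].
#' @param n_range module counts for the VAF curve (must start at 1).
#' @param floor,gain_eps dimensionality-selection parameters
#'   (see [select_dimensionality()]).
#' @param n_restarts NMF restarts per fit.
#' @param iterations multiplicative updates for fixed-factor fits.
#' @param seed integer seed for all stochastic stages.
#' @return a `subject_report` list; see Details in the package vignette.
#' @export
run_subject <- function(subject, n_range = 1:8, floor = 0.80, gain_eps = 3,
                        n_restarts = 5, iterations = 1000, seed = 1L) {
  seed <- as.integer(seed)
  trials <- subject$trials
  is_upt <- trials$conditions == "UPT"
  if (!any(is_upt)) stop("stage trials: at least one UPT trial is required")
  if (sum(!is_upt) > 1)
    stop("stage trials: at most one PTB trial per subject is supported")

  norm <- normalize_amplitude(trials$trials)
  upt <- norm[is_upt]
  ptb <- norm[!is_upt]
  n_points <- ncol(upt[[1]])

  # dimensionality from the concatenated unperturbed trials
  X_upt <- concatenate_trials(upt)
  curve <- vaf_curve(X_upt, n_range = n_range, seed = seed,
                     n_restarts = n_restarts)
  N <- select_dimensionality(curve, floor = floor, gain_eps = gain_eps)
  mod_upt <- curve$fits[[which(curve$n_values == as.integer(N))]]

  report <- list(
    n_modules = as.integer(N),
    dimensionality_flagged = attr(N, "flagged"),
    vaf_curve = data.frame(n_modules = curve$n_values,
                           vaf = curve$vaf_values),
    upt = list(fit_vaf = mod_upt$vaf$global_vaf,
               weightings = mod_upt$weightings,
               peak_pct = peak_timing(
                 cycle_average_activations(mod_upt$activations, n_points)))
  )

  if (length(ptb) == 1) {
    X_ptb <- ptb[[1]]
    mod_ptb <- synergy_nmf(X_ptb, as.integer(N), seed = seed + 1L,
                           n_restarts = n_restarts)
    P_upt_cycle <- cycle_average_activations(mod_upt$activations, n_points)
    cross <- list(
      fixed_weightings = fixed_factor_fit(X_ptb, mod_upt$weightings,
                                          "weightings", iterations,
                                          seed = seed + 2L),
      fixed_activations = fixed_factor_fit(X_ptb, P_upt_cycle,
                                           "activations", iterations,
                                           seed = seed + 3L),
      random_weightings = fixed_factor_fit(
        X_ptb, random_factor(nrow(X_ptb), as.integer(N), seed + 4L),
        "weightings", iterations, seed = seed + 5L),
      random_activations = fixed_factor_fit(
        X_ptb, random_factor(as.integer(N), n_points, seed + 6L),
        "activations", iterations, seed = seed + 7L))
    report$ptb <- list(fit_vaf = mod_ptb$vaf$global_vaf,
                       weightings = mod_ptb$weightings,
                       peak_pct = peak_timing(mod_ptb$activations))
    report$similarity <- list(
      weightings = match_modules(mod_upt, mod_ptb, on = "weightings"),
      activations = match_modules(
        list(activations = P_upt_cycle),
        list(activations = mod_ptb$activations), on = "activations"))
    report$cross_reconstruction <- data.frame(
      fixed = names(cross),
      vaf = vapply(cross, function(cr) cr$vaf$global_vaf, 1))
    report$cross_fits <- cross
  }

  # epoch / co-contraction analysis on stance-normalized envelopes
  if (!is.null(subject$kinetics)) {
    ic_frac <- subject$cycle$ic_frac
    kin1 <- subject$kinetics[[1]]
    ev <- detect_stance(kin1$grf["Fz", ], kin1$rate)
    pw <- com_power(kin1)
    ce <- cycle_epochs(ev, pw, kin1$rate, ic_frac, n_points)
    stance_norm <- epoch_normalize_amplitude(trials$trials, ce$stance)
    cc <- lapply(seq_along(stance_norm), function(i) {
      m <- epoch_mean_amplitude(stance_norm[[i]], ce$epochs)
      list(condition = trials$conditions[i],
           ccr = apply(m, 2, ccr), cci = apply(m, 2, cci))
    })
    agg <- function(cond, what) {
      rows <- Filter(function(x) x$condition == cond, cc)
      if (length(rows) == 0) return(NULL)
      colMeans(do.call(rbind, lapply(rows, function(x) x[[what]])))
    }
    report$cocontraction <- list(
      upt = list(ccr = agg("UPT", "ccr"), cci = agg("UPT", "cci")),
      ptb = list(ccr = agg("PTB", "ccr"), cci = agg("PTB", "cci")),
      epochs = ce$epochs, stance = ce$stance)

    kin_sum <- lapply(subject$kinetics, function(k) {
      e <- detect_stance(k$grf["Fz", ], k$rate)
      p <- com_power(k)
      hf <- horizontal_force_peaks(k$grf, e, k$body_mass)
      spd <- com_speed(k$com_position, k$kin_rate, e$ic / k$rate)
      c(stance_ms = 1000 * (e$toe_off - e$ic) / k$rate,
        com_speed = spd, w_lac = p$w_lac, w_prp = p$w_prp, hf)
    })
    report$kinetics <- colMeans(do.call(rbind, kin_sum))
  }

  report$provenance <- list(seed = seed, n_restarts = n_restarts,
                            iterations = iterations, floor = floor,
                            gain_eps = gain_eps,
                            n_trials = length(trials$trials),
                            conditions = table(trials$conditions))
  class(report) <- "subject_report"
  report
}

#' @export
print.subject_report <- function(x, ...) {
  cat(sprintf("Subject report: %d motor modules (UPT VAF %.1f%%)\n",
              x$n_modules, 100 * x$upt$fit_vaf))
  if (!is.null(x$similarity)) {
    cat(sprintf("  UPT vs PTB similarity: weightings %.3f, activations %.3f (median)\n",
                x$similarity$weightings$summary["median"],
                x$similarity$activations$summary["median"]))
  }
  if (!is.null(x$cross_reconstruction)) {
    cr <- x$cross_reconstruction
    cat("  cross-reconstruction VAF (%): ",
        paste(sprintf("%s %.1f", cr$fixed, 100 * cr$vaf), collapse = ", "),
        "\n", sep = "")
  }
  if (!is.null(x$cocontraction$upt$ccr)) {
    cat("  CCR (UPT): ",
        paste(sprintf("%s %.2f", names(x$cocontraction$upt$ccr),
                      x$cocontraction$upt$ccr), collapse = ", "), "\n",
        sep = "")
  }
  if (!is.null(x$kinetics)) {
    cat("  kinetics: ",
        paste(sprintf("%s %.2f", names(x$kinetics), x$kinetics),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Serialize a subject report to JSON
#'
#' @param report a `subject_report`.
#' @param path output file.
#' @export
write_report_json <- function(report, path) {
  strip <- report
  strip$cross_fits <- NULL
  strip$similarity <- lapply(report$similarity, function(s)
    list(pair_similarities = s$pair_similarities, matching = s$matching,
         summary = as.list(s$summary)))
  jsonlite::write_json(strip, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' Load a study configuration and assemble a subject from files
#'
#' Reads a YAML file describing one subject's trials: a list of EMG CSV
#' files with condition labels (written by [write_emg_csv()]), optional
#' kinetics TSVs ([write_kinetics_tsv()]), body mass, and cycle metadata.
#' Exactly one perturbed trial is permitted and at least one unperturbed
#' trial is required.
#'
#' @param path YAML file with fields `trials` (list of `{file, condition}`),
#'   optional `kinetics` (list of files), `body_mass`, `ic_frac`.
#' @return a subject list compatible with [run_subject()].
#' @export
load_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$trials) || length(cfg$trials) == 0)
    stop("config must list at least one trial")
  conds <- vapply(cfg$trials, function(t) t$condition, "")
  if (!all(conds %in% c("UPT", "PTB")))
    stop("trial conditions must be UPT or PTB")
  if (sum(conds == "UPT") < 1) stop("at least one UPT trial is required")
  if (sum(conds == "PTB") > 1) stop("at most one PTB trial is permitted")
  base <- dirname(path)
  resolve <- function(f) if (file.exists(f)) f else file.path(base, f)
  mats <- lapply(cfg$trials, function(t) read_emg_csv(resolve(t$file)))
  trials <- structure(list(trials = mats, conditions = conds, truth = NULL),
                      class = "trial_set")
  kin <- NULL
  if (!is.null(cfg$kinetics)) {
    mass <- if (is.null(cfg$body_mass)) NA_real_ else cfg$body_mass
    kin <- lapply(cfg$kinetics, function(f)
      read_kinetics_tsv(resolve(f), body_mass = mass))
  }
  list(trials = trials, kinetics = kin, truth = NULL,
       cycle = list(ic_frac = if (is.null(cfg$ic_frac)) 0.3 else cfg$ic_frac,
                    n_points = ncol(mats[[1]])))
}

#' Write a synthetic subject to disk in the package's text formats
#'
#' Emits one EMG CSV per trial, one kinetics TSV per trial, the ground-truth
#' JSON sidecar, and a `study.yaml` configuration that
#' [load_study_config()] can read back.
#'
#' @param subject a `synthetic_subject` from [simulate_subject()].
#' @param dir output directory (created if needed).
#' @return the path to the written YAML config.
#' @export
write_subject <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  trials <- subject$trials
  entries <- vector("list", length(trials$trials))
  kin_files <- character(length(subject$kinetics))
  for (i in seq_along(trials$trials)) {
    f <- sprintf("trial_%02d_%s.csv", i, trials$conditions[i])
    write_emg_csv(trials$trials[[i]], file.path(dir, f))
    entries[[i]] <- list(file = f, condition = trials$conditions[i])
    kf <- sprintf("kinetics_%02d.tsv", i)
    write_kinetics_tsv(subject$kinetics[[i]], file.path(dir, kf))
    kin_files[i] <- kf
  }
  write_truth_json(subject$truth, file.path(dir, "truth.json"))
  cfg <- list(trials = entries, kinetics = as.list(kin_files),
              body_mass = subject$kinetics[[1]]$body_mass,
              ic_frac = subject$cycle$ic_frac)
  yaml::write_yaml(cfg, file.path(dir, "study.yaml"))
  file.path(dir, "study.yaml")
}
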