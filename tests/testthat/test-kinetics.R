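test_that("stance detection applies the 20 N threshold with debounce", {
  fz <- c(rep(0, 499), rep(100, 400), rep(0, 100))
  ev <- detect_stance(fz, rate = 1024)
  expect_equal(ev$ic, 500)
  expect_equal(ev$toe_off, 900)

  # single-sample spike shorter than the 5 ms debounce is ignored
  fz2 <- rep(0, 1000); fz2[100] <- 25; fz2[400:800] <- 100
  ev2 <- detect_stance(fz2, rate = 1024, debounce_ms = 5)
  expect_equal(ev2$ic, 400)

  expect_error(detect_stance(rep(5, 100)), "no contact")

  # synthetic trace (with measurement noise): detected events match the
  # planted ones within a sample
  kin <- synthesize_kinetics(330, 71, seed = 7, fz_noise_sd = 1)
  ev3 <- detect_stance(kin$grf["Fz", ], kin$rate)
  expect_lte(abs(ev3$ic - kin$events_true$ic), 1)
  expect_lte(abs(ev3$toe_off - kin$events_true$toe_off), 1)

  # invariant to sub-threshold baseline noise
  set.seed(8)
  noisy <- pmax(kin$grf["Fz", ] + runif(ncol(kin$grf), 0, 9.9), 0)
  ev4 <- detect_stance(noisy, kin$rate)
  expect_lte(abs(ev4$ic - ev3$ic), 2)
})

test_that("CoM power has the load-acceptance sign and integrates works", {
  # downward motion under load: negative power
  grf <- matrix(0, 3, 10, dimnames = list(c("Fx", "Fy", "Fz"), NULL))
  grf["Fz", ] <- 710
  v <- matrix(0, 3, 10); v[3, ] <- -0.5
  p <- colSums(grf * v) / 71
  expect_true(all(p < 0))

  # constant -10 W/kg for 0.1 s integrates to -1 J/kg
  tt <- seq(0, 0.1, length.out = 103)
  p2 <- rep(-10, length(tt))
  expect_equal(pracma::trapz(tt, p2), -1, tolerance = 1e-9)

  # package path: work over phases equals the whole-trace trapezoid
  kin <- synthesize_kinetics(330, 71, seed = 9)
  pw <- com_power(kin)
  tt <- (seq_along(pw$com_power) - 1) / kin$rate
  expect_equal(pw$w_lac + pw$w_prp, trapz_ref(tt, pw$com_power),
               tolerance = 1e-9)
  expect_lte(pw$w_lac, 0)
  expect_gte(pw$w_prp, 0)
  expect_lt(pw$neg_peak_sample, pw$pos_peak_sample)
})

test_that("resampling kinematics before or after power agrees within 1%", {
  kin <- synthesize_kinetics(330, 71, seed = 10)
  pw_resampled <- com_power(kin)   # 256 Hz velocity resampled to 1024
  v1024 <- synergyflow:::resample_rows(kin$com_velocity, kin$kin_rate,
                                       ncol(kin$grf), kin$rate)
  pw_direct <- com_power(kin$grf, v1024, kin$body_mass, kin$rate)
  expect_equal(pw_resampled$w_lac, pw_direct$w_lac, tolerance = 0.01)
  expect_equal(pw_resampled$w_prp, pw_direct$w_prp, tolerance = 0.01)

  # rate mismatch without metadata is an error
  expect_error(com_power(kin$grf, kin$com_velocity, 71, 1024), "kin_rate")
})

test_that("approach speed is read off the pre-contact window", {
  # linear motion at 2.67 m/s
  rate <- 256
  tt <- seq(0, 1, by = 1 / rate)
  pos <- rbind(0 * tt, 2.67 * tt, 0 * tt)
  expect_equal(com_speed(pos, rate, ic_time = 0.5, lp = NULL), 2.67,
               tolerance = 1e-6)
  expect_equal(com_speed(0 * pos, rate, ic_time = 0.5, lp = NULL), 0)
  expect_error(com_speed(pos, rate, ic_time = 0.1), "outside")

  # synthetic trajectory reproduces the planted approach speed
  kin <- synthesize_kinetics(330, 71, com_speed = 2.67, seed = 11)
  ev <- detect_stance(kin$grf["Fz", ], kin$rate)
  spd <- com_speed(kin$com_position, kin$kin_rate, ev$ic / kin$rate)
  expect_equal(spd, 2.67, tolerance = 0.01 * 2.67)
})

test_that("horizontal force peaks scan the first half of stance only", {
  n <- 1000
  grf <- matrix(0, 3, n, dimnames = list(c("Fx", "Fy", "Fz"), NULL))
  grf["Fz", 200:800] <- 1000
  # triangular AP pulse peaking at 710 N inside the first half
  grf["Fy", 250:349] <- -710 * c(seq(0, 1, length.out = 50),
                                 seq(1, 0, length.out = 50))
  ev <- detect_stance(grf["Fz", ])
  hf <- horizontal_force_peaks(grf, ev, 71)
  expect_equal(unname(hf["hf_ap"]), 10.0, tolerance = 1e-9)
  expect_equal(unname(hf["hf_ml"]), 0)

  # a larger peak in the second half is excluded
  grf2 <- grf
  grf2["Fy", 700:750] <- -2000
  hf2 <- horizontal_force_peaks(grf2, ev, 71)
  expect_equal(unname(hf2["hf_ap"]), 10.0, tolerance = 1e-9)
})

test_that("series peaks report phase extrema with stance timing", {
  kin <- synthesize_kinetics(330, 71, seed = 12)
  ev <- detect_stance(kin$grf["Fz", ], kin$rate)
  pw <- com_power(kin)
  # monotone ramp over the trace peaks at the end of propulsion
  ramp <- seq(0, 1, length.out = length(pw$com_power))
  sp <- series_peaks(ramp, pw, ev, mode = "max")
  expect_equal(unname(sp["prp", "peak"]),
               ramp[pw$prp_window[2]], tolerance = 1e-12)
  expect_gt(sp["prp", "timing_pct"], sp["la", "timing_pct"])

  # planted two-bump series: peaks and timings recovered exactly
  s2 <- numeric(length(ramp))
  i_la <- pw$la_window[1] + 10; i_prp <- pw$prp_window[1] + 10
  s2[i_la] <- -2; s2[i_prp] <- 3
  expect_equal(unname(series_peaks(s2, pw, ev, "min")["la", "peak"]), -2)
  expect_equal(unname(series_peaks(s2, pw, ev, "max")["prp", "peak"]), 3)
  expect_equal(unname(series_peaks(s2, pw, ev, "absmax")["prp", "timing_pct"]),
               100 * (i_prp - ev$ic) / (ev$toe_off - ev$ic))
})
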