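test_that("generated module sets satisfy the planted-truth contract", {
  S <- generate_module_set(16, 5, 0.4, seed = 1)
  expect_equal(dim(S), c(16L, 5L))
  expect_true(all(S >= 0))
  expect_equal(sqrt(colSums(S^2)), rep(1, 5))
  expect_true(all(rowSums(S) > 0))
  # roughly the requested sparsity
  expect_gt(mean(S == 0), 0.2)
  expect_lt(mean(S == 0), 0.6)

  S2 <- generate_module_set(2, 2, 0, seed = 7)
  expect_equal(sqrt(colSums(S2^2)), rep(1, 2))

  expect_error(generate_module_set(3, 5, 0, seed = 1), "exceed")
  expect_error(generate_module_set(16, 5, 0.4), "seed")

  # reproducibility
  expect_identical(generate_module_set(16, 5, 0.4, seed = 3),
                   generate_module_set(16, 5, 0.4, seed = 3))
})

test_that("activation bumps peak at the requested cycle percentages", {
  P <- generate_activation_signals(5, 200, c(10, 37, 64, 83, 95), 8)
  expect_equal(dim(P), c(5L, 200L))
  expect_true(all(P >= 0))
  expect_equal(apply(P, 1, max), rep(1, 5), ignore_attr = TRUE)
  got <- 100 * (apply(P, 1, which.max) - 1) / 199
  expect_true(all(abs(got - c(10, 37, 64, 83, 95)) <= 100 / 199))

  P1 <- generate_activation_signals(1, 200, 50, 5)
  expect_lte(abs(which.max(P1[1, ]) - 1L - 100L), 1L)

  # timings matching the reported module peak placements
  P2 <- generate_activation_signals(2, 200, c(37.2, 64.1), 8)
  pk <- 100 * (apply(P2, 1, which.max) - 1) / 199
  expect_gte(pk[1], 37.0); expect_lte(pk[1], 37.5)
  expect_gte(pk[2], 64.0); expect_lte(pk[2], 64.5)

  expect_error(generate_activation_signals(2, 200, c(50, 120), 8), "0, 100")
  expect_error(generate_activation_signals(2, 200, 50, 8), "length")
})

test_that("zero-noise trials reproduce S %*% P exactly", {
  truth <- tiny_truth(noise_level = 0)
  ts <- synthesize_trials(truth, 3, "UPT", seed = 5)
  clean <- truth$weightings %*% truth$activations
  for (x in ts$trials) expect_equal(x, clean, ignore_attr = TRUE)
})

test_that("trial synthesis is seed-deterministic and nonnegative", {
  truth <- tiny_truth(noise_level = 0.05)
  a <- synthesize_trials(truth, 10, "UPT", seed = 9)
  b <- synthesize_trials(truth, 10, "UPT", seed = 9)
  expect_identical(a, b)
  expect_true(all(vapply(a$trials, function(x) all(x >= 0), TRUE)))
  expect_error(synthesize_trials(truth, 0, "UPT"), "n_trials")
})

test_that("perturbation gain < 1 lowers exactly the windowed module's output", {
  truth <- cutting_truth_preset(
    noise_level = 0,
    perturb_spec = list(list(module = 2, start_pct = 0, end_pct = 25,
                             gain = 0.5)))
  upt <- synthesize_trials(truth, 1, "UPT", seed = 1)$trials[[1]]
  ptb <- synthesize_trials(truth, 1, "PTB", seed = 1)$trials[[1]]
  K <- ncol(upt)
  pct <- 100 * (seq_len(K) - 1) / (K - 1)
  win <- pct <= 25
  loaded <- truth$weightings[, 2] > 0
  # strictly below wherever module 2 contributes inside the window
  expect_true(all(ptb[loaded, win] < upt[loaded, win]))
  # untouched outside the window and for unloaded muscles
  expect_equal(ptb[, !win], upt[, !win])
  expect_equal(ptb[!loaded, ], upt[!loaded, ])
})

test_that("empirical noise magnitude tracks the nominal level despite clipping", {
  for (nl in c(0.05, 0.1, 0.2)) {
    S <- generate_module_set(16, 5, 0.4, seed = 21)
    P <- generate_activation_signals(5, 200, c(10, 37, 64, 83, 95))
    truth <- planted_truth(S, P, noise_level = nl, seed = 21)
    clean <- S %*% P
    ts <- synthesize_trials(truth, 10, "UPT", seed = 22)
    dev <- unlist(lapply(ts$trials, function(x) x - clean))
    target <- nl * sqrt(mean(clean^2))
    expect_lt(abs(sd(dev) - target) / target, 0.10)
  }
})

test_that("parameter recovery is near-exact at low noise and degrades at high noise", {
  S <- generate_module_set(16, 5, 0.4, seed = 32)
  P <- generate_activation_signals(5, 200, c(10, 37, 64, 83, 95))
  sims <- vapply(c(0, 0.1, 0.2, 0.5, 1.0), function(nl) {
    truth <- planted_truth(S, P, noise_level = nl, seed = 31)
    # shared noise seed: the same noise realization, scaled up with nl
    ts <- synthesize_trials(truth, 5, "UPT", seed = 33)
    norm <- normalize_amplitude(ts$trials)
    X <- concatenate_trials(norm)
    St <- normalized_truth_weightings(S, attr(norm, "norm_factors"))
    fit <- synergy_nmf(X, 5, seed = 34, n_restarts = 3)
    mean(match_modules(fit, list(weightings = St),
                       on = "weightings")$pair_similarities)
  }, 1)
  expect_gt(sims[1], 0.99)
  # weak monotone degradation (estimator jitter tolerance), clear at the end
  expect_true(all(diff(sims) < 5e-3))
  expect_lt(sims[5], sims[1] - 0.02)
})

test_that("synthetic kinetics have contact-threshold crossing and one power sign change", {
  kin <- synthesize_kinetics(330, 71, 1500, 2.67, seed = 1)
  expect_lt(kin$grf["Fz", 1], 20)
  expect_gt(max(kin$grf["Fz", ]), 20)

  pw <- com_power(kin)
  p <- pw$com_power
  s <- sign(p[abs(p) > 1e-9])
  expect_equal(sum(diff(s) != 0), 1)
  expect_lt(pw$w_lac, 0)
  expect_gt(pw$w_prp, 0)

  expect_identical(synthesize_kinetics(330, 71, 1500, 2.67, seed = 1),
                   synthesize_kinetics(330, 71, 1500, 2.67, seed = 1))
  expect_error(synthesize_kinetics(-5, 71), "stance_ms")
})

test_that("text round-trips preserve trials, truth and kinetics", {
  truth <- tiny_truth(noise_level = 0.05)
  ts <- synthesize_trials(truth, 2, "UPT", seed = 2)
  f <- tempfile(fileext = ".csv")
  write_emg_csv(ts$trials[[1]], f)
  back <- read_emg_csv(f)
  expect_equal(back, ts$trials[[1]], tolerance = 1e-12)

  tf <- tempfile(fileext = ".json")
  write_truth_json(truth, tf)
  tr2 <- read_truth_json(tf)
  expect_equal(tr2$weightings, truth$weightings, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(tr2$activations, truth$activations, tolerance = 1e-12,
               ignore_attr = TRUE)

  kin <- synthesize_kinetics(330, 71, seed = 3)
  kf <- tempfile(fileext = ".tsv")
  write_kinetics_tsv(kin, kf)
  kin2 <- read_kinetics_tsv(kf, body_mass = 71)
  expect_equal(kin2$grf, kin$grf, tolerance = 1e-6)
  expect_equal(kin2$rate, kin$rate)
})
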