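test_that("VAF follows 1 - SSE/SST with uncentered SST", {
  X <- matrix(c(1, 3, 2, 4), 2)          # [[1,2],[3,4]]
  Xr <- matrix(c(1, 3, 2, 0), 2)         # [[1,2],[3,0]]
  v <- vaf(X, Xr)
  expect_equal(v$sse, 16)
  expect_equal(v$sst, 30)
  expect_equal(v$global_vaf, 1 - 16 / 30)

  expect_equal(vaf(X, X)$global_vaf, 1)
  expect_equal(vaf(X, 0 * X)$global_vaf, 0)
  expect_error(vaf(0 * X, 0 * X), "SST")
  expect_error(vaf(X, matrix(1, 3, 3)), "shape")

  # per-muscle VAF is row-wise
  expect_equal(v$per_muscle_vaf[1], 1, ignore_attr = TRUE)
  expect_equal(v$per_muscle_vaf[2], 1 - 16 / 25, ignore_attr = TRUE)
})

test_that("rank-limited nonnegative data is reconstructed exactly", {
  set.seed(11)
  u <- runif(8); v <- runif(60)
  X1 <- outer(u, v)
  fit1 <- synergy_nmf(X1, 1, seed = 2, n_restarts = 3)
  expect_gte(fit1$vaf$global_vaf, 0.999)

  truth <- tiny_truth(noise_level = 0)
  X <- truth$weightings %*% truth$activations
  fit <- synergy_nmf(X, 3, seed = 3, n_restarts = 5)
  expect_gte(fit$vaf$global_vaf, 0.999)
})

test_that("multiplicative updates are monotone and match the reference rules", {
  set.seed(21)
  for (rep in 1:5) {
    X <- matrix(runif(12 * 40), 12)
    fit <- synergy_nmf(X, 3, seed = rep, n_restarts = 2)
    expect_true(all(diff(fit$fit$error_trace) <= 1e-8 * fit$fit$error_trace[1]))
    expect_true(all(fit$weightings >= 0))
    expect_true(all(fit$activations >= 0))
  }

  # compiled loop reproduces the independently written update rules
  set.seed(22)
  X <- matrix(runif(6 * 20), 6)
  W0 <- matrix(runif(6 * 2) + 0.1, 6)
  H0 <- matrix(runif(2 * 20) + 0.1, 2)
  ref <- nmf_mu_ref(X, W0, H0, 50)
  cpp <- synergyflow:::.nmf_mu_cpp(X, W0, H0, 50, -1, 0L)
  expect_equal(cpp$W, ref$W, tolerance = 1e-10)
  expect_equal(cpp$H, ref$H, tolerance = 1e-10)
  expect_equal(cpp$error, ref$error, tolerance = 1e-10)
})

test_that("canonicalization preserves the reconstruction and unit norms", {
  truth <- tiny_truth(noise_level = 0.1)
  X <- synthesize_trials(truth, 1, "UPT", seed = 4)$trials[[1]]
  fit <- synergy_nmf(X, 3, seed = 5, n_restarts = 3)
  expect_equal(sqrt(colSums(fit$weightings^2)), rep(1, 3),
               ignore_attr = TRUE)
  expect_equal(fit$reconstruction, fit$weightings %*% fit$activations,
               tolerance = 1e-12)
  # modules ordered by activation peak time
  expect_false(is.unsorted(apply(fit$activations, 1, which.max)))
})

test_that("fits are deterministic and validate their inputs", {
  truth <- tiny_truth(noise_level = 0.1)
  X <- synthesize_trials(truth, 1, "UPT", seed = 6)$trials[[1]]
  a <- synergy_nmf(X, 3, seed = 7, n_restarts = 2)
  b <- synergy_nmf(X, 3, seed = 7, n_restarts = 2)
  expect_identical(a$weightings, b$weightings)
  expect_identical(a$fit$error, b$fit$error)

  expect_error(synergy_nmf(X - 1, 3), "nonnegative")
  expect_error(synergy_nmf(0 * X, 3), "zero")
  expect_error(synergy_nmf(X, 0), "n_modules")
  expect_error(synergy_nmf(X, 100), "n_modules")
})

test_that("dimensionality selection applies the floor-plus-flattening rule", {
  mkcurve <- function(v) structure(list(n_values = seq_along(v),
                                        vaf_values = v, fits = NULL),
                                   class = "vaf_curve")
  expect_equal(as.integer(
    select_dimensionality(mkcurve(c(0.60, 0.75, 0.86, 0.93, 0.95, 0.957)))),
    4L)
  expect_equal(as.integer(select_dimensionality(mkcurve(c(0.95, 0.96)))), 1L)
  expect_error(select_dimensionality(mkcurve(c(0.5, 0.6, 0.7))),
               "insufficient dimensionality")
  # floor reached but curve never flattens: flagged fallback
  res <- select_dimensionality(mkcurve(c(0.81, 0.86, 0.93)))
  expect_equal(as.integer(res), 1L)
  expect_true(attr(res, "flagged"))
  expect_error(select_dimensionality(
    structure(list(n_values = 2:4, vaf_values = c(0.8, 0.9, 0.95)),
              class = "vaf_curve")), "contiguous")
})

test_that("VAF curves are non-decreasing and reproducible", {
  truth <- tiny_truth(noise_level = 0.1)
  ts <- synthesize_trials(truth, 4, "UPT", seed = 8)
  X <- concatenate_trials(normalize_amplitude(ts$trials))
  cv <- vaf_curve(X, 1:5, seed = 9, n_restarts = 2)
  expect_true(all(diff(cv$vaf_values) >= -1e-10))
  cv2 <- vaf_curve(X, 1:5, seed = 9, n_restarts = 2)
  expect_equal(cv$vaf_values, cv2$vaf_values)
  sel <- select_dimensionality(cv)
  expect_equal(as.integer(sel), 3L)
})

test_that("concatenation stacks trials and supports exact recovery", {
  t1 <- matrix(runif(16 * 200), 16)
  t2 <- matrix(runif(16 * 200), 16)
  cc <- concatenate_trials(list(t1, t2))
  expect_equal(dim(cc), c(16L, 400L))
  expect_equal(attr(cc, "boundaries"), c(200L, 400L))
  expect_equal(concatenate_trials(list(t1)), t1, ignore_attr = TRUE)
  expect_error(concatenate_trials(list(t1, matrix(1, 4, 5))), "share")

  # factorizing 10 concatenated zero-noise trials recovers the truth
  truth <- tiny_truth(noise_level = 0)
  ts <- synthesize_trials(truth, 10, "UPT", seed = 10)
  X <- concatenate_trials(ts$trials)
  fit <- synergy_nmf(X, 3, seed = 11, n_restarts = 5, max_iter = 5000,
                     tol = 1e-10)
  r <- match_modules(fit, list(weightings = truth$weightings),
                     on = "weightings")
  expect_true(all(r$pair_similarities >= 0.999))
})

test_that("model methods expose factors, fit and simulation", {
  truth <- tiny_truth(noise_level = 0.05)
  X <- synthesize_trials(truth, 1, "UPT", seed = 12)$trials[[1]]
  fit <- synergy_nmf(X, 3, seed = 13, n_restarts = 2)
  expect_equal(coef(fit), fit$weightings)
  expect_equal(coef(fit, "activations"), fit$activations)
  expect_equal(fitted(fit) + residuals(fit), X, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(predict(fit), fit$reconstruction)
  expect_output(print(fit), "Motor module set")
  expect_output(print(summary(fit)), "global VAF")

  sims <- simulate(fit, nsim = 2, seed = 14)
  expect_length(sims, 2)
  expect_true(all(sims[[1]] >= 0))

  # predict on new data with fixed weightings reconstructs well
  Xnew <- synthesize_trials(truth, 1, "UPT", seed = 15)$trials[[1]]
  rec <- predict(fit, newdata = Xnew)
  expect_gte(attr(rec, "fit")$vaf$global_vaf, 0.95)
})
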