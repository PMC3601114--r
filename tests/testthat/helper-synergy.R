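# Shared fixtures and independent oracles for the test suite.

# Pure-R multiplicative-update NMF, written independently of the package's
# compiled loop; used as the oracle for update-rule equivalence checks.
nmf_mu_ref <- function(X, W, H, n_iter) {
  eps <- 1e-12
  err <- numeric(n_iter + 1)
  err[1] <- sum((X - W %*% H)^2)
  for (it in seq_len(n_iter)) {
    H <- H * (t(W) %*% X) / (t(W) %*% W %*% H + eps)
    W <- W * (X %*% t(H)) / (W %*% (H %*% t(H)) + eps)
    err[it + 1] <- sum((X - W %*% H)^2)
  }
  list(W = W, H = H, error = err)
}

# Small separable ground truth (no tonic baseline): block-structured
# weightings and well-separated bumps, so the factorization is essentially
# unique and exact recovery is expected at zero noise.
tiny_truth <- function(n_muscles = 8, n_modules = 3, n_points = 120,
                       noise_level = 0, seed = 42L) {
  S <- matrix(0, n_muscles, n_modules)
  groups <- split(seq_len(n_muscles),
                  sort(rep_len(seq_len(n_modules), n_muscles)))
  for (j in seq_len(n_modules)) {
    rows <- c(groups[[j]], min(groups[[j]]) - 1)  # one overlapping muscle
    rows <- rows[rows >= 1]
    S[rows, j] <- seq(1, 0.5, length.out = length(rows))
  }
  S <- sweep(S, 2, sqrt(colSums(S^2)), "/")
  rownames(S) <- paste0("mu", seq_len(n_muscles))
  P <- generate_activation_signals(n_modules, n_points,
                                   peak_pcts = seq(15, 85,
                                                   length.out = n_modules),
                                   width_pct = 6, baseline = 0)
  planted_truth(S, P, noise_level = noise_level, seed = seed)
}

# trapezoid integral oracle (independent of pracma)
trapz_ref <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
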