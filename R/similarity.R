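#' Normalized scalar product between two nonnegative vectors
#'
#' `(u . v) / (|u| |v|)`; for nonnegative vectors this similarity lies in
#' `[0, 1]`, reaching 1 for proportional vectors and 0 for vectors with
#' disjoint support.
#'
#' @param u,v numeric vectors of equal length with nonzero norm.
#' @return scalar similarity.
#' @export
normalized_scalar_product <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero vector has undefined similarity")
  sum(u * v) / (nu * nv)
}

# All-pairs similarity matrix between columns of A and B (for weightings)
# or rows (for activations).
similarity_matrix <- function(A, B, on = c("weightings", "activations")) {
  on <- match.arg(on)
  if (on == "activations") { A <- t(A); B <- t(B) }
  if (nrow(A) != nrow(B)) stop("incompatible dimensions for similarity")
  outer(seq_len(ncol(A)), seq_len(ncol(B)),
        Vectorize(function(i, j) normalized_scalar_product(A[, i], B[, j])))
}

# Optimal one-to-one assignment maximizing total similarity, by exhaustive
# permutation search (feasible for the module counts used here, N <= 8);
# greedy fallback for larger N.
solve_assignment <- function(sim, method = c("assignment", "greedy")) {
  method <- match.arg(method)
  N <- nrow(sim)
  if (method == "assignment" && N > 8) {
    warning("assignment matching uses exhaustive search; falling back to ",
            "greedy for N > 8")
    method <- "greedy"
  }
  if (method == "greedy") {
    perm <- integer(N)
    s <- sim
    for (step in seq_len(N)) {
      idx <- arrayInd(which.max(s), dim(s))
      perm[idx[1]] <- idx[2]
      s[idx[1], ] <- -Inf
      s[, idx[2]] <- -Inf
    }
    return(perm)
  }
  best <- NULL; best_val <- -Inf
  perms <- permutations_all(N)
  for (k in seq_len(nrow(perms))) {
    p <- perms[k, ]
    val <- sum(sim[cbind(seq_len(N), p)])
    if (val > best_val) { best_val <- val; best <- p }
  }
  best
}

# all permutations of 1..n as a matrix (n! rows)
permutations_all <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_all(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[r, ] <- c(k, rest[sub[i, ]])
      r <- r + 1L
    }
  }
  out
}

#' Match two motor-module sets and report pair similarities
#'
#' Finds the one-to-one pairing of modules in `B` to modules in `A` that
#' maximizes the total normalized scalar product, and reports the matched
#' similarities in A's module order. Pairs with similarity above 0.80 are
#' flagged as "similar".
#'
#' @param A,B [synergy_nmf()] fits (or lists with `weightings` /
#'   `activations`) with equal module counts.
#' @param on compare `"weightings"` (columns of S; requires equal M) or
#'   `"activations"` (rows of P; requires equal K).
#' @param method `"assignment"` (optimal, default) or `"greedy"`.
#' @param threshold similarity level above which a pair counts as similar.
#' @return a `similarity_report`: `pair_similarities`, `matching` (index of
#'   the B module matched to each A module), `similar` flags, summary
#'   quartiles, and the full similarity matrix.
#' @export
match_modules <- function(A, B, on = c("weightings", "activations"),
                          method = c("assignment", "greedy"),
                          threshold = 0.80) {
  on <- match.arg(on)
  a <- if (on == "weightings") A$weightings else A$activations
  b <- if (on == "weightings") B$weightings else B$activations
  na <- if (on == "weightings") ncol(a) else nrow(a)
  nb <- if (on == "weightings") ncol(b) else nrow(b)
  if (na != nb) stop("module sets must have equal dimensionality")
  sim <- similarity_matrix(a, b, on)
  perm <- solve_assignment(sim, method)
  pair <- sim[cbind(seq_len(na), perm)]
  structure(list(pair_similarities = pair, matching = perm,
                 similar = pair > threshold, threshold = threshold,
                 on = on,
                 summary = c(median = median(pair),
                             p25 = unname(quantile(pair, 0.25)),
                             p75 = unname(quantile(pair, 0.75))),
                 similarity_matrix = sim),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf("Module similarity (%s): median %.3f [%.3f, %.3f]\n",
              x$on, x$summary["median"], x$summary["p25"], x$summary["p75"]))
  cat("  matched pairs: ",
      paste(sprintf("%d-%d (%.2f%s)", seq_along(x$matching), x$matching,
                    x$pair_similarities, ifelse(x$similar, "*", "")),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  * similar at r > %.2f\n", x$threshold))
  invisible(x)
}

#' Pooled pairwise similarity across a group of module sets
#'
#' Matches every pair of sets with [match_modules()] and pools the matched
#' similarities per module index of the first set of each pair, summarizing
#' by median and quartiles (the descriptive statistics used for inter-subject
#' comparisons).
#'
#' @param sets list of two or more [synergy_nmf()] fits with equal N.
#' @param on `"weightings"` or `"activations"`.
#' @param ... passed to [match_modules()].
#' @return list with `per_module` (matrix: modules x median/p25/p75),
#'   `pooled` (all matched similarities) and `pairs` (the reports).
#' @export
group_similarity <- function(sets, on = c("weightings", "activations"), ...) {
  on <- match.arg(on)
  if (length(sets) < 2) stop("need at least two module sets")
  N <- as.integer(sets[[1]]$n_modules)
  if (any(vapply(sets, function(s) as.integer(s$n_modules), 1L) != N))
    stop("all sets must have equal dimensionality")
  reports <- list()
  per_mod <- vector("list", N)
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    if (j <= i) next
    r <- match_modules(sets[[i]], sets[[j]], on = on, ...)
    reports[[length(reports) + 1]] <- r
    for (n in seq_len(N))
      per_mod[[n]] <- c(per_mod[[n]], r$pair_similarities[n])
  }
  per_module <- t(vapply(per_mod, function(v)
    c(median = median(v), p25 = unname(quantile(v, 0.25)),
      p75 = unname(quantile(v, 0.75))), numeric(3)))
  rownames(per_module) <- paste0("M", seq_len(N))
  list(per_module = per_module, pooled = unlist(per_mod), pairs = reports)
}

#' Peak timing of activation signals as percent of cycle
#'
#' The time instant of each activation signal's maximum, expressed as
#' `100 * (index - 1) / (K - 1)` percent of the cycle. Constant rows are
#' reported at their earliest index and flagged via attribute `tied`.
#'
#' @param P N x K activation matrix (or a [synergy_nmf()] fit).
#' @return numeric vector of N percentages (attribute `tied` marks constant
#'   rows).
#' @export
peak_timing <- function(P) {
  if (inherits(P, "synergy_nmf")) P <- P$activations
  P <- as.matrix(P)
  K <- ncol(P)
  if (K < 2) stop("need at least 2 time points")
  idx <- apply(P, 1, which.max)
  tied <- apply(P, 1, function(r) all(r == r[1]))
  out <- 100 * (idx - 1) / (K - 1)
  names(out) <- rownames(P)
  attr(out, "tied") <- tied
  out
}
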