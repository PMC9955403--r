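#' Construct a weight vector object
#'
#' Common return type of the three feature-weighting filters. `ranking` is
#' always a full permutation of the feature indices; downstream the wrapper
#' consumes the ranking, not any thresholded subset.
#'
#' @param method one of `"FTEST"`, `"RNCA"`, `"MRMR"`.
#' @param weights nonnegative, finite per-feature scores.
#' @param ranking feature indices in decreasing order of importance.
#' @param meta method-specific diagnostics.
#' @return object of class `weight_vector`.
#' @export
weight_vector <- function(method, weights, ranking, meta = list()) {
  stopifnot(length(weights) == length(ranking),
            all(sort(ranking) == seq_along(weights)),
            all(is.finite(weights)), all(weights >= 0))
  structure(list(method = method, weights = weights, ranking = ranking,
                 meta = meta), class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf("<weight_vector> method=%s p=%d\n", x$method, length(x$weights)))
  cat("top ranking:", head(x$ranking, 10), "\n")
  invisible(x)
}

# Group a continuous response for one-way ANOVA. "integer": groups are
# responses rounded to the nearest integer (instances with the same response
# value), with undersized groups merged into the nearest group by value.
# "quantile": equal-frequency bins.
response_groups <- function(y, binning = c("integer", "quantile"),
                            n_bins = 10, min_size = 2) {
  binning <- match.arg(binning)
  if (binning == "integer") {
    g <- round(y)
  } else {
    br <- unique(quantile(y, probs = seq(0, 1, length.out = n_bins + 1)))
    g <- as.numeric(cut(y, breaks = br, include.lowest = TRUE))
  }
  repeat {
    tab <- table(g)
    small <- names(tab)[tab < min_size]
    if (!length(small) || length(tab) <= 2) break
    v <- as.numeric(small[1])
    others <- as.numeric(names(tab)[names(tab) != small[1]])
    g[g == v] <- others[which.min(abs(others - v))]
  }
  as.integer(factor(g))
}

#' F-test (one-way ANOVA) feature weights
#'
#' For each feature, groups observations by response value and computes the
#' ANOVA F-score `FS = [S_B/(m-1)] / [S_W/(n-m)]`, the ratio of
#' between-group to within-group mean squared deviation. The reported weight
#' is `-log10(p)` under the `F(m-1, n-m)` reference distribution; features
#' with `p < 0.05` are flagged significant.
#'
#' @param X n x p numeric matrix (or data.frame) of features.
#' @param y numeric response (mmHg).
#' @param binning grouping rule for the continuous response: `"integer"`
#'   (default; nearest-mmHg groups, undersized groups merged into the nearest)
#'   or `"quantile"`.
#' @param n_bins bins for `binning = "quantile"`.
#' @return a [weight_vector()] with meta fields `F` (scores), `p`
#'   (p-values), `significant`, and `groups`.
#' @export
ftest_weights <- function(X, y, binning = "integer", n_bins = 10) {
  X <- as.matrix(X)
  g <- response_groups(y, binning, n_bins)
  m <- length(unique(g)); n <- nrow(X)
  if (m < 2) stop_cghofd("fewer than 2 response groups", "invalid_input")
  Fs <- ps <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    gm <- tapply(x, g, mean)
    nk <- tabulate(g)
    xbar <- mean(x)
    ssb <- sum(nk * (gm - xbar)^2)
    ssw <- sum((x - gm[g])^2)
    if (ssb <= 0 && ssw <= 0) { Fs[j] <- 0; ps[j] <- 1; next }
    if (ssw <= 0) { Fs[j] <- Inf; ps[j] <- 0; next }
    Fs[j] <- (ssb / (m - 1)) / (ssw / (n - m))
    ps[j] <- pf(Fs[j], m - 1, n - m, lower.tail = FALSE)
  }
  w <- -log10(pmax(ps, 1e-300))
  weight_vector("FTEST", w, order(w, decreasing = TRUE),
                meta = list(F = Fs, p = ps, significant = ps < 0.05,
                            groups = g))
}

# Equal-frequency discretization used by the plug-in MI estimator. Variables
# with at most `bins` distinct values are treated as already discrete.
discretize_ef <- function(x, bins = 10) {
  ux <- unique(x)
  if (length(ux) <= bins) return(as.integer(factor(x)))
  br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

#' Plug-in mutual information between two columns
#'
#' Both columns are discretized by equal-frequency binning (columns with few
#' distinct values are used as-is) and MI is computed in nats from the joint
#' contingency table. Symmetric and nonnegative.
#'
#' @param a,b numeric or discrete vectors of equal length.
#' @param bins bins per continuous variable (default 10).
#' @return mutual information in nats.
#' @export
mutual_information <- function(a, b, bins = 10) {
  if (length(a) != length(b)) stop_cghofd("length mismatch", "invalid_input")
  if (length(a) < 2) stop_cghofd("need at least 2 observations", "invalid_input")
  da <- discretize_ef(a, bins); db <- discretize_ef(b, bins)
  tab <- table(da, db)
  p <- tab / sum(tab)
  pr <- rowSums(p); pc <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(pr, pc)[nz]))
}

#' Minimum-redundancy maximum-relevance feature ranking
#'
#' Greedy forward ranking by the mutual-information quotient. The first pick
#' is the most relevant feature (largest `I(x, y)`); next, any remaining
#' feature with nonzero relevance and zero redundancy against the selected set
#' is added (most relevant first); then features are added greedily by
#' `MIQ = I(x, y) / mean_z I(x, z)` over the selected set `S`; features with
#' zero relevance are appended last in random order under `seed`.
#'
#' @param X n x p matrix or data.frame.
#' @param y response.
#' @param bins MI discretization bins.
#' @param seed seed for the random order of zero-relevance leftovers.
#' @param zero_tol tolerance below which an MI estimate counts as zero.
#' @return a [weight_vector()]; `ranking` is the selection order and `weights`
#'   the per-step scores (MIQ; plain relevance for picks made before any
#'   redundancy exists). Meta records the per-step trace.
#' @export
mrmr_rank <- function(X, y, bins = 10, seed = 1L, zero_tol = 1e-12) {
  X <- as.matrix(X)
  p <- ncol(X)
  rel <- vapply(seq_len(p), function(j) mutual_information(X[, j], y, bins),
                numeric(1))
  mi_cache <- matrix(NA_real_, p, p)
  pair_mi <- function(i, j) {
    if (is.na(mi_cache[i, j])) {
      v <- mutual_information(X[, i], X[, j], bins)
      mi_cache[i, j] <<- v; mi_cache[j, i] <<- v
    }
    mi_cache[i, j]
  }
  S <- integer(0); scores <- numeric(0); step_kind <- character(0)
  Sc <- seq_len(p)
  add <- function(x, score, kind) {
    S <<- c(S, x); Sc <<- setdiff(Sc, x)
    scores <<- c(scores, score); step_kind <<- c(step_kind, kind)
  }
  first <- Sc[which.max(rel[Sc])]
  add(first, rel[first], "relevance")
  # zero-redundancy relevant features
  repeat {
    if (!length(Sc)) break
    red <- vapply(Sc, function(x) mean(vapply(S, function(z) pair_mi(x, z),
                                              numeric(1))), numeric(1))
    zr <- Sc[red <= zero_tol & rel[Sc] > zero_tol]
    if (!length(zr)) break
    x <- zr[which.max(rel[zr])]
    add(x, rel[x], "zero_redundancy")
  }
  # greedy MIQ over the relevant remainder
  repeat {
    cand <- Sc[rel[Sc] > zero_tol]
    if (!length(cand)) break
    red <- vapply(cand, function(x) mean(vapply(S, function(z) pair_mi(x, z),
                                                numeric(1))), numeric(1))
    miq <- rel[cand] / pmax(red, zero_tol)
    x <- cand[which.max(miq)]
    add(x, max(miq), "miq")
  }
  if (length(Sc)) {
    set.seed(derive_seed(seed, "mrmr_leftovers"))
    left <- if (length(Sc) > 1) sample(Sc) else Sc
    for (x in left) add(x, 0, "zero_relevance")
  }
  w <- numeric(p)
  w[S] <- scores
  weight_vector("MRMR", weights = pmax(w, 0), ranking = S,
                meta = list(selection_order = S, step_scores = scores,
                            step_kind = step_kind, relevance = rel,
                            seed = seed))
}
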