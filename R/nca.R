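#' NCA regression objective and gradient
#'
#' Evaluates the leave-one-out soft-neighbor regression loss with L2 weight
#' regularization. The weighted distance is `sum_m w_m^2 |x_im - x_jm|`, the
#' kernel `exp(-z / sigma)`, reference probabilities are row-normalized over
#' all other points, and the per-point loss is the probability-weighted mean
#' of pairwise losses. The analytic gradient is returned alongside.
#'
#' @param X n x p numeric matrix (already standardized by the caller if
#'   desired; [nca_fit()] standardizes internally).
#' @param y numeric response.
#' @param w feature weight vector (length p).
#' @param sigma kernel width (default 1).
#' @param lambda L2 regularization strength.
#' @param loss `"mad"` for `|y_i - y_j|`, `"robust"` for the bounded loss
#'   `1 - exp(-|y_i - y_j|)`.
#' @param want_gamma also return the n x n reference-probability matrix.
#' @return list with `value`, `gradient`, `Li` (per-point losses) and
#'   optionally `gamma`.
#' @export
nca_objective <- function(X, y, w, sigma = 1, lambda = 0,
                          loss = c("mad", "robust"), want_gamma = FALSE) {
  loss <- match.arg(loss)
  X <- as.matrix(X)
  if (sigma <= 0) stop_cghofd("sigma must be > 0", "invalid_config")
  nca_objective_cpp(X, as.numeric(y), as.numeric(w), sigma, lambda,
                    if (loss == "mad") 0L else 1L, want_gamma)
}

#' The bounded robust pairwise loss
#'
#' `zeta(y_i, y_j) = 1 - exp(-|y_i - y_j|)`: zero at equality, saturating at
#' one for large discrepancies, which caps the influence of outlying response
#' pairs on the NCA weights.
#'
#' @param yi,yj numeric (vectorized).
#' @return numeric in `[0, 1)`.
#' @export
robust_loss <- function(yi, yj) 1 - exp(-abs(yi - yj))

#' Fit NCA regression feature weights
#'
#' Minimizes the NCA objective by gradient descent with Armijo backtracking
#' line search (accepted iterates are non-increasing by construction), from an
#' all-ones start, after per-feature standardization of `X` with the kernel
#' width fixed at 1. Deterministic for fixed inputs.
#'
#' @inheritParams nca_objective
#' @param lambda regularization parameter; the conventional default is 0.015.
#' @param max_iter iteration cap; on hitting it the best iterate is returned
#'   with `converged = FALSE` and a warning.
#' @param tol stop when the objective decreases by less than `tol` (default
#'   1e-6) or the gradient sup-norm falls below `tol`.
#' @return object of class `nca_state`: `w` (fitted weights, reported as
#'   `abs(w)` since the objective depends on `w^2`), `sigma`, `lambda`,
#'   `loss`, `objective`, `trace` (objective at accepted iterates),
#'   `converged`, and the standardization `center`/`scale`.
#' @export
nca_fit <- function(X, y, lambda = 0.015, loss = c("mad", "robust"),
                    sigma = 1, max_iter = 300, tol = 1e-6) {
  loss <- match.arg(loss)
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop_cghofd("non-finite inputs", "invalid_input")
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  lk <- if (loss == "mad") 0L else 1L
  w <- rep(1, ncol(Xs))
  ob <- nca_objective_cpp(Xs, y, w, sigma, lambda, lk)
  f <- ob$value; g <- ob$gradient
  trace <- f
  step <- 1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    accepted <- FALSE
    for (bt in 1:30) {
      w_new <- w - step * g
      ob_new <- nca_objective_cpp(Xs, y, w_new, sigma, lambda, lk)
      if (is.finite(ob_new$value) &&
          ob_new$value <= f - 1e-4 * step * sum(g^2)) {
        accepted <- TRUE; break
      }
      step <- step / 2
    }
    if (!accepted) { converged <- TRUE; break }  # no descent direction left
    if (f - ob_new$value < tol) {
      w <- w_new; f <- ob_new$value; g <- ob_new$gradient
      trace <- c(trace, f); converged <- TRUE; break
    }
    w <- w_new; f <- ob_new$value; g <- ob_new$gradient
    trace <- c(trace, f)
    step <- step * 1.25
  }
  if (!converged)
    warning("nca_fit: iteration cap reached; returning best iterate")
  structure(list(w = abs(w), sigma = sigma, lambda = lambda, loss = loss,
                 objective = f, trace = trace, converged = converged,
                 center = ctr, scale = scl),
            class = "nca_state")
}

# Soft-neighbor prediction of new responses from a fitted nca_state.
nca_predict <- function(state, Xtr, ytr, Xnew) {
  std <- function(M) sweep(sweep(as.matrix(M), 2, state$center), 2,
                           state$scale, "/")
  nca_predict_cpp(std(Xtr), as.numeric(ytr), std(Xnew), state$w, state$sigma)
}

#' Select features whose weight meets a fixed threshold
#'
#' The classical (and criticized) hard-threshold rule for NCA weights; kept as
#' a reporting output. The wrapper stage never uses it — it consumes the full
#' ranking instead.
#'
#' @param weights numeric weights.
#' @param threshold cutoff (default 3).
#' @return integer indices with `weights >= threshold`.
#' @export
select_by_threshold <- function(weights, threshold = 3) {
  which(weights >= threshold)
}

#' Robust NCA with cross-validated regularization
#'
#' Tunes the regularization parameter over a grid by k-fold cross-validation
#' of the robust-loss NCA fit: for each lambda and fold, weights are fitted on
#' the training part and the held-out loss is the mean robust loss between the
#' held-out responses and their soft-neighbor predictions. The best lambda
#' minimizes the mean CV loss; a final fit on all data at that lambda yields
#' the weights.
#'
#' @param X n x p matrix or data.frame.
#' @param y response.
#' @param lambda_grid candidate values; default 20 points linearly spaced in
#'   `[0, 2 * sd(y) / n]`.
#' @param k folds (default 5).
#' @param threshold reporting threshold on weights (default 3).
#' @param seed seed for the fold partition.
#' @param max_iter per-fit iteration cap.
#' @return a [weight_vector()] with meta: `lambda_grid`, `cv_loss`,
#'   `lambda_b`, `selected` (thresholded indices), `state` (the final
#'   `nca_state`), `threshold`, `seed`.
#' @export
rnca_tune <- function(X, y, lambda_grid = NULL, k = 5, threshold = 3,
                      seed = 1L, max_iter = 150) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < k) stop_cghofd("need n >= k folds", "invalid_input")
  if (is.null(lambda_grid))
    lambda_grid <- seq(0, 2 * sd(y) / n, length.out = 20)
  if (!length(lambda_grid)) stop_cghofd("empty lambda grid", "invalid_input")
  set.seed(derive_seed(seed, "rnca_folds"))
  fold <- sample(rep(seq_len(k), length.out = n))
  cv_loss <- vapply(lambda_grid, function(lam) {
    mean(vapply(seq_len(k), function(f) {
      tr <- fold != f
      # cap-limited iterates are fine for CV scoring; silence the cap warning
      st <- suppressWarnings(
        nca_fit(X[tr, , drop = FALSE], y[tr], lambda = lam,
                loss = "robust", max_iter = max_iter))
      pred <- nca_predict(st, X[tr, , drop = FALSE], y[tr],
                          X[!tr, , drop = FALSE])
      mean(robust_loss(y[!tr], pred))
    }, numeric(1)))
  }, numeric(1))
  lambda_b <- lambda_grid[which.min(cv_loss)]
  final <- suppressWarnings(
    nca_fit(X, y, lambda = lambda_b, loss = "robust", max_iter = max_iter))
  w <- final$w
  weight_vector("RNCA", w, order(w, decreasing = TRUE),
                meta = list(lambda_grid = lambda_grid, cv_loss = cv_loss,
                            lambda_b = lambda_b,
                            selected = select_by_threshold(w, threshold),
                            threshold = threshold, seed = seed, state = final))
}
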