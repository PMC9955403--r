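#' HOFD configuration
#'
#' Settings for the hybrid-optimal-feature-decision wrapper: which weighting
#' filter supplies the ranking, how far down the ranked list to start, and the
#' cross-validation protocol used to score each candidate prefix.
#'
#' @param hybrid_mode 0 = robust NCA, 1 = F-test, 2 = MRMR.
#' @param start_size largest candidate subset size (default 25; clipped to p).
#' @param min_size smallest evaluated size (default 2).
#' @param cv_folds folds for the RMSE criterion (default 5).
#' @param seed integer; drives the fold partition, any weighting randomness,
#'   and GP restarts.
#' @param target response name used by [run_pipeline()] (`"SBP"` or `"DBP"`).
#' @param gp_opts options passed to [gp_fit()] inside the CV loop; the
#'   defaults (`restarts = 1`, `maxit = 40`) trade a little likelihood polish
#'   for wrapper speed, which subset comparison tolerates well.
#' @param weight_args extra arguments for the weighting filter (e.g.
#'   `lambda_grid` for RNCA, `bins` for MRMR).
#' @return object of class `hofd_config`.
#' @export
hofd_config <- function(hybrid_mode = 0, start_size = 25, min_size = 2,
                        cv_folds = 5, seed = 1L, target = "SBP",
                        gp_opts = list(restarts = 1, maxit = 40),
                        weight_args = list()) {
  if (!hybrid_mode %in% 0:2)
    stop_cghofd("hybrid_mode must be 0 (RNCA), 1 (F-test) or 2 (MRMR)",
                "invalid_config")
  if (!target %in% c("SBP", "DBP"))
    stop_cghofd("target must be SBP or DBP", "invalid_config")
  if (min_size < 1 || min_size >= start_size)
    stop_cghofd("need 1 <= min_size < start_size", "invalid_config")
  structure(list(hybrid_mode = hybrid_mode, start_size = start_size,
                 min_size = min_size, cv_folds = cv_folds,
                 seed = as.integer(seed), target = target,
                 gp_opts = gp_opts, weight_args = weight_args),
            class = "hofd_config")
}

#' Mean cross-validated GP RMSE of a feature subset
#'
#' Partitions the rows into k folds under `seed`, fits a GP on each training
#' part, predicts the held-out part, and returns the mean of the per-fold
#' RMSEs. The partition depends only on `(n, folds, seed)`, so all candidate
#' subsets within one wrapper run are scored on identical folds.
#'
#' @param X n x q matrix of the candidate subset's columns.
#' @param y response.
#' @param folds number of folds (2 <= folds <= n).
#' @param seed partition seed.
#' @param gp_opts options for [gp_fit()].
#' @return mean CV RMSE (scalar), with per-fold RMSEs as attribute `"folds"`.
#' @export
hofd_cv_rmse <- function(X, y, folds = 5, seed = 1L,
                         gp_opts = list(restarts = 1, maxit = 40)) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (folds < 2 || folds > n)
    stop_cghofd("need 2 <= folds <= n", "invalid_input")
  set.seed(derive_seed(seed, "hofd_folds"))
  fold <- sample(rep(seq_len(folds), length.out = n))
  rmse <- vapply(seq_len(folds), function(f) {
    tr <- fold != f
    model <- tryCatch(
      gp_fit(X[tr, , drop = FALSE], y[tr], opts = gp_opts),
      cghofd_error = function(e)
        stop_cghofd(sprintf("GP fit failed in fold %d: %s", f,
                            conditionMessage(e)), "fold_fit_failed"))
    pred <- gp_predict(model, X[!tr, , drop = FALSE])
    sqrt(mean((pred - y[!tr])^2))
  }, numeric(1))
  structure(mean(rmse), folds = rmse)
}

# Dispatch the configured weighting filter.
hofd_weights <- function(X, y, cfg) {
  args <- cfg$weight_args
  switch(as.character(cfg$hybrid_mode),
         "0" = do.call(rnca_tune, c(list(X = X, y = y, seed = cfg$seed), args)),
         "1" = do.call(ftest_weights, c(list(X = X, y = y), args)),
         "2" = do.call(mrmr_rank, c(list(X = X, y = y, seed = cfg$seed), args)))
}

#' Hybrid optimal feature decision
#'
#' The wrapper at the heart of the method: obtain a full feature ranking from
#' the configured filter, then for every prefix size from `start_size` down to
#' `min_size` score the top-ranked prefix by mean cross-validated GP RMSE
#' (identical fold partition for every size), and decide the subset whose
#' recorded RMSE is minimal, breaking ties toward fewer features.
#'
#' @param X n x p matrix or data.frame of features.
#' @param y response vector.
#' @param cfg a [hofd_config()].
#' @param weights optionally a precomputed [weight_vector()] (skips the
#'   filter stage).
#' @return object of class `hofd_result`: `rmse_curve` (data.frame
#'   `subset_size`, `cv_rmse`), `best_size`, `selected_indices`,
#'   `selected_names`, `weights_used`, `seed`.
#' @export
hofd_select <- function(X, y, cfg = hofd_config(), weights = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 2) stop_cghofd("need at least 2 features", "invalid_input")
  wv <- weights %||% hofd_weights(X, y, cfg)
  ranking <- wv$ranking
  start <- min(cfg$start_size, p)
  sizes <- seq(start, max(cfg$min_size, 1))
  rmse <- vapply(sizes, function(num) {
    as.numeric(hofd_cv_rmse(X[, ranking[seq_len(num)], drop = FALSE], y,
                            folds = cfg$cv_folds, seed = cfg$seed,
                            gp_opts = cfg$gp_opts))
  }, numeric(1))
  curve <- data.frame(subset_size = sizes, cv_rmse = rmse)
  minima <- which(rmse == min(rmse))
  best_size <- min(sizes[minima])  # ties -> fewer features
  sel <- ranking[seq_len(best_size)]
  structure(list(rmse_curve = curve, best_size = best_size,
                 selected_indices = sel,
                 selected_names = colnames(X)[sel] %||% as.character(sel),
                 weights_used = wv, seed = cfg$seed),
            class = "hofd_result")
}

#' @export
print.hofd_result <- function(x, ...) {
  cat(sprintf("<hofd_result> best_size=%d cv_rmse=%.4g\n", x$best_size,
              min(x$rmse_curve$cv_rmse)))
  cat("selected:", paste(x$selected_names, collapse = ", "), "\n")
  invisible(x)
}

#' Run the full estimation pipeline on a feature table
#'
#' Splits the rows 80/20 into training and test under the seed, runs the
#' wrapper on the training split, refits the GP on the training rows of the
#' decided subset, predicts the held-out rows, and evaluates. With
#' `repeats > 1` the split/decide/fit/evaluate cycle is repeated with derived
#' seeds and the evaluation metrics are averaged (30 repeats reproduces the
#' full protocol shape; 1 is the desk-run default).
#'
#' @param features data.frame (or path to CSV/TSV) with feature columns and
#'   the target column, or the 25 canonical features plus `SBP`/`DBP`.
#' @param cfg a [hofd_config()]; `cfg$target` picks the response column.
#' @param repeats number of independent repetitions (default 1).
#' @param train_frac training fraction (default 0.8).
#' @param final_gp_opts options for the final refit (default
#'   `restarts = 3, maxit = 100`).
#' @return list with `hofd` (last repeat's `hofd_result`), `model` (last final
#'   GP), `eval` (averaged `eval_report` across repeats), `per_repeat`
#'   (list of reports), `selected_names_per_repeat`.
#' @export
run_pipeline <- function(features, cfg = hofd_config(), repeats = 1,
                         train_frac = 0.8,
                         final_gp_opts = list(restarts = 3, maxit = 100)) {
  if (is.character(features)) features <- read_feature_table(features)
  stopifnot(cfg$target %in% names(features))
  drop_cols <- intersect(c("SBP", "DBP", "subject_id", "segment_index"),
                         names(features))
  Xall <- as.matrix(features[, setdiff(names(features), drop_cols), drop = FALSE])
  yall <- features[[cfg$target]]
  n <- nrow(Xall)
  reports <- list(); sel_names <- list(); hofd_res <- NULL; model <- NULL
  for (r in seq_len(repeats)) {
    rseed <- derive_seed(cfg$seed, paste0("repeat", r))
    set.seed(rseed)
    tr_idx <- sort(sample(n, floor(train_frac * n)))
    te_idx <- setdiff(seq_len(n), tr_idx)
    if (length(tr_idx) < cfg$cv_folds || length(te_idx) < 2)
      stop_cghofd("split leaves too few rows", "invalid_input")
    rcfg <- cfg; rcfg$seed <- rseed
    hofd_res <- hofd_select(Xall[tr_idx, , drop = FALSE], yall[tr_idx], rcfg)
    sel <- hofd_res$selected_indices
    model <- gp_fit(Xall[tr_idx, sel, drop = FALSE], yall[tr_idx],
                    opts = c(final_gp_opts, list(seed = rseed)))
    pred <- gp_predict(model, Xall[te_idx, sel, drop = FALSE])
    reports[[r]] <- eval_report(pred, yall[te_idx])
    sel_names[[r]] <- hofd_res$selected_names
  }
  list(hofd = hofd_res, model = model,
       eval = average_reports(reports), per_repeat = reports,
       selected_names_per_repeat = sel_names)
}

# Average the numeric fields of several eval_reports (protocol averaging).
average_reports <- function(reports) {
  if (length(reports) == 1) return(reports[[1]])
  avg <- reports[[1]]
  num_fields <- c("ME", "SDE", "MAE", "SDE_of_MAE", "RMSE", "R2")
  for (f in num_fields)
    avg[[f]] <- mean(vapply(reports, function(r) r[[f]], numeric(1)))
  avg$bhs_cum <- rowMeans(vapply(reports, function(r) r$bhs_cum, numeric(3)))
  avg$bhs_grade <- bhs_grade(avg$bhs_cum[1], avg$bhs_cum[2], avg$bhs_cum[3])
  avg$aami_pass <- abs(avg$ME) < 5 && avg$SDE < 8
  avg$bland_altman <- c(bias = avg$ME, lower = avg$ME - 1.96 * avg$SDE,
                        upper = avg$ME + 1.96 * avg$SDE)
  avg$n_repeats <- length(reports)
  avg
}
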