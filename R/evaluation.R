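#' Accuracy report for predicted vs reference blood pressures
#'
#' Computes the device-protocol metrics from paired (predicted, reference)
#' pressures: mean error (ME) and its sample standard deviation (SDE), mean
#' absolute error (MAE) and its SD, RMSE, the coefficient of determination
#' R-squared, the AAMI pass flag (`|ME| < 5` mmHg and `SDE < 8` mmHg, strict
#' inequalities), cumulative percentages of absolute error within 5/10/15 mmHg
#' with the corresponding BHS grade, and Bland-Altman statistics
#' (bias and limits of agreement `ME +/- 1.96 SDE`).
#'
#' @param pred predicted pressures (mmHg).
#' @param ref reference pressures (mmHg).
#' @return object of class `eval_report`.
#' @export
eval_report <- function(pred, ref) {
  if (length(pred) != length(ref))
    stop_cghofd("pred and ref must have equal length", "invalid_input")
  n <- length(pred)
  if (n < 2) stop_cghofd("need n >= 2", "invalid_input")
  e <- pred - ref
  ME <- mean(e)
  SDE <- sd(e)
  MAE <- mean(abs(e))
  SDE_of_MAE <- sd(abs(e))
  RMSE <- sqrt(mean(e^2))
  R2 <- 1 - sum(e^2) / sum((ref - mean(ref))^2)
  bhs_cum <- c(p5 = 100 * mean(abs(e) <= 5), p10 = 100 * mean(abs(e) <= 10),
               p15 = 100 * mean(abs(e) <= 15))
  structure(list(n = n, ME = ME, SDE = SDE, MAE = MAE,
                 SDE_of_MAE = SDE_of_MAE, RMSE = RMSE, R2 = R2,
                 bhs_cum = bhs_cum,
                 bhs_grade = bhs_grade(bhs_cum[1], bhs_cum[2], bhs_cum[3]),
                 aami_pass = abs(ME) < 5 && SDE < 8,
                 bland_altman = c(bias = ME, lower = ME - 1.96 * SDE,
                                  upper = ME + 1.96 * SDE)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n=%d\n", x$n))
  cat(sprintf("  ME %.2f  SDE %.2f  MAE %.2f  RMSE %.2f  R2 %.3f\n",
              x$ME, x$SDE, x$MAE, x$RMSE, x$R2))
  cat(sprintf("  BHS %.1f/%.1f/%.1f%% -> grade %s;  AAMI %s\n",
              x$bhs_cum[1], x$bhs_cum[2], x$bhs_cum[3], x$bhs_grade,
              if (x$aami_pass) "pass" else "fail"))
  invisible(x)
}

#' BHS grade from cumulative error percentages
#'
#' Grade A requires at least 60/85/95% of absolute errors within 5/10/15
#' mmHg, grade B 50/75/90, grade C 40/65/85; all three thresholds must hold
#' simultaneously, otherwise the grade is `"fail"`.
#'
#' @param cum5,cum10,cum15 cumulative percentages in `[0, 100]`,
#'   non-decreasing.
#' @return one of `"A"`, `"B"`, `"C"`, `"fail"`.
#' @export
bhs_grade <- function(cum5, cum10, cum15) {
  cums <- c(cum5, cum10, cum15)
  if (any(cums < 0 | cums > 100) || is.unsorted(cums))
    stop_cghofd("cumulative percentages must be non-decreasing in [0, 100]",
                "invalid_input")
  if (all(cums >= c(60, 85, 95))) "A"
  else if (all(cums >= c(50, 75, 90))) "B"
  else if (all(cums >= c(40, 65, 85))) "C"
  else "fail"
}

#' One-way ANOVA comparison of per-repeat RMSE samples
#'
#' Compares algorithms by the spread of their repeated-run RMSEs: F statistic
#' of between-group versus within-group mean squared deviation and its
#' p-value, with significance flagged at `alpha = 0.05`. Identical groups
#' yield `F = 0, p = 1`.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each >= 2
#'   values).
#' @param alpha significance level (default 0.05).
#' @return list with `F_stat`, `p_value`, `df`, `significant`, `alpha`,
#'   `group_means`.
#' @export
anova_compare <- function(groups, alpha = 0.05) {
  if (length(groups) < 2 || any(lengths(groups) < 2))
    stop_cghofd("need >= 2 groups with >= 2 values each", "invalid_input")
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  m <- length(groups); n <- length(x)
  gm <- tapply(x, g, mean); nk <- tabulate(g)
  ssb <- sum(nk * (gm - mean(x))^2)
  ssw <- sum((x - gm[g])^2)
  if (ssb <= .Machine$double.eps * sum(x^2)) {
    Fs <- 0; p <- 1
  } else if (ssw <= 0) {
    Fs <- Inf; p <- 0
  } else {
    Fs <- (ssb / (m - 1)) / (ssw / (n - m))
    p <- pf(Fs, m - 1, n - m, lower.tail = FALSE)
  }
  list(F_stat = Fs, p_value = p, df = c(m - 1, n - m),
       significant = p < alpha, alpha = alpha,
       group_means = setNames(as.numeric(gm), names(groups)))
}

#' Write an evaluation report as JSON
#'
#' @param report an `eval_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
eval_write_json <- function(report, path) {
  obj <- unclass(report)
  obj$bhs_cum <- as.list(obj$bhs_cum)
  obj$bland_altman <- as.list(obj$bland_altman)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
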