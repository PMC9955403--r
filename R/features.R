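#' Detect ECG R-peaks
#'
#' Amplitude-threshold local-maximum detector with a refractory period.
#' Candidates are local maxima above 60% of the signal range; they are
#' accepted greedily by amplitude subject to a minimum separation of 0.25 s
#' (240 bpm bound).
#'
#' @param ecg band-limited ECG series.
#' @param fs sampling rate (Hz).
#' @return strictly increasing integer vector of peak sample indices (1-based).
#' @export
detect_r_peaks <- function(ecg, fs) {
  n <- length(ecg)
  rng <- diff(range(ecg))
  if (n < 3 || !is.finite(rng) || rng < 1e-10)
    stop_cghofd("no cycles: flat or empty ECG", "no_cycles")
  thr <- min(ecg) + 0.6 * rng
  isloc <- c(FALSE, ecg[2:(n - 1)] > ecg[1:(n - 2)] &
                     ecg[2:(n - 1)] >= ecg[3:n], FALSE)
  cand <- which(isloc & ecg > thr)
  if (!length(cand)) stop_cghofd("no cycles: no peaks above threshold", "no_cycles")
  refr <- max(1L, round(0.25 * fs))
  cand <- cand[order(ecg[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in cand) {
    if (!length(keep) || all(abs(keep - i) >= refr)) keep <- c(keep, i)
  }
  sort(keep)
}

#' Detect PPG fiducial points per cardiac cycle
#'
#' For each pair of consecutive R-peaks: the systolic peak is the PPG maximum
#' in the interval, the foot is the minimum between the R-peak and the
#' systolic peak, the max-slope point is the first-derivative maximum on the
#' rise, and the falling-edge inflection is the second-derivative maximum
#' between the systolic peak and the next foot (the shoulder of the reflected
#' wave). Cycles whose landmarks cannot be resolved in the required order are
#' dropped, not fabricated.
#'
#' @param ppg PPG series (any monotone-affine scaling).
#' @param fs sampling rate.
#' @param r_peaks indices from [detect_r_peaks()].
#' @return data.frame with columns `r_peak`, `ppg_foot`, `max_slope`,
#'   `systolic_peak`, `inflection`, `next_foot` (one row per resolved cycle),
#'   plus attribute `"n_dropped"`.
#' @export
detect_ppg_fiducials <- function(ppg, fs, r_peaks) {
  if (length(r_peaks) < 2)
    stop_cghofd("need at least two R-peaks", "no_cycles")
  d1 <- central_diff(ppg, fs)
  d2 <- central_diff(d1, fs)
  n <- length(ppg)
  ncyc <- length(r_peaks) - 1L
  peaks <- feet <- integer(ncyc)
  ok <- rep(TRUE, ncyc)
  for (k in seq_len(ncyc)) {
    win <- r_peaks[k]:r_peaks[k + 1]
    pk <- win[which.max(ppg[win])]
    if (pk <= r_peaks[k] + 2 || pk >= r_peaks[k + 1] - 2) { ok[k] <- FALSE; next }
    fw <- r_peaks[k]:pk
    feet[k] <- fw[which.min(ppg[fw])]
    peaks[k] <- pk
    # the foot must lie strictly inside (r_peak, peak): a foot pinned to the
    # R-peak means there was no descent into a trough (e.g. record lead-in)
    if (!(feet[k] > r_peaks[k] && feet[k] < pk)) ok[k] <- FALSE
  }
  rows <- list(); dropped <- sum(!ok)
  for (k in seq_len(ncyc - 1L)) {
    if (!ok[k] || !ok[k + 1]) { next }
    foot <- feet[k]; pk <- peaks[k]; nf <- feet[k + 1]
    mw <- foot:pk
    ms <- mw[which.max(d1[mw])]
    iw_lo <- pk + 2L; iw_hi <- nf - 2L
    if (iw_lo >= iw_hi) { dropped <- dropped + 1L; next }
    iw <- iw_lo:iw_hi
    infl <- iw[which.max(d2[iw])]
    if (!(foot < ms && ms < pk && pk < infl && infl < nf)) {
      dropped <- dropped + 1L; next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      r_peak = r_peaks[k], ppg_foot = foot, max_slope = ms,
      systolic_peak = pk, inflection = infl, next_foot = nf)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(r_peak = integer(), ppg_foot = integer(), max_slope = integer(),
               systolic_peak = integer(), inflection = integer(),
               next_foot = integer())
  attr(out, "n_dropped") <- dropped
  out
}

# Trapezoidal area of x over sample index range [a, b], time step 1/fs.
trap_area <- function(x, a, b, fs) {
  idx <- a:b
  sum((x[idx[-length(idx)]] + x[idx[-1]]) / 2) / fs
}

#' Compute the per-cycle feature vector
#'
#' Evaluates all 25 features (plus cycle time `CT`) for one cardiac cycle from
#' its fiducials. Amplitude features use the supplied (typically per-segment
#' min-max normalized) PPG. The heart rate is the inverse R-R interval in
#' beats per second; `FHR` is the same quantity read as a frequency in Hz.
#' Divisions by zero yield `NaN` and the row is dropped at table assembly.
#'
#' The viscosity feature `MEU` has no closed-form definition in the cuffless
#' BP literature accessible here; the default surrogate is `ps/pm` (pulse max
#' over pulse mean), and a different function can be plugged in or the feature
#' excluded.
#'
#' @param fid one row of fiducials (list/data.frame row with the six indices).
#' @param ppg,ecg segment series (ECG only used via `fid$r_peak`).
#' @param fs sampling rate.
#' @param rr R-R interval in seconds for this cycle.
#' @param meu_fun surrogate for the blood-viscosity feature; a
#'   `function(ps, pd, pm)` (default `ps/pm`) or `NULL` for `NA`.
#' @return named numeric vector with the 25 canonical features plus `CT`.
#' @export
compute_features <- function(fid, ppg, ecg, fs, rr, meu_fun = function(ps, pd, pm) ps / pm) {
  foot <- fid$ppg_foot; ms <- fid$max_slope; pk <- fid$systolic_peak
  infl <- fid$inflection; nf <- fid$next_foot; rp <- fid$r_peak
  ST <- (pk - foot) / fs
  DT <- (nf - pk) / fs
  CT <- ST + DT
  PIR <- ppg[pk] / ppg[foot]
  HR <- 1 / rr
  FHR <- HR
  PAT1 <- (pk - rp) / fs
  PAT2 <- (ms - rp) / fs
  PAT3 <- (nf - rp) / fs
  LASI <- 1 / ((infl - pk) / fs)
  AI <- ppg[pk] / ppg[infl]
  S1 <- trap_area(ppg, foot, ms, fs)
  S2 <- trap_area(ppg, ms, pk, fs)
  S3 <- trap_area(ppg, pk, infl, fs)
  S4 <- trap_area(ppg, infl, nf, fs)
  IPAR <- S4 / (S1 + S2 + S3)
  pulse <- ppg[foot:nf]
  ps <- max(pulse); pd <- min(pulse)
  pm <- trap_area(ppg, foot, nf, fs) / ((nf - foot) / fs)
  PPGk <- (pm - pd) / (ps - pd)
  d1 <- central_diff(ppg, fs); d2 <- central_diff(d1, fs)
  dp <- d1[foot:nf]; ddp <- d2[foot:nf]
  dppgH <- max(dp)
  dppgW <- half_height_width(dp, fs)
  ddppgPH <- max(ddp)
  ddppgTH <- min(ddp)
  ddppgH <- ddppgPH - ddppgTH
  ddppgW <- half_height_width(ddp, fs)
  MXAP <- ps
  MIAP <- pd
  MEU <- if (is.null(meu_fun)) NA_real_ else meu_fun(ps, pd, pm)
  out <- c(ST = ST, DT = DT, PIR = PIR, HR = HR, PAT1 = PAT1, PAT3 = PAT3,
           PAT2 = PAT2, LASI = LASI, AI = AI, S1 = S1, S2 = S2, S3 = S3,
           S4 = S4, IPAR = IPAR, PPGk = PPGk, dppgH = dppgH, dppgW = dppgW,
           ddppgPH = ddppgPH, ddppgTH = ddppgTH, ddppgW = ddppgW,
           ddppgH = ddppgH, MXAP = MXAP, MIAP = MIAP, MEU = MEU, FHR = FHR,
           CT = CT)
  out[!is.finite(out)] <- NaN
  out
}

# Width (seconds) of the main peak of x at half its maximum, by linear
# interpolation of the crossings around the argmax.
half_height_width <- function(x, fs) {
  i <- which.max(x)
  h <- x[i] / 2
  l <- i
  while (l > 1 && x[l] > h) l <- l - 1
  r <- i
  n <- length(x)
  while (r < n && x[r] > h) r <- r + 1
  if (x[l] > h || x[r] > h) return(NaN)  # peak truncated at the boundary
  fl <- l + (h - x[l]) / (x[l + 1] - x[l])
  fr <- r - (h - x[r]) / (x[r - 1] - x[r])
  (fr - fl) / fs
}

#' Reference SBP/DBP from an ABP segment
#'
#' Per-segment reference systolic pressure is the mean of per-cycle ABP
#' maxima and diastolic pressure the mean of per-cycle minima, with cycles
#' delimited by consecutive PPG feet.
#'
#' @param abp ABP series in mmHg (unnormalized).
#' @param fiducials data.frame from [detect_ppg_fiducials()].
#' @return named numeric vector `c(sbp = , dbp = )`.
#' @export
reference_bp <- function(abp, fiducials) {
  if (nrow(fiducials) < 1) stop_cghofd("no cycles for reference BP", "no_cycles")
  sbp <- dbp <- numeric(nrow(fiducials))
  for (k in seq_len(nrow(fiducials))) {
    idx <- fiducials$ppg_foot[k]:fiducials$next_foot[k]
    sbp[k] <- max(abp[idx]); dbp[k] <- min(abp[idx])
  }
  c(sbp = mean(sbp), dbp = mean(dbp))
}

#' Extract the feature table from a list of segments
#'
#' Per segment: min-max normalize the PPG, detect R-peaks and PPG fiducials,
#' compute per-cycle feature vectors and aggregate them by the median over
#' cycles (robust to one bad beat), and attach reference SBP/DBP from the ABP
#' channel. Segments with no resolvable cycle, or whose aggregated row still
#' contains NaN, are dropped.
#'
#' @param segments list of `bp_segment` from [segment_and_gate()].
#' @param meu_fun viscosity surrogate passed to [compute_features()].
#' @param include_meu keep the MEU column (default TRUE).
#' @return data.frame with `subject_id`, `segment_index`, the 25 canonical
#'   feature columns, `SBP` and `DBP`.
#' @export
extract_features <- function(segments, meu_fun = function(ps, pd, pm) ps / pm,
                             include_meu = TRUE) {
  rows <- list()
  for (si in seq_along(segments)) {
    seg <- segments[[si]]
    row <- tryCatch({
      ppg_n <- normalize_minmax(seg$ppg)
      rp <- detect_r_peaks(seg$ecg, seg$fs)
      fid <- detect_ppg_fiducials(ppg_n, seg$fs, rp)
      if (nrow(fid) < 1) NULL else {
        rr_all <- diff(rp) / seg$fs
        mat <- t(vapply(seq_len(nrow(fid)), function(k) {
          rr <- rr_all[match(fid$r_peak[k], rp)]
          compute_features(fid[k, ], ppg_n, seg$ecg, seg$fs, rr, meu_fun)
        }, numeric(26)))
        feat <- apply(mat, 2, median, na.rm = TRUE)
        bp <- reference_bp(seg$abp, fid)
        c(feat, SBP = bp[["sbp"]], DBP = bp[["dbp"]])
      }
    }, cghofd_error = function(e) NULL)
    if (is.null(row) || any(!is.finite(row[canonical_feature_names()])))
      next
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = seg$parent, segment_index = si - 1L,
      as.list(row[c(canonical_feature_names(), "SBP", "DBP")]))
  }
  if (!length(rows)) stop_cghofd("no usable segments", "record_excluded")
  out <- do.call(rbind, rows)
  if (!include_meu) out$MEU <- NULL
  rownames(out) <- NULL
  out
}
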