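#' Configuration for the synthetic waveform generator
#'
#' Describes a 125 Hz ECG/PPG/ABP triplet with blood-pressure-coupled pulse
#' timing. The PPG foot lags the ECG R-peak by a delay that is linear in
#' systolic pressure via `ptt_slope` (milliseconds per mmHg, negative: higher
#' pressure, shorter transit time), which is the coupling the whole feature
#' family (PAT1-PAT3) exploits.
#'
#' @param duration_s record length in seconds.
#' @param fs sampling rate in Hz (default 125, the rate of bedside-monitor
#'   extracts this tool targets).
#' @param heart_rate_bpm heart rate, beats per minute.
#' @param sbp_mmHg,dbp_mmHg systolic/diastolic pressure of the emitted ABP
#'   channel; the noise-free ABP oscillates exactly between them.
#' @param ptt_slope ms of change in R-peak-to-PPG-foot delay per mmHg of SBP
#'   change; default -2 ms/mmHg (order-of-magnitude physiological; only the
#'   sign matters for the monotonicity tests).
#' @param noise_sd additive Gaussian noise SD per channel, in channel units.
#' @param hr_jitter_sd Gaussian jitter SD on cycle length, seconds (default 0).
#' @param seed integer RNG seed.
#' @return an object of class `synth_waveform_config`.
#' @export
synth_waveform_config <- function(duration_s = 20, fs = 125,
                                  heart_rate_bpm = 75,
                                  sbp_mmHg = 120, dbp_mmHg = 70,
                                  ptt_slope = -2, noise_sd = 0,
                                  hr_jitter_sd = 0, seed = 1L) {
  if (!is.numeric(fs) || fs <= 0) stop_cghofd("fs must be > 0", "invalid_config")
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop_cghofd("duration_s must be > 0", "invalid_config")
  if (dbp_mmHg >= sbp_mmHg)
    stop_cghofd("dbp_mmHg must be < sbp_mmHg", "invalid_config")
  if (heart_rate_bpm <= 0) stop_cghofd("heart_rate_bpm must be > 0", "invalid_config")
  structure(list(duration_s = duration_s, fs = fs,
                 heart_rate_bpm = heart_rate_bpm,
                 sbp_mmHg = sbp_mmHg, dbp_mmHg = dbp_mmHg,
                 ptt_slope = ptt_slope, noise_sd = noise_sd,
                 hr_jitter_sd = hr_jitter_sd, seed = as.integer(seed)),
            class = "synth_waveform_config")
}

# Asymmetric PPG-like pulse: sum of a systolic and a reflected/diastolic
# Gaussian bump, expressed in within-cycle time tau (seconds) for period T.
# The two-bump shape guarantees a genuine falling-edge inflection so the
# stiffness/augmentation features (LASI, AI) and sub-areas S1-S4 are defined.
ppg_pulse_shape <- function(tau, T) {
  exp(-((tau - 0.20 * T)^2) / (2 * (0.075 * T)^2)) +
    0.45 * exp(-((tau - 0.47 * T)^2) / (2 * (0.13 * T)^2))
}

abp_pulse_shape <- function(tau, T) {
  exp(-((tau - 0.25 * T)^2) / (2 * (0.09 * T)^2)) +
    0.5 * exp(-((tau - 0.52 * T)^2) / (2 * (0.14 * T)^2))
}

ecg_pulse_shape <- function(tau, T) {
  exp(-(tau^2) / (2 * 0.012^2))  # narrow QRS-like bump at tau = 0
}

# Sum pulse bumps over cycle onsets (seconds) onto a sample grid.
add_pulses <- function(n, fs, onsets, periods, shape, shift = 0) {
  x <- numeric(n)
  t <- (seq_len(n) - 1) / fs
  for (k in seq_along(onsets)) {
    T <- periods[k]
    lo <- max(1L, floor((onsets[k] + shift - 0.6 * T) * fs) + 1L)
    hi <- min(n, ceiling((onsets[k] + shift + 1.25 * T) * fs) + 1L)
    if (lo > hi) next
    idx <- lo:hi
    x[idx] <- x[idx] + shape(t[idx] - onsets[k] - shift, T)
  }
  x
}

#' Generate a BP-coupled ECG/PPG/ABP waveform triplet with ground truth
#'
#' Emits one narrow QRS-like bump per cycle on the ECG channel, an asymmetric
#' two-bump PPG pulse whose foot lags the R-peak by
#' `250 + ptt_slope * (sbp - 120)` milliseconds, and an ABP pulse rescaled to
#' oscillate exactly between `dbp_mmHg` and `sbp_mmHg`. Ground-truth fiducials
#' (R-peak, PPG foot, max-slope point, systolic peak, falling-edge inflection,
#' next foot) are read off the noise-free signals for every interior cycle.
#'
#' @param cfg a [synth_waveform_config()].
#' @return a list with `record` (a `waveform_record`: `subject_id`, `fs`,
#'   `ecg`, `ppg`, `abp`, `t0_offset_s`) and `truth` (per-cycle fiducial
#'   data.frame, per-cycle `reference_sbp`/`reference_dbp`, the noise-free
#'   channels, and the PPG delay in seconds).
#' @export
generate_waveforms <- function(cfg) {
  stopifnot(inherits(cfg, "synth_waveform_config"))
  set.seed(cfg$seed)
  fs <- cfg$fs
  n <- round(cfg$duration_s * fs)
  T0 <- 60 / cfg$heart_rate_bpm
  n_cycles <- ceiling(cfg$duration_s / T0) + 2L
  periods <- rep(T0, n_cycles) +
    if (cfg$hr_jitter_sd > 0) rnorm(n_cycles, 0, cfg$hr_jitter_sd) else 0
  periods <- pmax(periods, 0.3)
  onsets <- cumsum(c(0.02, periods[-n_cycles]))

  delay <- (250 + cfg$ptt_slope * (cfg$sbp_mmHg - 120)) / 1000
  if (delay <= 0.02) delay <- 0.02

  ecg0 <- add_pulses(n, fs, onsets, periods, ecg_pulse_shape)
  ppg0 <- add_pulses(n, fs, onsets, periods, ppg_pulse_shape, shift = delay)
  abp_raw <- add_pulses(n, fs, onsets, periods, abp_pulse_shape, shift = delay)

  # Rescale ABP to [dbp, sbp] using the range over interior cycles, so each
  # complete cycle attains the stated extremes exactly (noise-free case).
  interior <- which((seq_len(n) - 1) / fs >= onsets[2] &
                    (seq_len(n) - 1) / fs < onsets[min(n_cycles, length(onsets))])
  if (length(interior) < 2) interior <- seq_len(n)
  rng <- range(abp_raw[interior])
  abp0 <- cfg$dbp_mmHg + (cfg$sbp_mmHg - cfg$dbp_mmHg) *
    (abp_raw - rng[1]) / (rng[2] - rng[1])

  truth <- waveform_ground_truth(ecg0, ppg0, abp0, fs, onsets, periods, n)

  noisy <- function(x, scale) if (cfg$noise_sd > 0) x + rnorm(n, 0, cfg$noise_sd * scale) else x
  record <- structure(list(subject_id = sprintf("synth-%d", cfg$seed), fs = fs,
                           ecg = noisy(ecg0, 1), ppg = noisy(ppg0, 1),
                           abp = noisy(abp0, 1), t0_offset_s = 0),
                      class = "waveform_record")
  list(record = record,
       truth = c(truth, list(ecg0 = ecg0, ppg0 = ppg0, abp0 = abp0,
                             delay_s = delay)))
}

# Read per-cycle fiducials and reference SBP/DBP off noise-free channels.
# Two passes: first locate per-cycle R-peak / systolic peak / foot /
# max-slope, then pair consecutive cycles so next_foot is literally the next
# cycle's foot (keeps the emitted sequence consistent: next_foot[k] ==
# ppg_foot[k + 1]).
waveform_ground_truth <- function(ecg0, ppg0, abp0, fs, onsets, periods, n) {
  t_end <- (n - 1) / fs
  keep <- which(onsets + periods <= t_end - 0.05 & onsets > 0)
  keep <- keep[keep >= 2]  # interior cycles: previous pulse tail present
  d1 <- central_diff(ppg0, fs); d2 <- central_diff(d1, fs)
  cyc <- list()
  for (k in keep) {
    a <- floor(onsets[k] * fs) + 1L
    b <- min(n, floor((onsets[k] + periods[k]) * fs) + 1L)
    if (b - a < 8) next
    win <- a:b
    # the QRS bump sits at the cycle onset; search only the first half-period
    # so the next cycle's bump (at the right window edge) cannot win
    rw <- a:min(b, a + round(0.5 * periods[k] * fs))
    r_peak <- rw[which.max(ecg0[rw])]
    # PPG landmarks live delayed within this cycle; search up to 1.15 periods
    # past the onset — past this cycle's systolic peak (at delay + 0.2 T) but
    # short of the next one (at delay + 1.2 T)
    pw <- r_peak:min(n, a + round(1.15 * periods[k] * fs))
    peak <- pw[which.max(ppg0[pw])]
    if (peak <= r_peak + 1 || peak >= max(pw) - 2) next
    fw <- r_peak:peak
    foot <- fw[which.min(ppg0[fw])]
    if (!(foot > r_peak && foot < peak)) next
    mw <- foot:peak
    ms <- mw[which.max(d1[mw])]
    cyc[[length(cyc) + 1L]] <- list(k = k, win = win, r_peak = r_peak,
                                    foot = foot, ms = ms, peak = peak)
  }
  rows <- list(); sbp <- c(); dbp <- c()
  if (length(cyc) >= 2) for (i in seq_len(length(cyc) - 1L)) {
    cur <- cyc[[i]]; nxt <- cyc[[i + 1L]]
    if (nxt$k != cur$k + 1L) next  # non-adjacent cycles
    next_foot <- nxt$foot
    iw_lo <- cur$peak + 2L; iw_hi <- next_foot - 2L
    if (iw_lo >= iw_hi) next
    iw <- iw_lo:iw_hi
    infl <- iw[which.max(d2[iw])]
    if (!(cur$foot < cur$ms && cur$ms < cur$peak && cur$peak < infl &&
          infl < next_foot)) next
    rows[[length(rows) + 1L]] <- data.frame(
      r_peak = cur$r_peak, ppg_foot = cur$foot, max_slope = cur$ms,
      systolic_peak = cur$peak, inflection = infl, next_foot = next_foot)
    sbp <- c(sbp, max(abp0[cur$win])); dbp <- c(dbp, min(abp0[cur$win]))
  }
  fid <- if (length(rows)) do.call(rbind, rows) else
    data.frame(r_peak = integer(), ppg_foot = integer(), max_slope = integer(),
               systolic_peak = integer(), inflection = integer(),
               next_foot = integer())
  list(fiducials = fid, reference_sbp = sbp, reference_dbp = dbp)
}

central_diff <- function(x, fs) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  d[1] <- (x[2] - x[1]) * fs
  d[n] <- (x[n] - x[n - 1]) * fs
  d
}

#' Configuration for the synthetic feature-table generator
#'
#' A sparse linear world: standard-normal feature columns, a target that is a
#' linear combination over a known support plus Gaussian noise, optional
#' redundant columns that are noisy copies of support members, and the rest
#' independent of the target. Used to test the weighting filters and the
#' wrapper against known ground truth.
#'
#' @param n_segments number of rows.
#' @param n_features number of feature columns (default 25).
#' @param support indices of truly informative features.
#' @param effect_sizes linear coefficients over `support` (recycled).
#' @param n_redundant number of noisy copies of support members.
#' @param copy_noise_sd SD of the noise added to redundant copies (default 0.05).
#' @param noise_sd target noise SD, mmHg-scale (default 0.1).
#' @param seed integer RNG seed.
#' @return an object of class `synth_feature_config`.
#' @export
synth_feature_config <- function(n_segments = 200, n_features = 25,
                                 support = c(1, 2, 3), effect_sizes = 1,
                                 n_redundant = 0, copy_noise_sd = 0.05,
                                 noise_sd = 0.1, seed = 1L) {
  support <- as.integer(support)
  if (length(support) == 0) stop_cghofd("support must be non-empty", "invalid_config")
  if (!all(support >= 1 & support <= n_features))
    stop_cghofd("support must lie within 1..n_features", "invalid_config")
  if (n_redundant > n_features - length(support))
    stop_cghofd("n_redundant exceeds the non-support columns", "invalid_config")
  structure(list(n_segments = as.integer(n_segments),
                 n_features = as.integer(n_features), support = support,
                 effect_sizes = rep_len(effect_sizes, length(support)),
                 n_redundant = as.integer(n_redundant),
                 copy_noise_sd = copy_noise_sd, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_feature_config")
}

#' Generate a feature table with known sparse linear structure
#'
#' @param cfg a [synth_feature_config()].
#' @param target_name name of the target column (default `"SBP"`).
#' @return list with `table` (data.frame: feature columns then the target) and
#'   `truth` (`true_support`, `effect_sizes`, `redundant_of`: named map from
#'   redundant column index to the support column it copies).
#' @export
generate_feature_table <- function(cfg, target_name = "SBP") {
  stopifnot(inherits(cfg, "synth_feature_config"))
  set.seed(cfg$seed)
  n <- cfg$n_segments; p <- cfg$n_features
  X <- matrix(rnorm(n * p), n, p)
  y <- as.numeric(X[, cfg$support, drop = FALSE] %*% cfg$effect_sizes)
  if (cfg$noise_sd > 0) y <- y + rnorm(n, 0, cfg$noise_sd)
  non_support <- setdiff(seq_len(p), cfg$support)
  red_cols <- head(non_support, cfg$n_redundant)
  red_of <- integer(0)
  if (length(red_cols)) {
    src <- rep_len(cfg$support, length(red_cols))
    for (i in seq_along(red_cols)) {
      X[, red_cols[i]] <- X[, src[i]] +
        if (cfg$copy_noise_sd > 0) rnorm(n, 0, cfg$copy_noise_sd) else 0
    }
    red_of <- setNames(src, red_cols)
  }
  nm <- if (p == 25) canonical_feature_names() else paste0("F", seq_len(p))
  tab <- as.data.frame(X)
  names(tab) <- nm
  tab[[target_name]] <- y
  list(table = tab,
       truth = list(true_support = cfg$support,
                    effect_sizes = cfg$effect_sizes, redundant_of = red_of))
}

#' Canonical names of the 25 pulse features
#'
#' Ordered short names used throughout: timing (ST, DT), amplitude ratios
#' (PIR, AI), rates (HR, FHR), pulse arrival times (PAT1-PAT3), stiffness
#' (LASI), pulse sub-areas and ratios (S1-S4, IPAR, PPGk), first/second
#' PPG-derivative characteristics (dppg*/ddppg*), pulse amplitude extremes
#' (MXAP, MIAP) and the viscosity surrogate (MEU).
#'
#' @return character vector of length 25.
#' @export
canonical_feature_names <- function() {
  c("ST", "DT", "PIR", "HR", "PAT1", "PAT3", "PAT2", "LASI", "AI",
    "S1", "S2", "S3", "S4", "IPAR", "PPGk", "dppgH", "dppgW",
    "ddppgPH", "ddppgTH", "ddppgW", "ddppgH", "MXAP", "MIAP", "MEU", "FHR")
}
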