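#' Write a waveform record to CSV
#'
#' Columns `t`, `ecg`, `ppg`, `abp`; `t` in seconds from the record origin.
#'
#' @param record a `waveform_record`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(record, path) {
  n <- length(record$ecg)
  df <- data.frame(t = (seq_len(n) - 1) / record$fs + record$t0_offset_s,
                   ecg = record$ecg, ppg = record$ppg, abp = record$abp)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a waveform record from CSV
#'
#' Expects columns `t`, `ecg`, `ppg`, `abp`; the sampling rate is inferred
#' from the median time step unless given.
#'
#' @param path CSV path.
#' @param fs sampling rate override (Hz).
#' @param subject_id record label (default: file name).
#' @return a `waveform_record`.
#' @export
read_waveform_csv <- function(path, fs = NULL, subject_id = NULL) {
  df <- read.csv(path)
  need <- c("t", "ecg", "ppg", "abp")
  if (!all(need %in% names(df)))
    stop_cghofd("waveform CSV must have columns t, ecg, ppg, abp", "bad_input")
  if (is.null(fs)) fs <- 1 / median(diff(df$t))
  structure(list(subject_id = subject_id %||% basename(path), fs = fs,
                 ecg = df$ecg, ppg = df$ppg, abp = df$abp,
                 t0_offset_s = df$t[1]),
            class = "waveform_record")
}

#' Write a waveform record as a minimal WFDB record
#'
#' Emits a text header `<name>.hea` and a 16-bit little-endian signal file
#' `<name>.dat` (WFDB format 16, three multiplexed channels). Gains are chosen
#' per channel to span the 16-bit range; this writer/reader pair round-trips
#' to within quantization error and exists so records can be exchanged with
#' standard physiological-waveform tooling.
#'
#' @param record a `waveform_record`.
#' @param dir output directory.
#' @param name record name (default: subject id).
#' @return the header path, invisibly.
#' @export
write_wfdb <- function(record, dir, name = NULL) {
  name <- name %||% record$subject_id
  n <- length(record$ecg)
  sig <- list(ecg = record$ecg, ppg = record$ppg, abp = record$abp)
  gains <- numeric(3); bases <- numeric(3)
  dig <- matrix(0L, n, 3)
  for (j in 1:3) {
    x <- sig[[j]]
    rng <- range(x)
    span <- max(rng[2] - rng[1], 1e-9)
    gains[j] <- 60000 / span
    bases[j] <- rng[1]
    dig[, j] <- as.integer(round((x - bases[j]) * gains[j])) - 30000L
  }
  hea <- file.path(dir, paste0(name, ".hea"))
  dat <- paste0(name, ".dat")
  lines <- c(sprintf("%s 3 %g %d", name, record$fs, n),
             sprintf("%s 16 %.6f(-30000)/unit 16 0 0 0 0 %s", dat, gains,
                     c("ecg", "ppg", "abp")),
             # physical offsets kept in comments; format 16 stores ADC units
             sprintf("# base %s %.10g", c("ecg", "ppg", "abp"), bases))
  writeLines(lines, hea)
  con <- file(file.path(dir, dat), "wb")
  on.exit(close(con))
  writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  invisible(hea)
}

#' Read a minimal WFDB record written by [write_wfdb()]
#'
#' @param hea_path path to the `.hea` header.
#' @return a `waveform_record`.
#' @export
read_wfdb <- function(hea_path) {
  lines <- readLines(hea_path)
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  name <- top[1]; fs <- as.numeric(top[3]); n <- as.integer(top[4])
  sig_lines <- lines[2:4]
  gains <- vapply(sig_lines, function(l) {
    as.numeric(sub("^.* 16 ([0-9.]+)\\(.*$", "\\1", l))
  }, numeric(1), USE.NAMES = FALSE)
  base_lines <- grep("^# base ", lines, value = TRUE)
  bases <- setNames(
    as.numeric(sub("^# base \\S+ ", "", base_lines)),
    sub("^# base (\\S+) .*$", "\\1", base_lines))
  con <- file(file.path(dirname(hea_path), paste0(name, ".dat")), "rb")
  on.exit(close(con))
  dig <- readBin(con, "integer", n * 3L, size = 2, endian = "little",
                 signed = TRUE)
  dig <- matrix(dig, ncol = 3, byrow = TRUE)
  phys <- function(j, nm) (dig[, j] + 30000) / gains[j] + bases[[nm]]
  structure(list(subject_id = name, fs = fs,
                 ecg = phys(1, "ecg"), ppg = phys(2, "ppg"),
                 abp = phys(3, "abp"), t0_offset_s = 0),
            class = "waveform_record")
}

#' Write a feature table to CSV/TSV
#'
#' @param table data.frame with the 25 canonical feature columns plus
#'   reference columns.
#' @param path output path; a `.tsv` extension selects tab separation.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(table, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table from CSV/TSV
#'
#' @param path input path.
#' @return data.frame.
#' @export
read_feature_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::read.table(path, sep = sep, header = TRUE)
}
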