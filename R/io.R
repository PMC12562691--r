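# Reading and writing recordings and corpus manifests.
#
# Formats:
#  * delimited text (.tsv/.csv/.txt): one column per channel, microvolts,
#    with a JSON sidecar "<path>.json" carrying {"fs", "label",
#    "recording_id"}; lossless round-trip.
#  * EDF (.edf): minimal European Data Format implementation (fixed ASCII
#    header, 16-bit little-endian samples, one data record holding the whole
#    signal). 16-bit quantization limits round-trip precision to about one
#    part in 65,000 of the per-channel amplitude range.
#  * manifest: TSV with columns recording_id, label, duration_s, fs, path.

#' Write a recording to disk
#'
#' Format chosen by extension: `.edf` for EDF, `.tsv`/`.csv`/`.txt` for
#' delimited text with a JSON sidecar.
#'
#' @param rec an `eeg_recording`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "edf") {
    write_edf(rec, path)
  } else if (ext %in% c("tsv", "csv", "txt")) {
    delim <- if (ext == "csv") "," else "\t"
    m <- t(rec$signal)
    colnames(m) <- paste0("ch", seq_len(nrow(rec$signal)))
    readr::write_delim(tibble::as_tibble(m), path, delim = delim)
    jsonlite::write_json(
      list(fs = rec$fs, label = rec$label, recording_id = rec$recording_id),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  } else {
    stop("unknown recording format: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' Read a recording from disk
#'
#' @param path input path (`.edf`, `.tsv`, `.csv`, `.txt`).
#' @param fs_hint sampling rate (Hz) for text files lacking a sidecar.
#' @return An `eeg_recording` (channel order as stored).
#' @export
read_recording <- function(path, fs_hint = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "edf") return(read_edf(path))
  if (!ext %in% c("tsv", "csv", "txt")) {
    stop("unknown recording format: .", ext, call. = FALSE)
  }
  delim <- if (ext == "csv") "," else "\t"
  first <- readLines(path, n = 1)
  has_header <- any(is.na(suppressWarnings(
    as.numeric(strsplit(first, delim, fixed = TRUE)[[1]]))))
  df <- utils::read.delim(path, sep = delim, header = has_header)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  fs <- meta$fs %||% fs_hint
  if (is.null(fs)) stop("sampling rate unknown", call. = FALSE)
  sig <- t(as.matrix(df))
  dimnames(sig) <- NULL
  eeg_recording(sig, fs = fs,
                label = meta$label %||% NA_character_,
                recording_id = meta$recording_id %||%
                  tools::file_path_sans_ext(basename(path)))
}

# ---- minimal EDF ---------------------------------------------------------

edf_pad <- function(x, width) {
  formatC(substr(as.character(x), 1, width), width = width, flag = "-")
}

write_edf <- function(rec, path) {
  ns <- n_channels(rec)
  n <- n_samples(rec)
  pmin_ <- apply(rec$signal, 1, min)
  pmax_ <- apply(rec$signal, 1, max)
  flat <- pmax_ - pmin_ <= 0
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X", 80),
    edf_pad(paste0("label=", rec$label, " id=", rec$recording_id), 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 + 256 * ns, 8), edf_pad("", 44),
    edf_pad(1, 8), edf_pad(format(rec$duration_s, digits = 8), 8),
    edf_pad(ns, 4),
    paste(edf_pad(paste0("EEG ch", seq_len(ns)), 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(edf_pad(format(pmin_, digits = 7), 8), collapse = ""),
    paste(edf_pad(format(pmax_, digits = 7), 8), collapse = ""),
    paste(rep(edf_pad(dmin, 8), ns), collapse = ""),
    paste(rep(edf_pad(dmax, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(n, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  for (ch in seq_len(ns)) {
    dig <- round((rec$signal[ch, ] - pmin_[ch]) / (pmax_[ch] - pmin_[ch]) *
                   (dmax - dmin) + dmin)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80)
  recfield <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rd_many <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  rd_many(16); rd_many(80); rd_many(8)
  pmin_ <- as.numeric(rd_many(8))
  pmax_ <- as.numeric(rd_many(8))
  dmin <- as.numeric(rd_many(8))
  dmax <- as.numeric(rd_many(8))
  rd_many(80)
  spr <- as.integer(rd_many(8))
  rd_many(32)
  total <- spr * n_rec
  sig <- matrix(0, nrow = ns, ncol = total[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, signed = TRUE,
                     endian = "little")
      idx <- ((r - 1) * spr[ch] + 1):(r * spr[ch])
      sig[ch, idx] <- (dig - dmin[ch]) / (dmax[ch] - dmin[ch]) *
        (pmax_[ch] - pmin_[ch]) + pmin_[ch]
    }
  }
  label <- if (grepl("label=", recfield)) {
    sub(".*label=(\\S+).*", "\\1", recfield)
  } else NA_character_
  if (!is.na(label) && !label %in% seizure_types()) label <- NA_character_
  rid <- if (grepl("id=", recfield)) sub(".*id=(\\S+).*", "\\1", recfield)
  else tools::file_path_sans_ext(basename(path))
  eeg_recording(sig, fs = spr[1] / rec_dur, label = label,
                recording_id = rid)
}

# ---- manifest + corpus ---------------------------------------------------

#' Write a corpus to a directory with a manifest
#'
#' One file per recording plus `manifest.tsv` with columns `recording_id`,
#' `label`, `duration_s`, `fs`, `path` (relative).
#'
#' @param corpus a corpus tibble.
#' @param dir output directory (created if absent).
#' @param format `"tsv"` or `"edf"`.
#' @return Path to the manifest, invisibly.
#' @export
write_corpus <- function(corpus, dir, format = c("tsv", "edf")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(corpus$recording, function(rec) {
    p <- paste0(rec$recording_id, ".", format)
    write_recording(rec, file.path(dir, p))
    p
  }, character(1))
  manifest <- dplyr::mutate(
    dplyr::select(corpus, "recording_id", "label", "duration_s", "fs"),
    path = paths)
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(file.path(dir, "manifest.tsv"))
}

#' Read a corpus back from a manifest
#'
#' @param manifest_path path to a manifest TSV; recording paths are resolved
#'   relative to its directory.
#' @return A corpus tibble.
#' @export
read_corpus <- function(manifest_path) {
  manifest <- readr::read_tsv(manifest_path, show_col_types = FALSE)
  if (anyDuplicated(manifest$recording_id)) {
    stop("duplicate recording_id in manifest", call. = FALSE)
  }
  check_labels(manifest$label)
  base <- dirname(manifest_path)
  recs <- purrr::pmap(manifest, function(recording_id, label, duration_s,
                                         fs, path) {
    rec <- read_recording(file.path(base, path), fs_hint = fs)
    rec$label <- label
    rec$recording_id <- recording_id
    rec
  })
  as_corpus(recs)
}

#' Resample a recording
#'
#' Polyphase resampling with anti-alias filtering; the identity when the
#' rate already matches. The output length is
#' `round(samples * target_fs / fs)`.
#'
#' @param rec an `eeg_recording`.
#' @param target_fs target sampling rate in Hz (default 250).
#' @return Resampled `eeg_recording`.
#' @export
resample_recording <- function(rec, target_fs = 250) {
  if (target_fs <= 0) stop("target_fs must be positive", call. = FALSE)
  if (isTRUE(all.equal(rec$fs, target_fs))) return(rec)
  num <- round(target_fs * 1000)
  den <- round(rec$fs * 1000)
  g <- gcd_int(num, den)
  p <- num / g
  q <- den / g
  n_out <- round(n_samples(rec) * target_fs / rec$fs)
  sig <- t(apply(rec$signal, 1, function(x) {
    y <- as.numeric(signal::resample(x, p, q))
    length(y) <- n_out            # pad/trim boundary fuzz to exact length
    y[is.na(y)] <- 0
    y
  }))
  eeg_recording(sig, fs = target_fs, label = rec$label,
                recording_id = rec$recording_id)
}

gcd_int <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}
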