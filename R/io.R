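# File interfaces. Sessions round-trip through a documented directory
# container (JSON metadata + CSV arrays; the analogue of an HDF5 container
# with groups eeg / streams / schedule / meta, using text formats only).
# Raw EEG can be exchanged as EDF (16-bit, hence quantized) and audio as WAV.

write_matrix_csv <- function(m, path) {
  data.table::fwrite(data.table::as.data.table(m), path)
}

read_matrix_csv <- function(path) {
  m <- as.matrix(data.table::fread(path))
  dimnames(m) <- NULL
  m
}

#' Save a session to a directory container
#'
#' Layout: `meta.json` (config, montage, flags), `truth/` (generative kernels
#' and topography, when present), and one `trial_NNN/` per trial holding
#' `eeg.csv`, `schedule.csv`, `meta.json` and `stream_<name>.csv`. All arrays
#' are written at full precision; save-then-load reproduces every array and
#' metadata field.
#'
#' @param session an `aad_session`.
#' @param path container directory (created; must not be an existing file).
#' @return `path`, invisibly.
#' @export
save_session <- function(session, path) {
  if (file.exists(path) && !dir.exists(path))
    stop("path exists and is not a directory", call. = FALSE)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- unclass(session$cfg)
  cfg_json$trial_counts <- as.list(cfg_json$trial_counts)
  meta <- list(n_trials = length(session$trials),
               preprocessed = session$preprocessed,
               montage = unclass(session$montage),
               cfg = cfg_json)
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!is.null(session$truth)) {
    td <- file.path(path, "truth")
    dir.create(td, showWarnings = FALSE)
    tr <- session$truth
    jsonlite::write_json(
      list(topography = tr$channel_topography,
           noise_spectrum_exponent = tr$noise_spectrum_exponent,
           kernel_lags = tr$attended_kernel$lags,
           kernel_fs = tr$attended_kernel$fs),
      file.path(td, "truth.json"), auto_unbox = TRUE, digits = NA)
    write_matrix_csv(tr$attended_kernel$coef, file.path(td, "attended_kernel.csv"))
    write_matrix_csv(tr$ignored_kernel$coef, file.path(td, "ignored_kernel.csv"))
  }
  for (i in seq_along(session$trials)) {
    tr <- session$trials[[i]]
    tdir <- file.path(path, sprintf("trial_%03d", i))
    dir.create(tdir, showWarnings = FALSE)
    jsonlite::write_json(
      list(condition = tr$condition, competing = tr$competing,
           control = tr$control, fs_eeg = tr$eeg$fs,
           eeg_channels = tr$eeg$channels,
           streams = lapply(tr$streams, function(s) s$fs),
           preprocessed = tr$preprocessed),
      file.path(tdir, "meta.json"), auto_unbox = TRUE, digits = NA)
    write_matrix_csv(tr$eeg$values, file.path(tdir, "eeg.csv"))
    data.table::fwrite(tr$schedule, file.path(tdir, "schedule.csv"))
    for (nm in names(tr$streams))
      write_matrix_csv(tr$streams[[nm]]$values,
                       file.path(tdir, paste0("stream_", nm, ".csv")))
  }
  invisible(path)
}

#' Load a session from a directory container
#'
#' @param path container directory written by [save_session()].
#' @return the reconstructed `aad_session`.
#' @export
load_session <- function(path) {
  need <- function(f) {
    fp <- file.path(path, f)
    if (!file.exists(fp))
      stop("malformed container: missing ", f, call. = FALSE)
    fp
  }
  meta <- jsonlite::fromJSON(need("meta.json"))
  montage <- make_montage(meta$montage$scalp,
                          if (is.null(meta$montage$ceegrid)) character()
                          else meta$montage$ceegrid)
  cfg <- meta$cfg
  cfg$trial_counts <- unlist(cfg$trial_counts)
  cfg <- structure(cfg, class = "sim_config")
  truth <- NULL
  tj <- file.path(path, "truth", "truth.json")
  if (file.exists(tj)) {
    ti <- jsonlite::fromJSON(tj)
    ak <- trf_kernel(read_matrix_csv(file.path(path, "truth", "attended_kernel.csv")),
                     ti$kernel_lags, ti$kernel_fs)
    ik <- trf_kernel(read_matrix_csv(file.path(path, "truth", "ignored_kernel.csv")),
                     ti$kernel_lags, ti$kernel_fs)
    truth <- structure(list(attended_kernel = ak, ignored_kernel = ik,
                            channel_topography = ti$topography,
                            noise_spectrum_exponent = ti$noise_spectrum_exponent),
                       class = "ground_truth")
  }
  trials <- lapply(seq_len(meta$n_trials), function(i) {
    tdir <- sprintf("trial_%03d", i)
    tmeta <- jsonlite::fromJSON(need(file.path(tdir, "meta.json")))
    sched_fp <- need(file.path(tdir, "schedule.csv"))
    eeg <- ts_block(read_matrix_csv(need(file.path(tdir, "eeg.csv"))),
                    tmeta$fs_eeg, tmeta$eeg_channels)
    schedule <- as.data.frame(data.table::fread(sched_fp))
    streams <- lapply(names(tmeta$streams), function(nm) {
      ts_block(read_matrix_csv(need(file.path(tdir, paste0("stream_", nm, ".csv")))),
               tmeta$streams[[nm]], nm)
    })
    names(streams) <- names(tmeta$streams)
    new_trial(tmeta$condition, streams, schedule, tmeta$competing,
              tmeta$control, eeg, preprocessed = isTRUE(tmeta$preprocessed))
  })
  new_session(trials, montage, cfg, truth,
              preprocessed = isTRUE(meta$preprocessed))
}

pad_ascii <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write EEG to an EDF file
#'
#' Minimal EDF writer: 1-s data records, 16-bit samples with per-channel
#' physical scaling. Quantization to 16 bits makes the format lossy at about
#' `range/2^16` resolution.
#'
#' @param eeg a [ts_block()] with an integer sampling rate.
#' @param path output file.
#' @param patient,recording free-text header fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(eeg, path, patient = "X", recording = "aadtrf") {
  stopifnot_block(eeg, "eeg")
  fs <- eeg$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF export needs an integer rate", call. = FALSE)
  spr <- as.integer(round(fs))
  v <- eeg$values
  ns <- ncol(v)
  nrec <- ceiling(nrow(v) / spr)
  if (nrow(v) < nrec * spr)
    v <- rbind(v, matrix(0, nrec * spr - nrow(v), ns))
  pmin <- apply(v, 2, min); pmax <- apply(v, 2, max)
  flat <- pmax - pmin < 1e-12
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeChar(paste0(pad_ascii(x, w), collapse = ""), con,
                                 eos = NULL)
  wr("0", 8); wr(patient, 80); wr(recording, 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256 * (ns + 1), 8); wr("", 44); wr(nrec, 8); wr("1", 8); wr(ns, 4)
  for (f in list(list(eeg$channels, 16), list(rep("", ns), 80),
                 list(rep("uV", ns), 8),
                 list(formatC(pmin, digits = 6, format = "g"), 8),
                 list(formatC(pmax, digits = 6, format = "g"), 8),
                 list(rep(dmin, ns), 8), list(rep(dmax, ns), 8),
                 list(rep("", ns), 80), list(rep(spr, ns), 8),
                 list(rep("", ns), 32)))
    wr(f[[1]], f[[2]])
  # header stores rounded physical bounds; quantize against the stored values
  pmin_s <- as.numeric(formatC(pmin, digits = 6, format = "g"))
  pmax_s <- as.numeric(formatC(pmax, digits = 6, format = "g"))
  dig <- matrix(0L, nrow(v), ns)
  for (j in seq_len(ns)) {
    d <- round((v[, j] - pmin_s[j]) / (pmax_s[j] - pmin_s[j]) * (dmax - dmin) + dmin)
    dig[, j] <- as.integer(pmin(pmax(d, dmin), dmax))
  }
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (j in seq_len(ns))
      writeBin(dig[idx, j], con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file.
#' @return a [ts_block()]; channel labels come from the EDF header.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  nrec <- as.integer(rd(8))
  recdur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)              # transducer
  for (i in seq_len(ns)) rd(8)               # dimension
  pmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)              # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  v <- matrix(0, nrec * spr[1], ns)
  for (r in seq_len(nrec)) {
    for (j in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[j], size = 2, endian = "little")
      v[((r - 1) * spr[j] + 1):(r * spr[j]), j] <-
        (d - dmin[j]) / (dmax[j] - dmin[j]) * (pmax[j] - pmin[j]) + pmin[j]
    }
  }
  ts_block(v, spr[1] / recdur, labels)
}

#' Split channel labels into scalp and cEEGrid montage groups
#'
#' Labels matching the cEEGrid convention (`L1`-`L10`, `R1`-`R10`) form the
#' cEEGrid group; everything else is scalp.
#'
#' @param labels channel labels.
#' @return a [make_montage()].
#' @export
montage_from_labels <- function(labels) {
  is_grid <- grepl("^[LR](10|[1-9])$", labels)
  make_montage(labels[!is_grid], labels[is_grid])
}

#' Write audio as WAV
#'
#' @param x single-channel [ts_block()] (values in `[-1, 1]` for PCM16).
#' @param path output file.
#' @param format `"pcm16"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, format = c("pcm16", "float32")) {
  stopifnot_block(x)
  format <- match.arg(format)
  v <- x$values[, 1]
  fs <- as.integer(round(x$fs))
  con <- file(path, "wb")
  on.exit(close(con))
  bits <- if (format == "pcm16") 16L else 32L
  bytes <- bits / 8L
  data_size <- length(v) * bytes
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(if (format == "pcm16") 1L else 3L, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * bytes), con, size = 4, endian = "little")
  writeBin(as.integer(bytes), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (format == "pcm16") {
    writeBin(as.integer(round(pmin(pmax(v, -1), 1) * 32767)), con, size = 2,
             endian = "little")
  } else {
    writeBin(as.numeric(v), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file (PCM16 or float32, first channel)
#'
#' @param path WAV file.
#' @return single-channel [ts_block()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4, useBytes = TRUE) != "RIFF") stop("not a WAV file", call. = FALSE)
  readBin(con, "integer", size = 4, endian = "little")
  if (readChar(con, 4, useBytes = TRUE) != "WAVE") stop("not a WAV file", call. = FALSE)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (!length(id) || nchar(id) < 4) stop("no data chunk found", call. = FALSE)
    sz <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      tag <- readBin(con, "integer", size = 2, endian = "little")
      nchan <- readBin(con, "integer", size = 2, endian = "little")
      fs <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 2, endian = "little")
      bits <- readBin(con, "integer", size = 2, endian = "little")
      if (sz > 16) readBin(con, "raw", n = sz - 16)
      fmt <- list(tag = tag, nchan = nchan, fs = fs, bits = bits)
    } else if (id == "data") {
      if (is.null(fmt)) stop("data chunk before fmt", call. = FALSE)
      n <- sz / (fmt$bits / 8)
      v <- if (fmt$tag == 3) {
        readBin(con, "numeric", n = n, size = 4, endian = "little")
      } else {
        readBin(con, "integer", n = n, size = 2, endian = "little") / 32767
      }
      if (fmt$nchan > 1) {  # mix down to mono
        v <- matrix(v, ncol = fmt$nchan, byrow = TRUE)
        v <- rowMeans(v)
      }
      return(ts_block(v, fmt$fs, "audio"))
    } else {
      readBin(con, "raw", n = sz)
    }
  }
}
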