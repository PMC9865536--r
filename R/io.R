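## File I/O: a minimal EDF writer/reader (16-bit, 5 s data records so the
## 178.2 Hz rate gives an integer 891 samples per record), a CSV fallback
## with an `# fs=` metadata line, and label tables.

pad_ascii <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  sprintf(paste0("%-", width, "s"), x)
}

edf_record_duration <- function(fs) {
  for (dur in 1:10) if (abs(fs * dur - round(fs * dur)) < 1e-6) return(dur)
  stop("no integer samples-per-record found for fs = ", fs, call. = FALSE)
}

#' Write an EEG record as EDF
#'
#' Minimal EDF: 16-bit samples, one record per `record_duration` seconds
#' (default: the smallest duration giving an integer number of samples;
#' 5 s at 178.2 Hz).  The trailing partial record is dropped.
#'
#' @param record an [eeg_record()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_edf <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  dur <- edf_record_duration(record$fs)
  spr <- as.integer(round(record$fs * dur))
  n_rec <- ncol(record$data) %/% spr
  stop_if(n_rec < 1L, "record shorter than one EDF data record (", spr,
          " samples)")
  ns <- nrow(record$data)
  pmin_v <- pmax_v <- numeric(ns)
  fmt8 <- function(v) {
    s <- sprintf("%.6g", v)
    if (nchar(s) > 8) s <- sprintf("%.3g", v)
    s
  }
  for (ch in seq_len(ns)) {
    rng <- range(record$data[ch, ])
    half <- max(abs(rng), 1e-6) * 1.01
    ## use the printed (8-character) header values for scaling so the
    ## round trip is limited by 16-bit quantisation, not header precision
    pmax_v[ch] <- as.numeric(fmt8(half))
    pmin_v[ch] <- -pmax_v[ch]
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad_ascii("0", 8), pad_ascii(record$subject_id, 80),
    pad_ascii("synthetic EEG", 80), pad_ascii("01.01.00", 8),
    pad_ascii("00.00.00", 8), pad_ascii(256 + 256 * ns, 8),
    pad_ascii("", 44), pad_ascii(n_rec, 8), pad_ascii(dur, 8),
    pad_ascii(ns, 4),
    paste(pad_ascii(record$channel_names, 16), collapse = ""),
    paste(rep(pad_ascii("", 80), ns), collapse = ""),
    paste(rep(pad_ascii("uV", 8), ns), collapse = ""),
    paste(pad_ascii(vapply(pmin_v, fmt8, character(1)), 8), collapse = ""),
    paste(pad_ascii(vapply(pmax_v, fmt8, character(1)), 8), collapse = ""),
    paste(rep(pad_ascii("-32768", 8), ns), collapse = ""),
    paste(rep(pad_ascii("32767", 8), ns), collapse = ""),
    paste(rep(pad_ascii("", 80), ns), collapse = ""),
    paste(rep(pad_ascii(spr, 8), ns), collapse = ""),
    paste(rep(pad_ascii("", 32), ns), collapse = "")),
    con, eos = NULL)
  scale <- (pmax_v - pmin_v) / (32767 - (-32768))
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- as.integer(round((record$data[ch, idx] - pmin_v[ch]) /
                                scale[ch]) - 32768)
      writeBin(pmin(pmax(dig, -32768L), 32767L), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  fld <- function(s, from, len) trimws(substr(s, from, from + len - 1))
  n_rec <- as.integer(fld(hdr, 237, 8))
  dur <- as.numeric(fld(hdr, 245, 8))
  ns <- as.integer(fld(hdr, 253, 4))
  sh <- readChar(con, 256 * ns, useBytes = TRUE)
  ## per-signal field offsets within the signal header block
  offs <- c(label = 0, transducer = 16 * ns, dim = (16 + 80) * ns,
            pmin = (16 + 80 + 8) * ns, pmax = (16 + 80 + 16) * ns,
            dmin = (16 + 80 + 24) * ns, dmax = (16 + 80 + 32) * ns,
            prefilter = (16 + 80 + 40) * ns,
            spr = (16 + 80 + 40 + 80) * ns)
  getf <- function(name, len)
    vapply(seq_len(ns), function(i)
      fld(sh, offs[[name]] + (i - 1) * len + 1, len), character(1))
  labels <- getf("label", 16)
  pmin_v <- as.numeric(getf("pmin", 8))
  pmax_v <- as.numeric(getf("pmax", 8))
  dmin <- as.numeric(getf("dmin", 8))
  dmax <- as.numeric(getf("dmax", 8))
  spr <- as.integer(getf("spr", 8))
  fs <- spr[1] / dur
  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", spr[ch], size = 2, endian = "little")
      phys <- pmin_v[ch] + (dig - dmin[ch]) * (pmax_v[ch] - pmin_v[ch]) /
        (dmax[ch] - dmin[ch])
      data[ch, ((r - 1L) * spr[ch] + 1L):(r * spr[ch])] <- phys
    }
  }
  sid <- trimws(substr(hdr, 9, 88))
  list(data = data, fs = fs, labels = labels, subject_id = sid)
}

#' Read an EEG record from EDF or CSV
#'
#' EDF as written by [write_edf()] (any EDF with the four montage channels
#' works); CSV with a `# fs=<Hz> subject=<id>` first line and columns
#' `L1`, `L2`, `R1`, `R2`.  Channels are reordered to L1, L2, R1, R2.
#'
#' @param path input file (`.edf` or `.csv`).
#' @return an [eeg_record()].
#' @export
read_eeg <- function(path) {
  stop_if(!file.exists(path), "file not found: ", path)
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    raw <- read_edf(path)
    miss <- setdiff(.eeg_channels, raw$labels)
    stop_if(length(miss) > 0, "missing channel(s): ",
            paste(miss, collapse = ", "))
    ord <- match(.eeg_channels, raw$labels)
    eeg_record(raw$data[ord, , drop = FALSE], raw$fs,
               subject_id = raw$subject_id)
  } else {
    first <- readLines(path, n = 1)
    stop_if(!grepl("^#\\s*fs=", first),
            "CSV must start with a '# fs=<Hz>' metadata line")
    fs <- as.numeric(sub(".*fs=([0-9.]+).*", "\\1", first))
    sid <- if (grepl("subject=", first))
      sub(".*subject=(\\S+).*", "\\1", first) else "S01"
    df <- read.csv(path, comment.char = "#")
    miss <- setdiff(.eeg_channels, names(df))
    stop_if(length(miss) > 0, "missing channel(s): ",
            paste(miss, collapse = ", "))
    eeg_record(t(as.matrix(df[, .eeg_channels])), fs, subject_id = sid)
  }
}

#' Write an EEG record as CSV
#' @param record an [eeg_record()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_eeg_csv <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  writeLines(sprintf("# fs=%g subject=%s", record$fs, record$subject_id),
             path)
  df <- as.data.frame(t(record$data))
  names(df) <- record$channel_names
  suppressWarnings(write.table(df, path, append = TRUE, sep = ",",
                               row.names = FALSE, quote = FALSE))
  invisible(path)
}

write_manifest <- function(path, stage, config, seed, extra = list()) {
  jsonlite::write_json(
    c(list(stage = stage, seed = seed,
           package_version = as.character(utils::packageVersion("anescore")),
           config = config,
           config_hash = substr(paste(
             as.hexmode(utils::head(utf8ToInt(
               paste(deparse(config), collapse = "")), 64)), collapse = ""), 1, 40)),
      extra),
    path, auto_unbox = TRUE, pretty = TRUE, force = TRUE, digits = NA)
  invisible(path)
}

samples_to_csv <- function(samples, path) {
  df <- data.frame(subject = samples$subject, psi = samples$psi)
  xs <- as.data.frame(samples$x)
  names(xs) <- paste0("x", seq_len(ncol(xs)))
  writeLines(sprintf("# fs=%g window=%d", samples$fs, samples$window), path)
  suppressWarnings(write.table(cbind(df, xs), path, append = TRUE,
                               sep = ",", row.names = FALSE, quote = FALSE))
  invisible(path)
}

samples_from_csv <- function(path) {
  first <- readLines(path, n = 1)
  stop_if(!grepl("^#\\s*fs=", first), "not a samples CSV: ", path)
  fs <- as.numeric(sub(".*fs=([0-9.]+).*", "\\1", first))
  win <- as.integer(sub(".*window=([0-9]+).*", "\\1", first))
  df <- read.csv(path, comment.char = "#")
  structure(list(x = as.matrix(df[, grep("^x[0-9]+$", names(df))]),
                 psi = df$psi, subject = as.character(df$subject),
                 fs = fs, window = win),
            class = "doa_samples")
}
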