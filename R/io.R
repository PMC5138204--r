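# File I/O: European Data Format (EDF) recordings, delimited event files,
# and result export.  The EDF reader/writer below covers the plain
# continuous EDF subset used here (identical sampling rate on all signals,
# 1-second data records, 16-bit samples).

pad_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1, width)
}

num_field <- function(x, width) pad_field(format(x, trim = TRUE), width)

#' Write a recording to an EDF file
#'
#' Stores the sample matrix as 16-bit EDF with one-second data records and
#' a symmetric physical range per signal; the tail is zero-padded to a
#' whole record.  Events are not stored in the EDF itself — use
#' [write_events()] for the sidecar table.
#'
#' @param rec A [continuous_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "continuous_recording"))
  ns <- nrow(rec$samples)
  spr <- round(rec$fs) # samples per 1 s record
  n_rec <- ceiling(ncol(rec$samples) / spr)
  x <- rec$samples
  if (ncol(x) < n_rec * spr) {
    x <- cbind(x, matrix(0, ns, n_rec * spr - ncol(x)))
  }
  pmax_ <- apply(abs(x), 1, max)
  pmax_ <- ifelse(pmax_ > 0, pmax_ * (1 + 1e-3), 1)
  # scale with the value actually stored in the 8-char ASCII header field,
  # otherwise the reader reconstructs with a subtly different gain
  pmax_ <- as.numeric(sprintf("%.6g", pmax_))

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("synthetic", 80), pad_field("riemerp", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 + ns * 256, 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field(1, 8), pad_field(ns, 4)
  )
  sig <- paste0(
    paste(pad_field(rec$channel_names, 16), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field("uV", 8), ns), collapse = ""),
    paste(num_field(sprintf("%.6g", -pmax_), 8), collapse = ""),
    paste(num_field(sprintf("%.6g", pmax_), 8), collapse = ""),
    paste(rep(pad_field(-32768, 8), ns), collapse = ""),
    paste(rep(pad_field(32767, 8), ns), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field(spr, 8), ns), collapse = ""),
    paste(rep(pad_field("", 32), ns), collapse = "")
  )
  writeChar(paste0(hdr, sig), con, eos = NULL)

  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    # inverse of the reader's affine map digital -> physical
    dig <- round((x[, cols, drop = FALSE] + pmax_) / (2 * pmax_) * 65535 -
                   32768)
    block <- t(pmin(pmax(dig, -32768), 32767))
    storage.mode(block) <- "integer"
    writeBin(as.integer(block), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf_header <- function(con) {
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8); patient <- rd(80); recording <- rd(80)
  date <- rd(8); time <- rd(8)
  hdr_bytes <- as.integer(rd(8)); reserved <- rd(44)
  n_rec <- as.integer(rd(8)); dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  field <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- field(16); transducer <- field(80); dim_ <- field(8)
  pmin <- as.numeric(field(8)); pmax <- as.numeric(field(8))
  dmin <- as.numeric(field(8)); dmax <- as.numeric(field(8))
  prefilter <- field(80); spr <- as.integer(field(8)); field(32)
  list(ns = ns, n_rec = n_rec, dur = dur, labels = labels,
       pmin = pmin, pmax = pmax, dmin = dmin, dmax = dmax, spr = spr,
       hdr_bytes = hdr_bytes)
}

#' Read an EDF recording (optionally with an event file)
#'
#' Reads a continuous EDF file in which every signal shares the same
#' sampling rate, and attaches the events from a delimited sidecar file
#' when given.
#'
#' @param path EDF file path.
#' @param event_path Optional event file path (see [read_events()]).
#' @return A [continuous_recording()].
#' @export
read_edf <- function(path, event_path = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  if (length(unique(h$spr)) != 1) {
    stop("signals with differing sampling rates are not supported")
  }
  spr <- h$spr[1]
  fs <- spr / h$dur
  samples <- matrix(0, h$ns, h$n_rec * spr)
  for (r in seq_len(h$n_rec)) {
    raw <- readBin(con, "integer", n = h$ns * spr, size = 2,
                   endian = "little")
    if (length(raw) < h$ns * spr) stop("EDF file is truncated")
    block <- matrix(raw, nrow = spr, ncol = h$ns)
    cols <- ((r - 1) * spr + 1):(r * spr)
    for (s in seq_len(h$ns)) {
      samples[s, cols] <- (block[, s] - h$dmin[s]) *
        (h$pmax[s] - h$pmin[s]) / (h$dmax[s] - h$dmin[s]) + h$pmin[s]
    }
  }
  events <- if (!is.null(event_path)) read_events(event_path) else NULL
  continuous_recording(samples, fs, h$labels, events)
}

#' Read a delimited stimulus event file
#'
#' Expects a tab-separated file with header columns `onset_sample`
#' (0-based, strictly increasing), `code` (1..K), `is_target` (0/1), and
#' optionally `block`.  Violations are reported with the offending line
#' number.
#'
#' @param path Event file path.
#' @return Data frame with columns `onset`, `code`, `is_target` and, when
#'   present, `block`.
#' @export
read_events <- function(path) {
  ev <- utils::read.delim(path, sep = "\t")
  required <- c("onset_sample", "code", "is_target")
  missing_cols <- setdiff(required, names(ev))
  if (length(missing_cols) > 0) {
    stop("event file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad <- which(diff(ev$onset_sample) <= 0)
  if (length(bad) > 0) {
    # +2: one for the header line, one for diff() offset
    stop(sprintf("event onsets must be strictly increasing (file line %d)",
                 bad[1] + 2L))
  }
  out <- data.frame(onset = as.integer(ev$onset_sample),
                    code = as.integer(ev$code),
                    is_target = as.logical(ev$is_target))
  if ("block" %in% names(ev)) out$block <- as.integer(ev$block)
  validate_events(out)
}

#' Write a stimulus event file
#'
#' @param events Event data frame (columns `onset`, `code`, `is_target`,
#'   optionally `block`) as carried by a [continuous_recording()].
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- data.frame(onset_sample = events$onset, code = events$code,
                    is_target = as.integer(events$is_target))
  if ("block" %in% names(events)) out$block <- events$block
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write evaluation results to a directory
#'
#' Emits `accuracy.tsv` (classifier, k, mean, sd, p), `grand_average.tsv`
#' (long-format waveforms with standard errors) and `metadata.json`
#' (configuration, seed, package version, aggregation convention).  Output
#' is deterministic for a fixed seed: repeated runs produce byte-identical
#' files.
#'
#' @param table An [evaluate_accuracy()] result.
#' @param ga A [grand_average()] result, or `NULL` to skip waveforms.
#' @param outdir Output directory (created if needed).
#' @param config Optional named list recorded in the metadata.
#' @param seed Seed recorded in the metadata.
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(table, ga, outdir, config = list(), seed = NULL) {
  stopifnot(inherits(table, "accuracy_table"))
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", outdir)
  }
  files <- character(0)

  tab <- table$table
  tab$p <- NA_real_
  if (!is.null(table$p_values)) {
    tab$p <- table$p_values$p[match(tab$k, table$p_values$k)]
  }
  acc_path <- file.path(outdir, "accuracy.tsv")
  utils::write.table(format(tab, digits = 10, trim = TRUE), acc_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, acc_path)

  if (!is.null(ga)) {
    stopifnot(inherits(ga, "grand_average"))
    M <- ncol(ga$target$mean)
    tt <- (0:(M - 1)) / ga$fs * 1000
    long <- do.call(rbind, lapply(c("target", "nontarget"), function(cl) {
      comp <- ga[[cl]]
      do.call(rbind, lapply(seq_len(nrow(comp$mean)), function(ch) {
        data.frame(class = cl, channel = ga$channel_names[ch],
                   time_ms = tt, mean = comp$mean[ch, ], se = comp$se[ch, ])
      }))
    }))
    ga_path <- file.path(outdir, "grand_average.tsv")
    utils::write.table(format(long, digits = 10, trim = TRUE), ga_path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, ga_path)
  }

  meta <- list(
    config = config,
    seed = seed,
    chance_percent = table$chance_percent,
    n_folds = table$n_folds,
    k_range = table$k_range,
    aggregation = table$aggregation,
    package = "riemerp",
    package_version = as.character(utils::packageVersion("riemerp"))
  )
  meta_path <- file.path(outdir, "metadata.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  files <- c(files, meta_path)
  invisible(files)
}
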