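# Continuous EEG -> filtered, epoched, prototype-augmented super-trial
# covariance features.

#' Continuous multi-channel EEG recording
#'
#' Container for a channels-by-time sample matrix (microvolts) with an
#' event table.  Event onsets are 0-based sample indices (the convention of
#' the accompanying event files); an epoch of `M` samples starting at onset
#' `o` covers samples `o .. o + M - 1` in 0-based terms.
#'
#' @param samples Numeric matrix, channels x time (microvolts).
#' @param fs Sampling rate in Hz.
#' @param channel_names Optional character vector of channel labels
#'   (10/10 positions such as `"Cz"`, `"Pz"`).
#' @param events Optional data frame with columns `onset` (0-based sample,
#'   strictly increasing), `code` (stimulus code, 1..K), `is_target`
#'   (logical), and optionally `block` (selection-block index).
#' @return An object of class `continuous_recording`.
#' @export
continuous_recording <- function(samples, fs, channel_names = NULL,
                                 events = NULL) {
  stopifnot(is.matrix(samples), fs > 0)
  n <- nrow(samples)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(n))
  stopifnot(length(channel_names) == n)
  if (!is.null(events)) {
    events <- validate_events(events, n_samples = ncol(samples))
  }
  structure(
    list(samples = samples, fs = fs, channel_names = channel_names,
         events = events),
    class = "continuous_recording"
  )
}

validate_events <- function(events, n_samples = Inf) {
  stopifnot(is.data.frame(events))
  required <- c("onset", "code", "is_target")
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols) > 0) {
    stop("event table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(events) > 0) {
    if (any(events$onset < 0)) stop("event onsets must be non-negative")
    d <- diff(events$onset)
    if (any(d <= 0)) {
      stop(sprintf("event onsets must be strictly increasing (line %d)",
                   which(d <= 0)[1] + 1L))
    }
    if (any(events$code < 1) || any(events$code != round(events$code))) {
      stop("stimulus codes must be positive integers")
    }
  }
  events$is_target <- as.logical(events$is_target)
  events
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf(
    "<continuous_recording: %d channels x %d samples @ %g Hz, %d events>\n",
    nrow(x$samples), ncol(x$samples), x$fs,
    if (is.null(x$events)) 0L else nrow(x$events)
  ))
  invisible(x)
}

# ---- zero-phase filtering ----------------------------------------------

# One-pass IIR filter started in steady state for a constant input equal to
# the first sample, so a DC signal passes without any transient.
filter_steady <- function(b, a, x) {
  g <- sum(b) / sum(a)
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x[1], length(b) - 1),
                            init.y = rep(g * x[1], length(a) - 1)))
}

# Forward-backward (zero-phase) filtering with odd-symmetric end padding.
# The pad length is taken from the slowest filter pole (six time constants)
# so that even a 0.1 Hz high-pass transient has decayed before the data
# proper begins.
filtfilt_zerophase <- function(b, a, x) {
  n <- length(x)
  r <- max(Mod(polyroot(rev(a))))
  tau <- if (r < 1) -1 / log(r) else n
  pad <- as.integer(min(n - 1, max(3 * max(length(a), length(b)),
                                   ceiling(6 * tau))))
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- filter_steady(b, a, ext)
  y <- rev(filter_steady(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Zero-phase band-pass filter a recording
#'
#' Applies a Butterworth band-pass forward and backward (zero phase, so the
#' P300 latency is not shifted) to every channel.  The band is realised as a
#' cascade of a high-pass at `low` and a low-pass at `high`, each of order
#' `order`; the cascade avoids the numerical ill-conditioning of a direct
#' band-pass transfer function whose lower edge sits at a tiny fraction of
#' the Nyquist frequency.
#'
#' @param rec A [continuous_recording()].
#' @param low Lower cut-off in Hz (default 0.1).
#' @param high Upper cut-off in Hz (default 40).
#' @param order Butterworth order of each cascade section (default 4).
#' @return The recording with filtered samples; events are untouched.
#' @export
bandpass_filter <- function(rec, low = 0.1, high = 40, order = 4L) {
  stopifnot(inherits(rec, "continuous_recording"))
  nyq <- rec$fs / 2
  if (!(0 < low && low < high)) stop("need 0 < low < high")
  if (high >= nyq) {
    stop(sprintf("high cut-off %g Hz is at or above the Nyquist frequency %g Hz",
                 high, nyq))
  }
  hp <- signal::butter(order, low / nyq, type = "high")
  lp <- signal::butter(order, high / nyq, type = "low")
  out <- rec$samples
  for (ch in seq_len(nrow(out))) {
    y <- filtfilt_zerophase(hp$b, hp$a, out[ch, ])
    out[ch, ] <- filtfilt_zerophase(lp$b, lp$a, y)
  }
  rec$samples <- out
  rec
}

# ---- epochs -------------------------------------------------------------

#' Labelled single-trial ERP epochs
#'
#' @param epochs 3-d array, trials x channels x samples.
#' @param fs Sampling rate in Hz.
#' @param labels Integer class per trial: 1 = rare target (carries the
#'   P300), 2 = non-target.
#' @param stimulus_codes Stimulus code 1..K per trial.
#' @param block_ids Selection-block index per trial.
#' @param channel_names Optional channel labels.
#' @param group Optional within-(block, code) occurrence index, filled in by
#'   [average_erps()].
#' @param window Epoch window in ms relative to stimulus onset.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, fs, labels, stimulus_codes, block_ids,
                      channel_names = NULL, group = NULL,
                      window = c(0, 1000)) {
  stopifnot(is.array(epochs), length(dim(epochs)) == 3, fs > 0)
  n_trials <- dim(epochs)[1]
  stopifnot(
    length(labels) == n_trials,
    length(stimulus_codes) == n_trials,
    length(block_ids) == n_trials,
    all(labels %in% c(1L, 2L))
  )
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(dim(epochs)[2]))
  structure(
    list(epochs = epochs, fs = fs, window = window,
         labels = as.integer(labels),
         stimulus_codes = as.integer(stimulus_codes),
         block_ids = as.integer(block_ids),
         group = if (is.null(group)) NULL else as.integer(group),
         channel_names = channel_names),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf(
    "<epoch_set: %d trials x %d channels x %d samples @ %g Hz (%d targets, %d non-targets)>\n",
    d[1], d[2], d[3], x$fs, sum(x$labels == 1), sum(x$labels == 2)
  ))
  invisible(x)
}

n_trials <- function(es) dim(es$epochs)[1]

get_epoch <- function(es, i) {
  m <- es$epochs[i, , , drop = FALSE]
  dim(m) <- dim(es$epochs)[2:3]
  m
}

#' Subset an epoch set by trial index
#'
#' @param x An [epoch_set()].
#' @param i Trial indices (any form accepted by row subsetting).
#' @param ... Unused.
#' @return An [epoch_set()] with the selected trials.
#' @export
`[.epoch_set` <- function(x, i, ...) subset_epochs(x, i)

subset_epochs <- function(es, idx) {
  epoch_set(es$epochs[idx, , , drop = FALSE], es$fs,
            es$labels[idx], es$stimulus_codes[idx], es$block_ids[idx],
            channel_names = es$channel_names,
            group = if (is.null(es$group)) NULL else es$group[idx],
            window = es$window)
}

#' Cut 0-1000 ms epochs around stimulus onsets
#'
#' Extracts one epoch of `round(fs * window_s)` samples per event, starting
#' at the event onset sample.  Events whose epoch would run past the end of
#' the recording are dropped with a warning.
#'
#' @param rec A [continuous_recording()] with an event table.
#' @param window_s Epoch length in seconds (default 1, i.e. 0-1000 ms).
#' @return An [epoch_set()]; labels are 1 for targets, 2 for non-targets.
#' @export
extract_epochs <- function(rec, window_s = 1) {
  stopifnot(inherits(rec, "continuous_recording"))
  if (is.null(rec$events) || nrow(rec$events) == 0) {
    stop("recording carries no events to epoch")
  }
  M <- round(rec$fs * window_s)
  total <- ncol(rec$samples)
  ev <- rec$events
  keep <- ev$onset + M <= total
  if (any(!keep)) {
    warning(sprintf("dropped %d truncated epoch(s) at the recording edge",
                    sum(!keep)))
    ev <- ev[keep, , drop = FALSE]
  }
  n <- nrow(ev)
  N <- nrow(rec$samples)
  epochs <- array(0, dim = c(n, N, M))
  for (i in seq_len(n)) {
    epochs[i, , ] <- rec$samples[, (ev$onset[i] + 1):(ev$onset[i] + M)]
  }
  blocks <- if ("block" %in% names(ev)) ev$block else rep(1L, n)
  epoch_set(epochs, rec$fs,
            labels = ifelse(ev$is_target, 1L, 2L),
            stimulus_codes = ev$code,
            block_ids = blocks,
            channel_names = rec$channel_names,
            window = c(0, window_s * 1000))
}

# ---- prototypes and super-trials ---------------------------------------

#' Averaged target / non-target prototype responses
#'
#' Computes the arithmetic mean epoch of each class over a *training*
#' epoch set.  The prototypes are later stacked under every single trial to
#' form the super-trial whose covariance carries the trial-to-prototype
#' correlation structure; computing them from training data only (and
#' passing them explicitly to [build_super_trial()]) makes test-set leakage
#' impossible by construction.
#'
#' @param train An [epoch_set()] containing both classes.
#' @return List with `target` and `nontarget` channel-by-sample prototype
#'   matrices and the per-class trial counts.
#' @export
class_prototypes <- function(train) {
  stopifnot(inherits(train, "epoch_set"))
  it <- which(train$labels == 1L)
  inr <- which(train$labels == 2L)
  if (length(it) == 0) stop("no target epochs in the training set")
  if (length(inr) == 0) stop("no non-target epochs in the training set")
  avg <- function(idx) {
    m <- train$epochs[idx, , , drop = FALSE]
    apply(m, c(2, 3), mean)
  }
  structure(
    list(target = avg(it), nontarget = avg(inr),
         n_target = length(it), n_nontarget = length(inr)),
    class = "erp_prototypes"
  )
}

#' Stack a trial with the class prototypes into a super-trial
#'
#' Rows are ordered `[single-trial epoch; target prototype; non-target
#' prototype]`, giving a 3N x M matrix; every row is centred to zero mean
#' over the epoch, matching the zero-mean assumption under which the sample
#' covariance is the sufficient description of the trial.
#'
#' @param epoch Channel-by-sample matrix of one trial (N x M).
#' @param prototypes Output of [class_prototypes()].
#' @return An object of class `super_trial` with the 3N x M matrix.
#' @export
build_super_trial <- function(epoch, prototypes) {
  stopifnot(is.matrix(epoch), inherits(prototypes, "erp_prototypes"))
  if (!identical(dim(epoch), dim(prototypes$target)) ||
      !identical(dim(epoch), dim(prototypes$nontarget))) {
    stop("epoch and prototypes must share channel and sample dimensions")
  }
  X <- rbind(epoch, prototypes$target, prototypes$nontarget)
  X <- X - rowMeans(X)
  structure(
    list(matrix = X, n_channels = nrow(epoch), n_samples = ncol(epoch)),
    class = "super_trial"
  )
}

#' Sample covariance of a super-trial
#'
#' Computes \eqn{C = X X^\top / (M - 1)} on the row-centred 3N x M
#' super-trial matrix and passes the result through [ensure_spd()], so that
#' rank-deficient covariances from short epochs are floored back onto the
#' SPD manifold.
#'
#' @param st A [build_super_trial()] result.
#' @param loading Diagonal-loading floor forwarded to [ensure_spd()].
#' @return An `spd` covariance matrix of dimension 3N x 3N.
#' @export
supertrial_covariance <- function(st, loading = 1e-10) {
  stopifnot(inherits(st, "super_trial"))
  M <- st$n_samples
  if (M < 2) stop("need at least 2 samples to form a covariance")
  C <- st$matrix %*% t(st$matrix) / (M - 1)
  ensure_spd(C, loading)
}

#' Super-trial covariances for every trial of an epoch set
#'
#' @param epochs An [epoch_set()].
#' @param prototypes Output of [class_prototypes()] (from training data).
#' @param loading Forwarded to [supertrial_covariance()].
#' @return List of `spd` covariance matrices, one per trial.
#' @export
supertrial_covariances <- function(epochs, prototypes, loading = 1e-10) {
  lapply(seq_len(n_trials(epochs)), function(i) {
    supertrial_covariance(build_super_trial(get_epoch(epochs, i), prototypes),
                          loading)
  })
}
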