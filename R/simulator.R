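# Synthetic spatial-oddball EEG sessions with controllable P300 structure.
# The simulator is the primary test input of the package: it reproduces the
# block-randomised K-command oddball schedule, an additive Gaussian-bump
# P300 on rare targets, and a white + 1/f background.

#' Oddball paradigm configuration
#'
#' Describes one K-command oddball session: each selection block presents
#' every stimulus code once per sub-round in randomised order, for
#' `reps_per_command` sub-rounds, while the user attends a single target
#' command.  Successive onsets are separated by `stim_ms + isi_ms`
#' (stimulus duration plus inter-stimulus interval); with short ISIs and
#' 1000 ms epochs, consecutive epochs overlap — a property of the paradigm,
#' not an error.
#'
#' @param K Number of commands (stimulus codes), >= 2.
#' @param isi_ms Inter-stimulus interval in ms (gap from stimulus offset to
#'   the next onset).
#' @param stim_ms Stimulus duration in ms.
#' @param fs Sampling rate in Hz.
#' @param n_channels Number of EEG channels (8 and 16 carry standard
#'   parieto-central montages).
#' @param reps_per_command Stimulus repetitions per command per block.
#' @param n_blocks Number of selection blocks per session.
#' @param attended_sequence Optional integer vector, the attended command
#'   of each block; drawn uniformly at simulation time when `NULL`.
#' @param channel_names Optional channel labels; defaults to the montage
#'   for 8 or 16 channels.
#' @return An object of class `paradigm_config`.
#' @export
paradigm_config <- function(K = 5L, isi_ms = 150, stim_ms = 100, fs = 512,
                            n_channels = 8L, reps_per_command = 5L,
                            n_blocks = 10L, attended_sequence = NULL,
                            channel_names = NULL) {
  stopifnot(K >= 2, isi_ms > 0, stim_ms > 0, fs > 0,
            n_channels >= 1, reps_per_command >= 1, n_blocks >= 1)
  if (!is.null(attended_sequence)) {
    stopifnot(length(attended_sequence) == n_blocks,
              all(attended_sequence %in% seq_len(K)))
  }
  if (is.null(channel_names)) channel_names <- default_montage(n_channels)
  stopifnot(length(channel_names) == n_channels)
  structure(
    list(K = as.integer(K), isi_ms = isi_ms, stim_ms = stim_ms, fs = fs,
         n_channels = as.integer(n_channels),
         reps_per_command = as.integer(reps_per_command),
         n_blocks = as.integer(n_blocks),
         attended_sequence = attended_sequence,
         channel_names = channel_names),
    class = "paradigm_config"
  )
}

default_montage <- function(n) {
  base8 <- c("Cz", "Pz", "P3", "P4", "C3", "C4", "CP5", "CP6")
  ext16 <- c(base8, "P1", "P2", "POz", "C1", "C2", "FC1", "FC2", "FCz")
  if (n == 8) base8
  else if (n == 16) ext16
  else if (n < 8) base8[seq_len(n)]
  else c(ext16, paste0("ch", seq_len(n - 16)))[seq_len(n)]
}

# Paradigm presets mirroring the nine reviewed tactile/auditory oddball
# set-ups (command count, ISI, stimulus duration, montage size, sampling
# rate).  Where a study did not state a timing or rate, the common values
# of the remaining studies (ISI 150 ms, stimulus 100 ms, 512 Hz) are used.
paradigm_preset_table <- list(
  vrtba = list(K = 5L, isi_ms = 150, stim_ms = 100, fs = 512, n_channels = 8L),
  vrtpp = list(K = 5L, isi_ms = 150, stim_ms = 100, fs = 512, n_channels = 8L),
  rtc   = list(K = 5L, isi_ms = 150, stim_ms = 100, fs = 512, n_channels = 16L),
  rbt   = list(K = 6L, isi_ms = 150, stim_ms = 100, fs = 512, n_channels = 16L),
  rautd = list(K = 6L, isi_ms = 150, stim_ms = 100, fs = 512, n_channels = 16L),
  rtpp  = list(K = 6L, isi_ms = 400, stim_ms = 100, fs = 256, n_channels = 8L),
  rsa   = list(K = 5L, isi_ms = 150, stim_ms = 150, fs = 512, n_channels = 16L),
  rtg   = list(K = 5L, isi_ms = 150, stim_ms = 100, fs = 512, n_channels = 8L),
  rfbt  = list(K = 6L, isi_ms = 150, stim_ms = 100, fs = 512, n_channels = 8L)
)

#' Named oddball paradigm presets
#'
#' Returns a [paradigm_config()] for one of the built-in scenarios
#' (`vrtba`, `vrtpp`, `rtc`, `rbt`, `rautd`, `rtpp`, `rsa`, `rtg`,
#' `rfbt`), each carrying the command count, stimulus timing, montage size
#' and sampling rate of the corresponding tactile/auditory BCI set-up.
#' Additional arguments override preset fields (e.g. `n_blocks`).
#'
#' @param name Preset name.
#' @param ... Overrides passed on to [paradigm_config()].
#' @return A `paradigm_config`.
#' @export
paradigm_preset <- function(name, ...) {
  name <- match.arg(name, names(paradigm_preset_table))
  args <- utils::modifyList(paradigm_preset_table[[name]], list(...))
  do.call(paradigm_config, args)
}

#' P300 response and background-noise model
#'
#' The target-only ERP component is a single positive Gaussian bump,
#' peaking by default at 450 ms with an 80 ms temporal standard deviation —
#' a minimal model of the rare-target positivity seen in the 300-600 ms
#' window — scaled per channel by a smooth parieto-central topography.
#' The background is white Gaussian noise plus an independent 1/f ("pink")
#' component per channel.
#'
#' @param p300_amplitude Peak amplitude in microvolts added on rare targets
#'   (0 switches the effect off).
#' @param p300_latency_ms Peak latency in ms after stimulus onset.
#' @param p300_width_ms Gaussian temporal standard deviation in ms.
#' @param channel_topography Optional per-channel gain vector; defaults to
#'   a smooth scalp map peaking at Pz.
#' @param noise_sigma White-noise standard deviation in microvolts.
#' @param pink_noise_scale Standard deviation of the 1/f component in
#'   microvolts.
#' @param seed Optional random seed stored with the model; simulation
#'   functions use it unless given an explicit seed.
#' @return An object of class `erp_model`.
#' @export
erp_model <- function(p300_amplitude = 5, p300_latency_ms = 450,
                      p300_width_ms = 80, channel_topography = NULL,
                      noise_sigma = 4, pink_noise_scale = 4, seed = NULL) {
  stopifnot(p300_amplitude >= 0, p300_latency_ms > 0, p300_width_ms > 0,
            noise_sigma >= 0, pink_noise_scale >= 0)
  structure(
    list(p300_amplitude = p300_amplitude,
         p300_latency_ms = p300_latency_ms,
         p300_width_ms = p300_width_ms,
         channel_topography = channel_topography,
         noise_sigma = noise_sigma,
         pink_noise_scale = pink_noise_scale,
         seed = seed),
    class = "erp_model"
  )
}

# smooth scalp gains for the P300 topography, peaking parieto-centrally
topography_gains <- c(
  Fz = 0.40, FCz = 0.50, FC1 = 0.45, FC2 = 0.45,
  Cz = 0.85, C1 = 0.70, C2 = 0.70, C3 = 0.55, C4 = 0.55,
  CPz = 0.90, CP5 = 0.50, CP6 = 0.50,
  Pz = 1.00, P1 = 0.85, P2 = 0.85, P3 = 0.70, P4 = 0.70, POz = 0.90
)

channel_topography_for <- function(channel_names) {
  g <- topography_gains[channel_names]
  g[is.na(g)] <- 0.6
  unname(g)
}

p300_bump <- function(erp, fs, M) {
  tt <- (0:(M - 1)) / fs * 1000
  erp$p300_amplitude *
    exp(-0.5 * ((tt - erp$p300_latency_ms) / erp$p300_width_ms)^2)
}

# 1/f amplitude noise via spectral synthesis, standardised to unit variance
pink_noise <- function(n) {
  if (n < 4) return(stats::rnorm(n))
  nf <- (n - 1) %/% 2
  amp <- 1 / sqrt(seq_len(nf))
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  full[n:(n - nf + 1)] <- Conj(spec)
  if (n %% 2 == 0) full[n / 2 + 1] <- complex(real = stats::rnorm(1) / sqrt(nf))
  x <- Re(stats::fft(full, inverse = TRUE))
  (x - mean(x)) / stats::sd(x)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

sample_codes <- function(cfg) {
  # block-randomised order: each code once per sub-round
  unlist(lapply(seq_len(cfg$n_blocks * cfg$reps_per_command), function(i) {
    sample.int(cfg$K)
  }))
}

noise_epoch <- function(erp, N, M) {
  e <- matrix(stats::rnorm(N * M, 0, erp$noise_sigma), N, M)
  if (erp$pink_noise_scale > 0) {
    for (ch in seq_len(N)) {
      e[ch, ] <- e[ch, ] + erp$pink_noise_scale * pink_noise(M)
    }
  }
  e
}

#' Simulate a continuous oddball EEG session
#'
#' Generates a full multi-channel recording: stimulus codes are presented
#' in block-randomised order (each code once per sub-round,
#' `reps_per_command` sub-rounds per block, one attended command per
#' block), target events receive the additive Gaussian-bump P300 scaled by
#' the channel topography, and the background is white plus 1/f noise.
#' Blocks are separated by a one-second gap and the recording is padded so
#' that the final epoch fits.  The same seed reproduces the session
#' bit-identically.
#'
#' @param cfg A [paradigm_config()].
#' @param erp An [erp_model()].
#' @param seed Random seed; defaults to the model's stored seed.
#' @return A [continuous_recording()] whose event table carries `onset`
#'   (0-based sample), `code`, `is_target` and `block`, plus an
#'   `attended_sequence` field with the target command of each block.
#' @export
simulate_session <- function(cfg, erp = erp_model(), seed = erp$seed) {
  stopifnot(inherits(cfg, "paradigm_config"), inherits(erp, "erp_model"))
  with_seed(seed, {
    M <- round(cfg$fs)
    soa <- round((cfg$isi_ms + cfg$stim_ms) / 1000 * cfg$fs)
    gap <- round(cfg$fs) # 1 s between blocks
    attended <- cfg$attended_sequence
    if (is.null(attended)) {
      attended <- sample.int(cfg$K, cfg$n_blocks, replace = TRUE)
    }

    onsets <- integer(0)
    codes <- integer(0)
    blocks <- integer(0)
    t0 <- round(cfg$fs / 2)
    for (b in seq_len(cfg$n_blocks)) {
      for (r in seq_len(cfg$reps_per_command)) {
        perm <- sample.int(cfg$K)
        onsets <- c(onsets, t0 + soa * (seq_len(cfg$K) - 1L))
        codes <- c(codes, perm)
        blocks <- c(blocks, rep(b, cfg$K))
        t0 <- t0 + soa * cfg$K
      }
      t0 <- t0 + gap
    }
    total <- max(onsets) + M

    N <- cfg$n_channels
    samples <- matrix(stats::rnorm(N * total, 0, erp$noise_sigma), N, total)
    if (erp$pink_noise_scale > 0) {
      for (ch in seq_len(N)) {
        samples[ch, ] <- samples[ch, ] + erp$pink_noise_scale * pink_noise(total)
      }
    }

    topo <- erp$channel_topography
    if (is.null(topo)) topo <- channel_topography_for(cfg$channel_names)
    stopifnot(length(topo) == N)
    bump <- p300_bump(erp, cfg$fs, M)
    is_target <- codes == attended[blocks]
    if (erp$p300_amplitude > 0) {
      for (i in which(is_target)) {
        idx <- (onsets[i] + 1):(onsets[i] + M)
        samples[, idx] <- samples[, idx] + topo %o% bump
      }
    }

    rec <- continuous_recording(
      samples, cfg$fs, cfg$channel_names,
      events = data.frame(onset = onsets, code = codes,
                          is_target = is_target, block = blocks)
    )
    rec$attended_sequence <- attended
    rec
  })
}

#' Simulate labelled oddball epochs directly
#'
#' Emits the epoch set that [extract_epochs()] applied to
#' [simulate_session()] would produce, but without synthesising the
#' continuous background — each epoch gets independent noise, so the result
#' matches the session route statistically only when epochs do not overlap.
#' Used for fast unit-level work where the continuous timeline is
#' irrelevant.
#'
#' @inheritParams simulate_session
#' @return An [epoch_set()]; the attended command of each block is
#'   recoverable as the code of the block's target trials (see
#'   [attended_commands()]).
#' @export
simulate_epochs <- function(cfg, erp = erp_model(), seed = erp$seed) {
  stopifnot(inherits(cfg, "paradigm_config"), inherits(erp, "erp_model"))
  with_seed(seed, {
    M <- round(cfg$fs)
    N <- cfg$n_channels
    attended <- cfg$attended_sequence
    if (is.null(attended)) {
      attended <- sample.int(cfg$K, cfg$n_blocks, replace = TRUE)
    }
    codes <- sample_codes(cfg)
    blocks <- rep(seq_len(cfg$n_blocks),
                  each = cfg$K * cfg$reps_per_command)
    n <- length(codes)
    is_target <- codes == attended[blocks]

    topo <- erp$channel_topography
    if (is.null(topo)) topo <- channel_topography_for(cfg$channel_names)
    stopifnot(length(topo) == N)
    bump <- topo %o% p300_bump(erp, cfg$fs, M)

    epochs <- array(0, dim = c(n, N, M))
    for (i in seq_len(n)) {
      e <- noise_epoch(erp, N, M)
      if (is_target[i] && erp$p300_amplitude > 0) e <- e + bump
      epochs[i, , ] <- e
    }
    epoch_set(epochs, cfg$fs,
              labels = ifelse(is_target, 1L, 2L),
              stimulus_codes = codes, block_ids = blocks,
              channel_names = cfg$channel_names)
  })
}

#' Attended command of each selection block
#'
#' Recovers the per-block target command of an oddball epoch set from its
#' labels: within a block, the attended command is the stimulus code of the
#' target trials.
#'
#' @param epochs An [epoch_set()] with block structure.
#' @return Named integer vector, one attended command per block.
#' @export
attended_commands <- function(epochs) {
  blocks <- sort(unique(epochs$block_ids))
  att <- vapply(blocks, function(b) {
    a <- unique(epochs$stimulus_codes[epochs$labels == 1L &
                                        epochs$block_ids == b])
    if (length(a) != 1) {
      stop(sprintf("block %d has %d distinct target codes; expected 1",
                   b, length(a)))
    }
    a
  }, integer(1))
  names(att) <- blocks
  att
}
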