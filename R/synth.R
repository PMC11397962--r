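#' Default channel-by-phase synergy gain matrix
#'
#' Builds a structured non-negative gain matrix in which each gait phase
#' preferentially drives a subset of channels: channel `c` is primarily
#' recruited by phase `(c - 1) mod n_phases` and secondarily (at 40% of the
#' primary weight) by the phase two steps ahead, on top of a constant
#' baseline tone. `contrast` scales the phase-specific structure; at
#' `contrast = 0` all phases drive all channels identically and the phase
#' label carries no amplitude information.
#'
#' @param n_channels,n_phases Matrix dimensions.
#' @param contrast Non-negative scale of the phase-specific pattern.
#' @param baseline Gain common to all channel/phase pairs (default 0.2).
#' @return `n_channels x n_phases` non-negative matrix.
#' @export
synergy_gain_matrix <- function(n_channels = 9, n_phases = 5,
                                contrast = 1, baseline = 0.2) {
  stopifnot(contrast >= 0, baseline >= 0, n_phases >= 2, n_channels >= 1)
  ch <- seq_len(n_channels) - 1L
  G <- matrix(baseline, n_channels, n_phases)
  for (p in seq_len(n_phases) - 1L) {
    G[ch %% n_phases == p, p + 1L] <- G[ch %% n_phases == p, p + 1L] + contrast
    G[(ch + 2L) %% n_phases == p, p + 1L] <-
      G[(ch + 2L) %% n_phases == p, p + 1L] + 0.4 * contrast
  }
  dimnames(G) <- list(paste0("ch", ch), paste0("phase", seq_len(n_phases) - 1L))
  G
}

#' Configuration for the synthetic gait EMG generator
#'
#' The generator emulates a lower-limb gait recording: `n_channels` surface
#' EMG channels sampled at `fs` Hz, with each gait cycle walking through
#' `n_phases` phases (default five: heel strike, flat foot, mid-stance,
#' heel-off, toe-off) of unbalanced mean durations. Each channel carries
#' band-limited Gaussian noise (the EMG "carrier", band `carrier_band`)
#' whose amplitude envelope is gated by the active phase through the
#' channel-by-phase `synergy_gains` matrix, with a raised-cosine crossfade
#' of `crossfade_ms` at phase transitions and additive white sensor noise
#' of standard deviation `noise_std`.
#'
#' @param n_channels Number of EMG channels (default 9 leg muscles).
#' @param n_phases Number of gait phases per cycle (default 5).
#' @param fs Sampling rate, Hz (default 1920).
#' @param phase_durations_ms Mean duration of each phase in ms; the default
#'   `c(100, 150, 250, 200, 300)` (1 s cycle) is deliberately unbalanced,
#'   as gait phases are.
#' @param duration_jitter Relative jitter fraction applied uniformly per
#'   cycle and phase (default 0.1).
#' @param synergy_gains Non-negative `n_channels x n_phases` envelope gain
#'   matrix; default [synergy_gain_matrix()] at `contrast = 1`.
#' @param carrier_band Carrier band edges in Hz (default 20--350, inside
#'   the usual 10--400 Hz surface-EMG band).
#' @param noise_std Additive sensor noise standard deviation, signal units.
#' @param n_cycles Gait cycles per trial (default 1; one trial models one
#'   recorded gait cycle).
#' @param n_trials Trials per synthetic subject (default 10).
#' @param subject_sigma Log-normal sigma of the per-subject multiplicative
#'   perturbation of `synergy_gains` (default 0.1).
#' @param crossfade_ms Raised-cosine envelope crossfade at transitions.
#' @param seed Integer RNG seed; all generation is deterministic given it.
#' @return A validated object of class `synth_config`.
#' @export
synth_config <- function(n_channels = 9, n_phases = 5, fs = 1920,
                         phase_durations_ms = c(100, 150, 250, 200, 300),
                         duration_jitter = 0.1,
                         synergy_gains = NULL,
                         carrier_band = c(20, 350),
                         noise_std = 0.05,
                         n_cycles = 1, n_trials = 10,
                         subject_sigma = 0.1,
                         crossfade_ms = 10,
                         seed = 1234L) {
  if (is.null(synergy_gains))
    synergy_gains <- synergy_gain_matrix(n_channels, n_phases)
  cfg <- structure(list(
    n_channels = as.integer(n_channels), n_phases = as.integer(n_phases),
    fs = fs, phase_durations_ms = phase_durations_ms,
    duration_jitter = duration_jitter, synergy_gains = synergy_gains,
    carrier_band = carrier_band, noise_std = noise_std,
    n_cycles = as.integer(n_cycles), n_trials = as.integer(n_trials),
    subject_sigma = subject_sigma, crossfade_ms = crossfade_ms,
    seed = as.integer(seed)), class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  if (cfg$n_phases < 2) stop("n_phases must be >= 2")
  if (length(cfg$phase_durations_ms) != cfg$n_phases)
    stop("phase_durations_ms must have one entry per phase")
  if (any(cfg$phase_durations_ms <= 0)) stop("all phase durations must be > 0")
  if (any(cfg$synergy_gains < 0)) stop("synergy gains must be >= 0")
  if (!all(dim(cfg$synergy_gains) == c(cfg$n_channels, cfg$n_phases)))
    stop("synergy_gains must be n_channels x n_phases")
  if (!(cfg$carrier_band[1] > 0 && cfg$carrier_band[2] > cfg$carrier_band[1] &&
        cfg$carrier_band[2] < cfg$fs / 2))
    stop("carrier_band must lie inside (0, fs/2)")
  if (cfg$noise_std < 0) stop("noise_std must be >= 0")
  if (cfg$duration_jitter < 0 || cfg$duration_jitter >= 1)
    stop("duration_jitter must be in [0, 1)")
  if (cfg$n_cycles < 1 || cfg$n_trials < 1) stop("n_cycles, n_trials >= 1")
  invisible(cfg)
}

#' Labeled multichannel EMG recording for one trial
#'
#' @param samples `channels x time` numeric matrix.
#' @param fs Sampling rate, Hz.
#' @param labels Integer per-sample phase id in `[0, n_phases)`, length
#'   equal to the time dimension.
#' @param trial_id,subject_id Identifiers.
#' @param channel_names Optional channel names (default `ch0..`).
#' @return Object of class `emg_recording`.
#' @export
emg_recording <- function(samples, fs, labels, trial_id, subject_id,
                          channel_names = NULL) {
  samples <- as.matrix(samples)
  if (length(labels) != ncol(samples))
    stop("labels length must equal the time dimension")
  if (anyNA(samples)) stop("samples contain missing values")
  if (!(fs > 0)) stop("fs must be > 0")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(samples)) - 1L)
  rownames(samples) <- channel_names
  structure(list(samples = samples, fs = fs, labels = as.integer(labels),
                 trial_id = trial_id, subject_id = subject_id,
                 channel_names = channel_names),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %s / %s: %d channels x %d samples @ %g Hz, %d phases\n",
              x$subject_id, x$trial_id, nrow(x$samples), ncol(x$samples),
              x$fs, length(unique(x$labels))))
  invisible(x)
}

# deterministic per-(seed, subject, trial) substream seed, kept < 2^31
.stream_seed <- function(seed, subject, trial) {
  as.integer((abs(seed) %% 65011 * 100003 + subject * 10007 + trial * 101) %%
               2147483647)
}

.phase_label_track <- function(cfg) {
  # per-cycle jittered phase durations -> per-sample 0-based labels
  labs <- integer(0)
  for (cy in seq_len(cfg$n_cycles)) {
    jit <- if (cfg$duration_jitter > 0)
      stats::runif(cfg$n_phases, -cfg$duration_jitter, cfg$duration_jitter)
    else rep(0, cfg$n_phases)
    dur <- cfg$phase_durations_ms * (1 + jit)
    nsamp <- pmax(1L, as.integer(round(dur * cfg$fs / 1000)))
    labs <- c(labs, rep(seq_len(cfg$n_phases) - 1L, times = nsamp))
  }
  labs
}

.smooth_gain <- function(g, fs, crossfade_ms) {
  # raised-cosine (Hann) smoothing of the piecewise-constant gain track;
  # within-phase values are untouched because the kernel sums to one
  w <- max(1L, as.integer(round(crossfade_ms * fs / 1000)))
  if (w < 3) return(g)
  kern <- 0.5 * (1 - cos(2 * pi * seq_len(w) / (w + 1)))
  kern <- kern / sum(kern)
  n <- length(g)
  pad <- (w %/% 2) + 1L
  ext <- c(rep(g[1], pad), g, rep(g[n], pad))
  sm <- as.numeric(stats::filter(ext, kern, method = "convolution", sides = 2))
  sm[(pad + 1):(pad + n)]
}

#' Generate one synthetic gait EMG trial
#'
#' Per channel, band-limited Gaussian carrier noise (filtered with the same
#' zero-lag Butterworth family used by [bandpass_filter()]) is multiplied by
#' the phase-gated envelope from `cfg$synergy_gains` (raised-cosine
#' crossfades at transitions) and white sensor noise of sd `cfg$noise_std`
#' is added. Output is bit-reproducible given `(cfg$seed, subject, trial)`.
#'
#' @param cfg A [synth_config()].
#' @param trial,subject Positive integer indices used for the RNG substream
#'   and the generated ids.
#' @param gains Optional override of the synergy gain matrix (used by
#'   [generate_dataset()] for per-subject perturbation).
#' @return An [emg_recording()].
#' @export
generate_trial <- function(cfg, trial = 1L, subject = 1L, gains = NULL) {
  validate_synth_config(cfg)
  if (is.null(gains)) gains <- cfg$synergy_gains
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(.stream_seed(cfg$seed, subject, trial))

  labels <- .phase_label_track(cfg)
  T_len <- length(labels)
  bt <- butter_bandpass(4, cfg$carrier_band[1], cfg$carrier_band[2], cfg$fs)
  padlen <- max(30 * (length(bt$a) - 1),
                ceiling(3 * cfg$fs / cfg$carrier_band[1]))
  samples <- matrix(0, cfg$n_channels, T_len)
  for (c in seq_len(cfg$n_channels)) {
    gain_track <- .smooth_gain(gains[c, labels + 1L], cfg$fs, cfg$crossfade_ms)
    if (all(gains[c, ] == 0)) {
      sig <- numeric(T_len)
      # keep RNG stream aligned with the generic path
      stats::rnorm(T_len)
    } else {
      carrier <- filtfilt_emg(bt$b, bt$a, stats::rnorm(T_len), padlen = padlen)
      sig <- carrier * gain_track
    }
    if (cfg$noise_std > 0) sig <- sig + stats::rnorm(T_len, 0, cfg$noise_std)
    else stats::rnorm(T_len)
    samples[c, ] <- sig
  }
  emg_recording(samples, cfg$fs, labels,
                trial_id = sprintf("T%02d", trial),
                subject_id = sprintf("S%02d", subject))
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic multi-subject gait EMG dataset
#'
#' Each subject's synergy gain matrix is the configured one perturbed
#' multiplicatively by log-normal noise (`cfg$subject_sigma`), drawn from a
#' subject-specific deterministic RNG substream, so subjects differ but the
#' whole dataset is reproducible from `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @param n_subjects Number of synthetic subjects (default 1).
#' @return A list of [emg_recording()]s, `n_subjects * cfg$n_trials` long.
#' @export
generate_dataset <- function(cfg, n_subjects = 1L) {
  validate_synth_config(cfg)
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old), add = TRUE)
  recs <- list()
  for (s in seq_len(n_subjects)) {
    set.seed(.stream_seed(cfg$seed, s, 0L))
    # per-channel multiplicative perturbation (electrode gain / impedance
    # variability); deliberately not per channel-by-phase so a zero-contrast
    # gain matrix still carries no phase information after perturbation
    gains <- cfg$synergy_gains *
      exp(stats::rnorm(cfg$n_channels, 0, cfg$subject_sigma))
    for (tr in seq_len(cfg$n_trials))
      recs[[length(recs) + 1L]] <- generate_trial(cfg, tr, s, gains = gains)
  }
  recs
}

#' Write / read synthetic trials as delimited text
#'
#' One CSV per trial with columns `ch0..chN-1,label` plus a dataset-level
#' YAML sidecar (`dataset.yaml`) holding the sampling rate, channel names
#' and phase names.
#'
#' @param recs List of [emg_recording()]s.
#' @param dir Output directory (created if needed).
#' @param phase_names Phase names for the sidecar; default the five gait
#'   phases HS/FF/MS/HO/TO (truncated or extended as needed).
#' @return `write_dataset`: invisibly, the written file paths.
#' @export
write_dataset <- function(recs, dir,
                          phase_names = c("HS", "FF", "MS", "HO", "TO")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_phases <- max(vapply(recs, function(r) max(r$labels), integer(1))) + 1L
  if (length(phase_names) < n_phases)
    phase_names <- c(phase_names,
                     paste0("P", seq.int(length(phase_names), n_phases - 1L)))
  files <- character(0)
  for (r in recs) {
    df <- as.data.frame(t(r$samples))
    names(df) <- r$channel_names
    df$label <- r$labels
    f <- file.path(dir, sprintf("%s_%s.csv", r$subject_id, r$trial_id))
    utils::write.csv(df, f, row.names = FALSE)
    files <- c(files, f)
  }
  yaml::write_yaml(list(fs = recs[[1]]$fs,
                        channel_names = recs[[1]]$channel_names,
                        phase_names = phase_names[seq_len(n_phases)]),
                   file.path(dir, "dataset.yaml"))
  invisible(files)
}

#' @rdname write_dataset
#' @param path Path of one trial CSV; its directory must hold `dataset.yaml`.
#' @return `read_trial`: one [emg_recording()].
#' @export
read_trial <- function(path) {
  meta <- yaml::read_yaml(file.path(dirname(path), "dataset.yaml"))
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- strsplit(sub("\\.csv$", "", basename(path)), "_")[[1]]
  emg_recording(t(as.matrix(df[meta$channel_names])), meta$fs, df$label,
                trial_id = ids[2], subject_id = ids[1],
                channel_names = meta$channel_names)
}

#' @rdname write_dataset
#' @return `read_dataset`: list of [emg_recording()]s, sorted by file name.
#' @export
read_dataset <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  lapply(files, read_trial)
}
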