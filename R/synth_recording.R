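#' Construct a move/rest cue schedule
#'
#' @param start,end epoch boundaries in seconds (vectors of equal length).
#' @param label `"MOVE"` or `"REST"` per epoch.
#' @return an `epoch_schedule` data.frame with columns `start`, `end`,
#'   `label`; epochs must be ordered, non-overlapping and alternating.
#' @export
epoch_schedule <- function(start, end, label) {
  stopifnot(length(start) == length(end), length(start) == length(label))
  if (any(end <= start)) stop("epochs must have positive duration")
  if (any(start[-1] < end[-length(end)] - 1e-12))
    stop("epochs overlap or are out of order")
  if (!all(label %in% c("MOVE", "REST"))) stop("labels must be MOVE or REST")
  if (length(label) > 1 && any(label[-1] == label[-length(label)]))
    stop("labels must alternate")
  structure(data.frame(start = start, end = end, label = label),
            class = c("epoch_schedule", "data.frame"))
}

#' The standard cued motor test schedule
#'
#' Ten repetitions of 10 s attempted movement followed by 10 s rest
#' (200 s total), the block structure of the cued Motor Signal Test.
#'
#' @param n_reps number of move/rest repetitions.
#' @param move_s,rest_s epoch durations in seconds.
#' @return an `epoch_schedule`.
#' @export
motor_test_schedule <- function(n_reps = 10, move_s = 10, rest_s = 10) {
  cycle <- move_s + rest_s
  start <- as.vector(rbind((seq_len(n_reps) - 1) * cycle,
                           (seq_len(n_reps) - 1) * cycle + move_s))
  end <- start + rep(c(move_s, rest_s), n_reps)
  epoch_schedule(start, end, rep(c("MOVE", "REST"), n_reps))
}

# Spectral gain of 1/f ("pink") noise with a white floor (memoised,
# normalised to unit RMS gain so the synthesised noise has expected unit
# variance).
pink_gain <- function(n, alpha = 1, white_floor = 0.3) {
  key <- paste("pink", n, alpha, white_floor, sep = ",")
  hit <- .gain_cache[[key]]
  if (!is.null(hit)) return(hit)
  k <- 0:(n - 1L)
  fk <- pmin(k, n - k)
  fk[1] <- 1
  gain <- 1 / fk^(alpha / 2) + white_floor
  gain[1] <- 0 # no DC
  gain <- gain / sqrt(mean(gain^2))
  .gain_cache[[key]] <- gain
  gain
}

# n-by-nc matrix of pink noise with (expected) unit variance, via spectral
# shaping of white Gaussian noise (two real channels per complex FFT).
# Realised channel variances fluctuate around 1 as real noise does.
pink_noise <- function(n, nc = 1L, alpha = 1, white_floor = 0.3) {
  x <- rnorm(n * nc)
  dim(x) <- c(n, nc)
  apply_dft_gain(x, pink_gain(n, alpha, white_floor))
}

# Gaussian-windowed tone burst waveform.
burst_waveform <- function(fs, duration, freq, amplitude) {
  t <- seq(0, duration, by = 1 / fs)
  win <- exp(-(t - duration / 2)^2 / (2 * (duration / 6)^2))
  amplitude * win * sin(2 * pi * freq * t)
}

#' Construct a recording object
#'
#' @param signal samples-by-channels numeric matrix (microvolts).
#' @param fs sampling rate in Hz; must exceed 400 Hz (twice the 200 Hz
#'   band edge used by the high-gamma analysis).
#' @param active logical vector marking channels with a live connection.
#' @param burst_truth optional list of planted burst onset times per channel.
#' @return a `recording`.
#' @export
recording <- function(signal, fs, active = rep(TRUE, ncol(signal)),
                      burst_truth = NULL) {
  signal <- cbind(signal)
  if (fs <= 400) stop("sampling rate must exceed 400 Hz")
  if (length(active) != ncol(signal)) stop("active mask length != channels")
  structure(list(
    signal = signal, fs = fs, active = as.logical(active),
    duration = nrow(signal) / fs, burst_truth = burst_truth
  ), class = "recording")
}

#' Generate a synthetic multichannel recording with planted bursts
#'
#' Background is pink (1/f) noise with a white floor on every channel. On
#' active channels, band-limited burst events (Gaussian-windowed 150 Hz
#' tones by default) are inserted at Poisson-process times, at
#' `rest_burst_rate` during REST epochs and `move_burst_rate` during MOVE
#' epochs. Inactive channels carry noise only. Planted burst onset times
#' are returned as ground truth alongside the signal.
#'
#' @param schedule an `epoch_schedule`.
#' @param n_channels,n_active total and active channel counts.
#' @param fs sampling rate (Hz, > 400).
#' @param rest_burst_rate,move_burst_rate per-channel burst rates (/s, >= 0).
#' @param burst_params list: `duration` (s), `freq` (Hz), `amp_snr`
#'   (burst amplitude as a multiple of the in-band noise SD).
#' @param noise_params list: `alpha` (spectral slope), `white_floor`,
#'   `scale_uv` (broadband noise SD in microvolts).
#' @param seed integer seed.
#' @return a `recording` with `$burst_truth` (onsets per channel) and
#'   planted rates stored in `$truth_rates`.
#' @export
generate_recording <- function(schedule, n_channels = 16,
                               n_active = n_channels,
                               fs = 1000, rest_burst_rate = 0.5,
                               move_burst_rate = 3,
                               burst_params = list(duration = 0.08,
                                                   freq = 150, amp_snr = 5),
                               noise_params = list(alpha = 1,
                                                   white_floor = 0.3,
                                                   scale_uv = 10),
                               seed = 1L) {
  if (n_active > n_channels) stop("n_active > n_channels")
  if (move_burst_rate < 0 || rest_burst_rate < 0) stop("rates must be >= 0")
  stopifnot(inherits(schedule, "epoch_schedule"))
  set.seed(child_seed(seed, 23L))
  duration <- max(schedule$end)
  n <- round(duration * fs)
  scale_uv <- noise_params$scale_uv %||% 10

  alpha <- noise_params$alpha %||% 1
  floor_ <- noise_params$white_floor %||% 0.3
  sig <- scale_uv * pink_noise(n, n_channels, alpha, floor_)

  # analytic in-band noise SD (noise gain times squared-Butterworth gain)
  # sets the burst amplitude
  pg <- pink_gain(n, alpha, floor_)
  bg <- dft_power_gain(butter_highgamma(fs), n)
  inband_sd <- scale_uv * sqrt(mean((pg * bg)^2))
  wave <- burst_waveform(fs, burst_params$duration %||% 0.08,
                         burst_params$freq %||% 150,
                         (burst_params$amp_snr %||% 5) * inband_sd)
  lw <- length(wave)

  truth <- vector("list", n_channels)
  for (ch in seq_len(n_channels)) truth[[ch]] <- numeric(0)
  for (ch in seq_len(n_active)) {
    onsets <- numeric(0)
    for (e in seq_len(nrow(schedule))) {
      rate <- if (schedule$label[e] == "MOVE") move_burst_rate else rest_burst_rate
      dur <- schedule$end[e] - schedule$start[e]
      k <- rpois(1, rate * dur)
      if (k > 0) onsets <- c(onsets, sort(runif(k, schedule$start[e],
                                                schedule$end[e])))
    }
    for (on in onsets) {
      i0 <- floor(on * fs) + 1L
      idx <- i0:min(i0 + lw - 1L, n)
      sig[idx, ch] <- sig[idx, ch] + wave[seq_along(idx)]
    }
    truth[[ch]] <- onsets
  }

  rec <- recording(sig, fs,
                   active = seq_len(n_channels) <= n_active,
                   burst_truth = truth)
  rec$truth_rates <- c(move = move_burst_rate, rest = rest_burst_rate)
  rec
}

#' Generate a unimodal per-slice activity profile
#'
#' Gaussian bump over slice indices plus truncated Gaussian noise
#' (activity is clamped at zero), standing in for the mean movement-related
#' fMRI activity per coronal slice along the dorsal strip.
#'
#' @param n_slices number of slices.
#' @param peak_slice 0-based index of the bump centre (`0 <= peak < n`).
#' @param spread bump SD in slices (>= 0; 0 puts all mass in one slice).
#' @param noise_sd additive noise SD before clamping.
#' @param amplitude bump height.
#' @param seed integer seed.
#' @return a `slice_profile` data.frame with columns `slice` (0-based) and
#'   `activity` (>= 0).
#' @export
generate_slice_profile <- function(n_slices, peak_slice, spread = 3,
                                   noise_sd = 0.1, amplitude = 1,
                                   seed = 1L) {
  if (spread < 0) stop("spread must be >= 0")
  if (peak_slice < 0 || peak_slice >= n_slices)
    stop("peak_slice must be in [0, n_slices)")
  set.seed(child_seed(seed, 31L))
  i <- seq_len(n_slices) - 1L
  bump <- if (spread == 0) as.numeric(i == round(peak_slice)) * amplitude
          else amplitude * exp(-(i - peak_slice)^2 / (2 * spread^2))
  act <- pmax(bump + rnorm(n_slices, 0, noise_sd), 0)
  structure(data.frame(slice = i, activity = act),
            class = c("slice_profile", "data.frame"))
}
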