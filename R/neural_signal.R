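# Butterworth band-pass used for high-gamma isolation; applied zero-phase,
# so the effective magnitude response is |H|^2.
butter_highgamma <- function(fs, band = c(100, 200), order = 4) {
  signal::butter(order, band / (fs / 2), type = "pass")
}

# Squared magnitude response |H|^2 of an ARMA filter at the n DFT
# frequencies (vectorised Horner evaluation of b(z)/a(z) at z = e^{-iw}).
# Memoised: the same filter/length pair recurs for every block of a cohort.
.gain_cache <- new.env(parent = emptyenv())
dft_power_gain <- function(bf, n) {
  key <- paste(c(n, signif(c(bf$b, bf$a), 12)), collapse = ",")
  hit <- .gain_cache[[key]]
  if (!is.null(hit)) return(hit)
  w <- 2 * pi * (0:(n - 1)) / n
  z <- exp(complex(imaginary = -w))
  horner <- function(cf) {
    acc <- rep(cf[1] + 0i, n)
    for (c in cf[-1]) acc <- acc * z + c
    acc
  }
  out <- Mod(horner(bf$b) / horner(bf$a))^2
  .gain_cache[[key]] <- out
  out
}

# Apply a real, even DFT gain to every column of x, zero-phase; pairs of
# real channels are packed into complex columns and transformed in one
# batched mvfft call.
apply_dft_gain <- function(x, gain) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  n <- nrow(x); nc <- ncol(x)
  odd <- seq(1L, nc, by = 2L)
  even <- seq_len(nc)[-odd]
  xe <- x[, even, drop = FALSE]
  if (length(even) < length(odd)) xe <- cbind(xe, 0)
  z <- matrix(complex(real = as.vector(x[, odd, drop = FALSE]),
                      imaginary = as.vector(xe)), n)
  y <- stats::mvfft(stats::mvfft(z) * gain, inverse = TRUE) / n
  out <- matrix(0, n, nc)
  out[, odd] <- Re(y)
  if (length(even) > 0)
    out[, even] <- Im(y)[, seq_along(even), drop = FALSE]
  out
}

#' Isolate the high-gamma band of a recording
#'
#' Applies a zero-phase Butterworth band-pass (default 100-200 Hz, the
#' high-gamma range carrying the movement-related signal) to every
#' channel. The filter is applied in the frequency domain with the squared
#' Butterworth magnitude response (the zero-phase equivalent of a
#' forward-backward pass), so phase is exactly preserved.
#'
#' @param rec a `recording`.
#' @param band length-2 numeric, pass band in Hz.
#' @param order Butterworth order (the zero-phase magnitude response is
#'   this order squared).
#' @return a `recording` with filtered signal; the band is stored in
#'   `$band`.
#' @export
bandpass_highgamma <- function(rec, band = c(100, 200), order = 4) {
  stopifnot(inherits(rec, "recording"))
  if (diff(band) <= 0) stop("band is degenerate")
  if (rec$fs <= 2 * band[2])
    stop("sampling rate too low for requested band (need fs > 2 * upper edge)")
  bf <- butter_highgamma(rec$fs, band, order)
  gain <- dft_power_gain(bf, nrow(rec$signal))
  out <- rec
  out$signal <- apply_dft_gain(rec$signal, gain)
  out$band <- band
  out
}

#' Detect high-gamma bursts per channel
#'
#' Computes a smoothed envelope (moving RMS) per channel and marks
#' excursions above `median + threshold_k * robust SD` of the baseline
#' envelope as bursts. Excursions separated by less than `merge_gap` are
#' merged; merged excursions shorter than `min_duration` are discarded.
#' The baseline is given as a logical sample mask (typically the
#' concatenated REST epochs of the same block, see
#' [rest_mask_from_schedule()]); the robust SD is `1.4826 * MAD`.
#'
#' @param rec a band-passed `recording`.
#' @param baseline logical vector over samples marking baseline data.
#' @param threshold_k threshold height in robust SDs above the baseline
#'   median (> 0).
#' @param min_duration minimum burst duration (s).
#' @param merge_gap maximum gap between excursions that are merged (s).
#' @param smooth_window envelope moving-RMS window (s).
#' @return a `burst_series`: list with per-channel `onsets` and `durations`
#'   (seconds), plus `fs`, `duration` and a per-channel `degenerate` flag
#'   (constant signal, robust SD zero).
#' @export
detect_bursts <- function(rec, baseline, threshold_k = 3,
                          min_duration = 0.02, merge_gap = 0.01,
                          smooth_window = 0.02) {
  stopifnot(inherits(rec, "recording"))
  if (threshold_k <= 0) stop("threshold_k must be > 0")
  baseline <- as.logical(baseline)
  if (length(baseline) != nrow(rec$signal))
    stop("baseline mask length != number of samples")
  if (!any(baseline)) stop("baseline is empty")
  fs <- rec$fs
  w <- max(1L, round(smooth_window * fs))
  min_n <- max(1L, round(min_duration * fs))
  gap_n <- round(merge_gap * fs)

  n_ch <- ncol(rec$signal)
  onsets <- durations <- vector("list", n_ch)
  degenerate <- logical(n_ch)
  # the envelope is smooth over the RMS window, so baseline quantiles are
  # estimated on a half-window stride of the baseline samples
  base_idx <- which(baseline)
  stride <- max(1L, w %/% 2L)
  if (length(base_idx) > 10L * stride)
    base_idx <- base_idx[seq(1L, length(base_idx), by = stride)]
  for (ch in seq_len(n_ch)) {
    env <- moving_rms(rec$signal[, ch], w)
    base <- env[base_idx]
    rsd <- mad(base)
    if (rsd == 0) {
      degenerate[ch] <- TRUE
      onsets[[ch]] <- numeric(0)
      durations[[ch]] <- numeric(0)
      next
    }
    thr <- median(base) + threshold_k * rsd
    above <- env > thr
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- cbind(starts[r$values], ends[r$values])
    if (nrow(runs) > 1L && gap_n > 0L) {
      # merge excursions separated by short sub-threshold gaps
      keep <- list(runs[1L, ])
      for (i in 2L:nrow(runs)) {
        last <- keep[[length(keep)]]
        if (runs[i, 1] - last[2] - 1L < gap_n)
          keep[[length(keep)]] <- c(last[1], runs[i, 2])
        else keep[[length(keep) + 1L]] <- runs[i, ]
      }
      runs <- do.call(rbind, keep)
    }
    if (nrow(runs) > 0L) {
      len <- runs[, 2] - runs[, 1] + 1L
      runs <- runs[len >= min_n, , drop = FALSE]
    }
    onsets[[ch]] <- (runs[, 1] - 1L) / fs
    durations[[ch]] <- (runs[, 2] - runs[, 1] + 1L) / fs
  }
  structure(list(onsets = onsets, durations = durations, fs = fs,
                 duration = rec$duration, degenerate = degenerate),
            class = "burst_series")
}

#' Logical sample mask of REST epochs
#' @param schedule an `epoch_schedule`
#' @param fs sampling rate (Hz)
#' @param n_samples number of samples in the recording
#' @return logical vector of length `n_samples`
#' @export
rest_mask_from_schedule <- function(schedule, fs, n_samples) {
  key <- paste(c("mask", fs, n_samples, schedule$start, schedule$end,
                 schedule$label), collapse = ",")
  hit <- .gain_cache[[key]]
  if (!is.null(hit)) return(hit)
  # sample i covers time (i-1)/fs; epochs are half-open [start, end)
  mask <- rep(FALSE, n_samples)
  for (e in which(schedule$label == "REST")) {
    i0 <- max(1L, as.integer(ceiling(schedule$start[e] * fs + 1 - 1e-9)))
    i1 <- min(n_samples,
              as.integer(ceiling(schedule$end[e] * fs + 1 - 1e-9)) - 1L)
    if (i1 >= i0) mask[i0:i1] <- TRUE
  }
  .gain_cache[[key]] <- mask
  mask
}

#' Per-epoch burst-count densities
#'
#' Counts bursts whose onset falls inside each cue epoch (half-open
#' `[start, end)` intervals, so boundary onsets are never double counted)
#' and divides by the epoch duration. Aggregation over channels:
#' `"pooled"` sums counts over active channels before dividing, `"mean"`
#' averages per-channel densities, `"best_channel"` returns the single
#' active channel whose own d-prime is largest.
#'
#' @param bursts a `burst_series`.
#' @param schedule an `epoch_schedule` within the recording duration.
#' @param mask logical active-channel mask (default: all channels).
#' @param aggregation one of `"pooled"`, `"mean"`, `"best_channel"`.
#' @return list with numeric vectors `move` and `rest` (bursts/s, one
#'   entry per epoch) and the `aggregation` used.
#' @export
epoch_densities <- function(bursts, schedule,
                            mask = rep(TRUE, length(bursts$onsets)),
                            aggregation = c("pooled", "mean",
                                            "best_channel")) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(bursts, "burst_series"))
  mask <- as.logical(mask)
  if (!any(mask)) stop("need at least one active channel")
  dur <- schedule$end - schedule$start
  if (any(dur <= 0)) stop("zero-duration epoch")
  if (max(schedule$end) > bursts$duration + 1e-9)
    stop("schedule extends beyond recording duration")
  chans <- which(mask)
  # epochs x channels count matrix (onset-membership, half-open intervals)
  counts <- sapply(chans, function(ch) {
    on <- bursts$onsets[[ch]]
    vapply(seq_len(nrow(schedule)), function(e)
      sum(on >= schedule$start[e] & on < schedule$end[e]), numeric(1))
  })
  counts <- matrix(counts, nrow = nrow(schedule))
  move <- schedule$label == "MOVE"
  density_of <- function(cnt) cnt / dur
  pick <- function(d) list(move = d[move], rest = d[!move])
  out <- switch(aggregation,
    pooled = pick(density_of(rowSums(counts))),
    mean = pick(rowMeans(apply(counts, 2L, density_of))),
    best_channel = {
      ds <- apply(counts, 2L, function(cnt) {
        d <- density_of(cnt)
        sensitivity_index(d[move], d[!move])
      })
      ds[!is.finite(ds)] <- -Inf
      best <- which.max(ds)
      d <- density_of(counts[, best])
      c(pick(d), list(channel = chans[best]))
    })
  out$aggregation <- aggregation
  out
}

#' Sensitivity index (d-prime) between move and rest densities
#'
#' `d' = (mean(move) - mean(rest)) / sqrt((var(move) + var(rest)) / 2)`
#' with n-1 sample variances. If both variances are zero the index is 0
#' when the means agree and signed infinity (flagged degenerate) when they
#' differ.
#'
#' @param move,rest numeric vectors of per-epoch burst densities
#'   (>= 2 values each).
#' @return the index (numeric scalar), with attribute `degenerate = TRUE`
#'   on the zero-variance, unequal-means case.
#' @export
sensitivity_index <- function(move, rest) {
  if (length(move) < 2 || length(rest) < 2)
    stop("need >= 2 epochs per condition")
  pooled <- (var(move) + var(rest)) / 2
  dm <- mean(move) - mean(rest)
  if (pooled == 0) {
    if (dm == 0) return(0)
    return(structure(sign(dm) * Inf, degenerate = TRUE))
  }
  dm / sqrt(pooled)
}

#' Default configuration of the motor signal strength computation
#' @return list of parameters consumed by [block_signal_strength()]
#' @export
signal_config <- function() {
  list(band = c(100, 200), threshold_k = 3, min_duration = 0.02,
       merge_gap = 0.01, smooth_window = 0.02, aggregation = "pooled")
}

#' Motor signal strength of one test block
#'
#' Chains the full per-block computation: high-gamma band-pass, envelope
#' burst detection against the block's own REST baseline, per-epoch
#' move/rest burst densities aggregated over active channels, and the
#' sensitivity index.
#'
#' @param rec a raw `recording`.
#' @param schedule the block's `epoch_schedule`.
#' @param config parameter list, see [signal_config()].
#' @return a `signal_strength_result`: list with `dprime`, `move` and
#'   `rest` densities, `aggregation`, the `burst_series`, and a
#'   `degenerate` flag.
#' @export
block_signal_strength <- function(rec, schedule, config = signal_config()) {
  # only active channels enter the densities; restrict the per-sample work
  sub <- rec
  sub$signal <- rec$signal[, rec$active, drop = FALSE]
  sub$active <- rec$active[rec$active]
  filt <- bandpass_highgamma(sub, config$band)
  baseline <- rest_mask_from_schedule(schedule, rec$fs, nrow(rec$signal))
  bursts <- detect_bursts(filt, baseline,
                          threshold_k = config$threshold_k,
                          min_duration = config$min_duration,
                          merge_gap = config$merge_gap,
                          smooth_window = config$smooth_window)
  dens <- epoch_densities(bursts, schedule, mask = sub$active,
                          aggregation = config$aggregation)
  dp <- sensitivity_index(dens$move, dens$rest)
  structure(list(
    dprime = as.numeric(dp), move = dens$move, rest = dens$rest,
    aggregation = dens$aggregation, bursts = bursts,
    degenerate = isTRUE(attr(dp, "degenerate"))
  ), class = "signal_strength_result")
}

#' Best signal strength over all blocks of all sessions
#'
#' The per-participant summary value is the maximum d-prime over every test
#' block of every session; on ties the earliest session is reported.
#'
#' @param blocks data.frame with columns `session` and `dprime`
#'   (one row per block).
#' @return list with `best` (the value) and `session`.
#' @export
best_session_strength <- function(blocks) {
  if (nrow(blocks) == 0) stop("no blocks supplied")
  best <- max(blocks$dprime)
  sessions <- blocks$session[blocks$dprime == best]
  list(best = best, session = min(sessions))
}

#' Wilcoxon signed-rank test of session strengths against zero
#'
#' Exact two-sided test of the per-session signal strength values against
#' zero. Zero values are dropped before testing. Participants with fewer
#' than 5 usable sessions are refused (too few for a meaningful exact
#' test); the exact null distribution is used up to n = 25 and the normal
#' approximation beyond.
#'
#' @param values per-session signal strength values of one participant.
#' @return list with `statistic` (V), `p.value`, `n` (after dropping
#'   zeros) and `exact`.
#' @export
strength_vs_zero_test <- function(values) {
  values <- values[values != 0]
  n <- length(values)
  if (n < 5)
    stop("need >= 5 nonzero session values for the signed-rank test")
  exact <- n <= 25 && !any(duplicated(abs(values)))
  wt <- suppressWarnings(
    wilcox.test(values, mu = 0, exact = exact, correct = !exact)
  )
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       n = n, exact = exact)
}
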