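#' Detect R peaks in a reference ECG channel
#'
#' Band-passes the signal to the QRS band (5-25 Hz, zero-phase Butterworth),
#' applies an adaptive threshold at half the rolling maximum of the rectified
#' filtered signal (2-s blocks), enforces a refractory period during which
#' only the larger of two competing detections survives, and finally refines
#' each detection to the apex of the raw signal within +/- 25 ms.
#'
#' @param ecg numeric vector, at least 2 s of samples.
#' @param fs_hz sampling frequency in Hz.
#' @param refractory_ms minimum separation between detections (ms).
#' @return Strictly increasing integer sample indices; empty (with a
#'   warning) when no deflection exceeds the adaptive threshold.
#' @export
detect_r_peaks <- function(ecg, fs_hz, refractory_ms = 250) {
  n <- length(ecg)
  if (n < 2 * fs_hz) stop_invalid("need at least 2 s of ECG samples")
  bf <- signal::butter(2, c(5, 25) / (fs_hz / 2), type = "pass")
  env <- abs(signal::filtfilt(bf, ecg))

  # rolling maximum on 2-s blocks, interpolated to per-sample
  block <- max(1L, round(2 * fs_hz))
  starts <- seq(1L, n, by = block)
  bmax <- vapply(starts, function(s) max(env[s:min(s + block - 1L, n)]), 0)
  ctr <- pmin(starts + block / 2, n)
  thr <- 0.5 * if (length(bmax) > 1)
    approx(ctr, bmax, xout = seq_len(n), rule = 2)$y else rep(bmax, n)

  cand <- which(env > thr & env > 0)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[env[cand] >= env[cand - 1] & env[cand] >= env[cand + 1]]
  if (length(cand) == 0) {
    warning("no peak exceeded the adaptive threshold")
    return(integer(0))
  }

  refr <- round(refractory_ms / 1000 * fs_hz)
  keep <- integer(0)
  for (i in cand[order(env[cand], decreasing = TRUE)]) {
    if (all(abs(keep - i) >= refr)) keep <- c(keep, i)
  }
  keep <- sort(keep)

  half <- round(0.025 * fs_hz)
  vapply(keep, function(p) {
    idx <- max(1, p - half):min(n, p + half)
    idx[which.max(abs(ecg[idx]))]
  }, integer(1))
}

#' Mean QRS-T template from a reference ECG
#'
#' Aligns a window from `pre_r_ms` before to `post_r_ms` after each detected
#' R peak and averages pointwise. Beats whose window is truncated by the
#' record edges are excluded.
#'
#' @param ecg numeric vector.
#' @param peaks R-peak sample indices (from [detect_r_peaks()]).
#' @param fs_hz sampling frequency in Hz.
#' @param pre_r_ms,post_r_ms template span before/after the R peak (ms).
#' @return Object of class `qrst_template`: list with `waveform` (length
#'   `round((pre_r_ms + post_r_ms) * fs / 1000) + 1`), `pre_r_ms`,
#'   `post_r_ms`, `fs_hz` and `n_beats`.
#' @export
build_qrst_template <- function(ecg, peaks, fs_hz, pre_r_ms = 50,
                                post_r_ms = 400) {
  pre_n <- round(pre_r_ms * fs_hz / 1000)
  post_n <- round(post_r_ms * fs_hz / 1000)
  usable <- peaks[peaks - pre_n >= 1 & peaks + post_n <= length(ecg)]
  if (length(usable) < 2)
    stop(structure(class = c("afcn_insufficient_beats", "error", "condition"),
                   list(message = sprintf(
                     "need >= 2 beats fully inside the recording, got %d",
                     length(usable)), call = sys.call())))
  beats <- vapply(usable, function(p) ecg[(p - pre_n):(p + post_n)],
                  numeric(pre_n + post_n + 1))
  structure(list(waveform = rowMeans(beats), pre_r_ms = pre_r_ms,
                 post_r_ms = post_r_ms, fs_hz = fs_hz,
                 n_beats = length(usable)),
            class = "qrst_template")
}

#' Subtract the mean QRS-T complex at each beat
#'
#' Removes ventricular far-field content by subtracting the template at every
#' R peak of the simultaneous reference ECG. Samples outside all beat windows
#' are returned bit-identical. The template can be subtracted as-is
#' (`scale = "off"`), scaled once per channel by a least-squares fit pooled
#' over all beats (`"global"`, the default: basket far-field amplitude varies
#' by electrode but is stable beat to beat), or refitted per beat
#' (`"per_beat"`).
#'
#' @param x numeric vector (one channel) or samples x channels matrix.
#' @param peaks R-peak sample indices from the reference ECG.
#' @param template a `qrst_template`.
#' @param scale `"global"`, `"per_beat"` or `"off"`.
#' @param quiet suppress the log message about beats skipped at record edges.
#' @return Cleaned signal with the same dimensions as `x`.
#' @export
subtract_qrst <- function(x, peaks, template,
                          scale = c("global", "per_beat", "off"),
                          quiet = FALSE) {
  scale <- match.arg(scale)
  stopifnot(inherits(template, "qrst_template"))
  if (is.matrix(x)) {
    for (ch in seq_len(ncol(x)))
      x[, ch] <- subtract_qrst(x[, ch], peaks, template, scale,
                               quiet = quiet || ch > 1)
    return(x)
  }
  if (length(peaks) == 0) {
    warning("no R peaks supplied; signal returned unchanged")
    return(x)
  }
  w <- template$waveform
  pre_n <- round(template$pre_r_ms * template$fs_hz / 1000)
  n <- length(x)
  starts <- peaks - pre_n
  inside <- starts >= 1 & starts + length(w) - 1 <= n
  if (any(!inside) && !quiet)
    message(sum(!inside), " beat(s) truncated by record edges; skipped")
  starts <- starts[inside]
  if (length(starts) == 0) return(x)
  wtw <- sum(w * w)
  if (wtw == 0) return(x)
  idx <- lapply(starts, function(s) s:(s + length(w) - 1))
  if (scale == "global") {
    b <- mean(vapply(idx, function(i) sum(x[i] * w), 0)) / wtw
    for (i in idx) x[i] <- x[i] - b * w
  } else {
    for (i in idx) {
      b <- if (scale == "off") 1 else sum(x[i] * w) / wtw
      x[i] <- x[i] - b * w
    }
  }
  x
}

#' Remove ventricular far-field from a recording
#'
#' Convenience wrapper chaining [detect_r_peaks()], [build_qrst_template()]
#' and [subtract_qrst()] over all channels of a recording, using a
#' simultaneous surface-ECG reference channel.
#'
#' @param rec an `af_recording`.
#' @param ecg the reference ECG vector (same length and sampling rate).
#' @param scale template scaling mode, see [subtract_qrst()].
#' @param pre_r_ms,post_r_ms template span (ms).
#' @return The cleaned `af_recording`.
#' @export
remove_farfield <- function(rec, ecg, scale = "global",
                            pre_r_ms = 50, post_r_ms = 400) {
  stopifnot(inherits(rec, "af_recording"))
  peaks <- detect_r_peaks(ecg, rec$fs_hz)
  tmpl <- build_qrst_template(ecg, peaks, rec$fs_hz, pre_r_ms, post_r_ms)
  out <- rec
  out$data <- subtract_qrst(rec$data, peaks, tmpl, scale = scale)
  out
}

#' Segment a recording into consecutive analysis windows
#'
#' Cuts the first `n_windows` consecutive, non-overlapping windows of
#' `window_s` seconds; any remainder of the recording is discarded.
#'
#' @param rec an `af_recording`.
#' @param window_s window length in seconds (default 10).
#' @param n_windows number of windows (default 5).
#' @return Object of class `window_set`: list with `windows` (list of
#'   samples x channels matrices), `window_s`, `n_windows`, `fs_hz`, `labels`.
#' @export
segment_windows <- function(rec, window_s = 10, n_windows = 5) {
  stopifnot(inherits(rec, "af_recording"))
  need <- n_windows * window_s
  if (rec$duration_s < need)
    stop(structure(class = c("afcn_insufficient_duration", "error", "condition"),
                   list(message = sprintf(
                     "recording is %.1f s but %d x %g s windows need %g s",
                     rec$duration_s, n_windows, window_s, need),
                     call = sys.call())))
  wn <- round(window_s * rec$fs_hz)
  windows <- lapply(seq_len(n_windows), function(i)
    rec$data[((i - 1) * wn + 1):(i * wn), , drop = FALSE])
  structure(list(windows = windows, window_s = window_s,
                 n_windows = n_windows, fs_hz = rec$fs_hz,
                 labels = rec$labels),
            class = "window_set")
}
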