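#' Simulation configuration
#'
#' Collects the generator settings used to emulate a clinical multi-electrode
#' AF recording: 60 s at 977 Hz, per-channel atrial cycle lengths drawn from
#' the 120-240 ms range typical of human AF, a slower ventricular rhythm
#' (RR interval 600-900 ms) responsible for far-field contamination, Gaussian
#' activation-time jitter, and white amplitude noise.
#'
#' @param fs_hz sampling frequency in Hz.
#' @param duration_s recording length in seconds.
#' @param cycle_length_ms_range interval from which per-channel AF cycle
#'   lengths are drawn (ms).
#' @param rr_interval_ms ventricular RR interval (ms); a length-2 vector is
#'   treated as a uniform range, a scalar is used as-is.
#' @param noise_sd white amplitude noise SD relative to the unit-variance
#'   atrial signal (0.1 corresponds to 20 dB SNR).
#' @param ventricular_amplitude nominal far-field QRS-T amplitude relative to
#'   the atrial signal SD; per-channel scales vary uniformly around it.
#' @param jitter_ms SD of Gaussian activation-time jitter (ms).
#' @param pulse_width_ms range of biphasic deflection widths (ms).
#' @param seed integer seed; identical configs give bit-identical recordings.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(fs_hz = 977, duration_s = 60,
                       cycle_length_ms_range = c(120, 240),
                       rr_interval_ms = c(600, 900),
                       noise_sd = 0.1, ventricular_amplitude = 1,
                       jitter_ms = 5, pulse_width_ms = c(10, 20),
                       seed = 1) {
  if (fs_hz <= 0) stop_invalid("fs_hz must be positive")
  if (duration_s <= 0) stop_invalid("duration_s must be positive")
  if (length(cycle_length_ms_range) != 2 ||
      cycle_length_ms_range[1] > cycle_length_ms_range[2])
    stop_invalid("cycle_length_ms_range must be an increasing interval")
  structure(list(fs_hz = fs_hz, duration_s = duration_s,
                 cycle_length_ms_range = cycle_length_ms_range,
                 rr_interval_ms = rr_interval_ms,
                 noise_sd = noise_sd,
                 ventricular_amplitude = ventricular_amplitude,
                 jitter_ms = jitter_ms, pulse_width_ms = pulse_width_ms,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Multichannel recording container
#'
#' @param data numeric matrix, samples x channels, no missing values.
#' @param fs_hz sampling frequency in Hz.
#' @param labels channel names; defaults to the matrix column names.
#' @return Object of class `af_recording` with fields `data`, `fs_hz`,
#'   `labels` and `duration_s`.
#' @export
af_recording <- function(data, fs_hz, labels = colnames(data)) {
  data <- as.matrix(data)
  if (anyNA(data)) stop_invalid("recording contains missing values")
  if (is.null(labels)) labels <- paste0("ch", seq_len(ncol(data)))
  if (length(labels) != ncol(data))
    stop_invalid("labels length must match channel count")
  colnames(data) <- labels
  structure(list(data = data, fs_hz = fs_hz, labels = labels,
                 duration_s = nrow(data) / fs_hz),
            class = "af_recording")
}

#' @export
print.af_recording <- function(x, ...) {
  cat(sprintf("Recording: %d channels x %d samples (%.1f s at %g Hz)\n",
              ncol(x$data), nrow(x$data), x$duration_s, x$fs_hz))
  invisible(x)
}

# Quasi-periodic activation times over [0, duration]: a uniform phase
# offset, then steps of cycle_ms with Gaussian jitter on each event.
activation_times <- function(duration_s, cycle_ms, jitter_ms) {
  n_max <- ceiling(duration_s * 1000 / cycle_ms) + 2
  t <- (runif(1) * cycle_ms + cycle_ms * (seq_len(n_max) - 1) +
        rnorm(n_max, 0, jitter_ms)) / 1000
  t[t >= 0 & t <= duration_s]
}

# Render a train of biphasic (derivative-of-Gaussian) deflections.  width_ms
# is the nominal lobe-to-lobe span; per-event amplitudes jitter around 1.
render_train <- function(times_s, width_ms, fs_hz, n_samples) {
  sig <- width_ms / 4 / 1000                      # seconds
  half <- ceiling(4 * sig * fs_hz)
  tt <- (-half:half) / fs_hz
  pulse <- -tt / sig * exp(0.5 - tt^2 / (2 * sig^2))  # peaks at +/-1
  out <- numeric(n_samples)
  amps <- rnorm(length(times_s), 1, 0.1)
  ctr <- round(times_s * fs_hz) + 1
  for (i in seq_along(ctr)) {
    idx <- (ctr[i] - half):(ctr[i] + half)
    keep <- idx >= 1 & idx <= n_samples
    out[idx[keep]] <- out[idx[keep]] + amps[i] * pulse[keep]
  }
  out
}

#' Simulate coupled atrial-fibrillation electrograms
#'
#' Generates one unipolar electrogram per electrode as a quasi-periodic train
#' of biphasic deflections. Channels joined in the planted network share
#' latent activation drivers: every ground-truth edge `e = (i, j)` has its
#' own shared deflection train `S_e`, and channel `i` mixes
#' `(1 - max_e c_e) * private_i + sum_{e : i in e} c_e * S_e`. A pair joined
#' with coupling 1 and no other edges is therefore identical up to
#' independent noise, expected pairwise mutual information increases with
#' coupling, channels not joined by an edge share no driver (two-hop
#' neighbours stay near-independent), and every channel keeps the same
#' marginal amplitude family (signals are standardized to unit variance
#' before noise is added).
#'
#' @param layout a `basket_layout`; its channel count must equal
#'   `truth$n_nodes`.
#' @param truth a `planted_network`.
#' @param cfg a `sim_config`.
#' @return An `af_recording` with the ground truth attached as attribute
#'   `truth`.
#' @export
simulate_coupled_af <- function(layout, truth, cfg) {
  stopifnot(inherits(layout, "basket_layout"),
            inherits(truth, "planted_network"),
            inherits(cfg, "sim_config"))
  nch <- n_channels(layout)
  if (truth$n_nodes != nch)
    stop_invalid("truth has ", truth$n_nodes, " nodes but layout has ",
                 nch, " channels")
  if (cfg$duration_s * 1000 < cfg$cycle_length_ms_range[2])
    stop_invalid("duration too short for a single activation cycle")
  set.seed(cfg$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  n_samples <- round(cfg$fs_hz * cfg$duration_s)
  clr <- cfg$cycle_length_ms_range
  wr <- cfg$pulse_width_ms
  new_train <- function() {
    cl <- runif(1, clr[1], clr[2])
    wd <- runif(1, wr[1], wr[2])
    render_train(activation_times(cfg$duration_s, cl, cfg$jitter_ms),
                 wd, cfg$fs_hz, n_samples)
  }

  # one shared driver per ground-truth edge, accumulated into both endpoints
  shared_acc <- matrix(0, n_samples, nch)
  edges <- which(upper.tri(truth$adjacency) & truth$adjacency == 1)
  for (e in edges) {
    i <- (e - 1) %% nch + 1
    j <- (e - 1) %/% nch + 1
    s_e <- truth$coupling[i, j] * new_train()
    shared_acc[, i] <- shared_acc[, i] + s_e
    shared_acc[, j] <- shared_acc[, j] + s_e
  }

  data <- matrix(0, n_samples, nch)
  w_ch <- apply(truth$coupling, 1, max)
  for (ch in seq_len(nch)) {
    s <- (1 - w_ch[ch]) * new_train() + shared_acc[, ch]
    s <- (s - mean(s)) / sd(s)
    data[, ch] <- s + rnorm(n_samples, 0, cfg$noise_sd)
  }

  rec <- af_recording(data, cfg$fs_hz, layout$labels)
  attr(rec, "truth") <- truth
  rec
}

#' Canonical QRS-T far-field template
#'
#' A stylized far-field ventricular complex spanning `pre_r_ms` before to
#' `post_r_ms` after the R peak: Q and S troughs flanking a dominant R wave,
#' followed by a broad T wave. Peak amplitude is 1 at the R apex (sample
#' index `round(pre_r_ms * fs / 1000) + 1`).
#'
#' @param fs_hz sampling frequency in Hz.
#' @param pre_r_ms,post_r_ms template span before/after the R peak (ms).
#' @return Numeric vector of length `round((pre_r_ms + post_r_ms) * fs / 1000) + 1`.
#' @export
ventricular_template <- function(fs_hz, pre_r_ms = 50, post_r_ms = 400) {
  t_ms <- seq(-round(pre_r_ms * fs_hz / 1000),
              round(post_r_ms * fs_hz / 1000)) / fs_hz * 1000
  bump <- function(a, mu, s) a * exp(-(t_ms - mu)^2 / (2 * s^2))
  w <- bump(1, 0, 8) + bump(-0.2, -18, 5) + bump(-0.3, 25, 6) +
    bump(0.35, 250, 45)
  w
}

#' Add ventricular far-field contamination
#'
#' Superimposes a scaled copy of the QRS-T far-field template on every
#' channel at each R time of a simulated ventricular rhythm, and returns a
#' synthetic surface-ECG reference channel carrying the same complexes at
#' unit amplitude. Per-channel scales vary uniformly in \[0.5, 1.5\] times
#' `cfg$ventricular_amplitude`, emulating the position-dependent far-field
#' pickup of basket electrodes.
#'
#' @param rec an `af_recording` (the clean atrial recording).
#' @param cfg a `sim_config`; `rr_interval_ms` sets the ventricular period
#'   and must exceed the template span.
#' @return List with `recording` (contaminated `af_recording`), `ecg`
#'   (numeric reference channel), `r_peaks` (true R sample indices),
#'   `channel_scale` (per-channel template scales) and `template` (the
#'   injected waveform), the last three serving as ground truth for
#'   validating the removal stage.
#' @export
add_ventricular_farfield <- function(rec, cfg) {
  stopifnot(inherits(rec, "af_recording"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L, kind = "Mersenne-Twister", normal.kind = "Inversion")
  fs <- rec$fs_hz
  n <- nrow(rec$data)
  rr <- if (length(cfg$rr_interval_ms) == 2)
    runif(1, cfg$rr_interval_ms[1], cfg$rr_interval_ms[2])
  else cfg$rr_interval_ms
  pre_ms <- 50; post_ms <- 400
  if (rr <= pre_ms + post_ms)
    stop_invalid("rr_interval_ms must exceed the QRS-T template span (",
                 pre_ms + post_ms, " ms)")
  tmpl <- ventricular_template(fs, pre_ms, post_ms)
  pre_n <- round(pre_ms * fs / 1000)

  r_times_ms <- seq(runif(1, 0, rr), rec$duration_s * 1000, by = rr)
  r_peaks <- round(r_times_ms / 1000 * fs) + 1
  r_peaks <- r_peaks[r_peaks >= 1 & r_peaks <= n]

  scales <- runif(ncol(rec$data), 0.5, 1.5) * cfg$ventricular_amplitude

  add_at <- function(x, scale) {
    for (r in r_peaks) {
      idx <- (r - pre_n):(r - pre_n + length(tmpl) - 1)
      keep <- idx >= 1 & idx <= n
      x[idx[keep]] <- x[idx[keep]] + scale * tmpl[keep]
    }
    x
  }

  data <- rec$data
  if (cfg$ventricular_amplitude != 0)
    for (ch in seq_len(ncol(data))) data[, ch] <- add_at(data[, ch], scales[ch])
  ecg <- add_at(rnorm(n, 0, 0.02), 1)

  out <- af_recording(data, fs, rec$labels)
  attr(out, "truth") <- attr(rec, "truth")
  list(recording = out, ecg = ecg, r_peaks = r_peaks,
       channel_scale = scales, template = tmpl)
}
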