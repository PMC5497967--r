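fs <- 977

test_that("R-peak detection recovers generator ground truth within 2 samples", {
  lay <- generate_basket_layout(2, 2)
  truth <- generate_planted_network(4, "random", m = 2, seed = 1)
  cfg <- sim_config(duration_s = 30, seed = 11)
  rec <- simulate_coupled_af(lay, truth, cfg)
  ff <- add_ventricular_farfield(rec, cfg)
  peaks <- detect_r_peaks(ff$ecg, fs)
  expect_equal(length(peaks), length(ff$r_peaks))
  expect_lte(max(abs(peaks - ff$r_peaks)), 2)
})

test_that("detection handles silence and the refractory rule", {
  expect_warning(p <- detect_r_peaks(numeric(3 * fs), fs))
  expect_length(p, 0)

  # two peaks 100 ms apart within a 250 ms refractory: larger one kept
  ecg <- numeric(4 * fs)
  t1 <- 2 * fs
  t2 <- t1 + round(0.1 * fs)
  w <- round(0.008 * fs)
  bump <- exp(-((-3 * w):(3 * w))^2 / (2 * w^2))
  ecg[t1 + (-3 * w):(3 * w)] <- 0.6 * bump
  ecg[t2 + (-3 * w):(3 * w)] <- pmax(ecg[t2 + (-3 * w):(3 * w)], 1.0 * bump)
  peaks <- detect_r_peaks(ecg, fs)
  expect_length(peaks, 1)
  expect_lte(abs(peaks - t2), 2)
})

test_that("template is the pointwise mean of aligned beats", {
  # two distinct beats a and b: template = (a+b)/2
  pre_n <- round(0.050 * fs)
  post_n <- round(0.400 * fs)
  len <- pre_n + post_n + 1
  ecg <- numeric(5 * fs)
  a <- sin(seq(0, pi, length.out = len))
  b <- 0.5 * cos(seq(0, 3 * pi, length.out = len))
  p1 <- fs
  p2 <- 3 * fs
  ecg[(p1 - pre_n):(p1 + post_n)] <- a
  ecg[(p2 - pre_n):(p2 + post_n)] <- b
  tmpl <- build_qrst_template(ecg, c(p1, p2), fs)
  expect_equal(tmpl$waveform, (a + b) / 2)
  expect_equal(length(tmpl$waveform), round((50 + 400) * fs / 1000) + 1)

  # identical beats: template equals a single beat
  ecg2 <- numeric(5 * fs)
  ecg2[(p1 - pre_n):(p1 + post_n)] <- a
  ecg2[(p2 - pre_n):(p2 + post_n)] <- a
  expect_equal(build_qrst_template(ecg2, c(p1, p2), fs)$waveform, a)

  expect_error(build_qrst_template(ecg, p1, fs),
               class = "afcn_insufficient_beats")
})

test_that("template estimated from noisy generator beats matches the truth", {
  lay <- generate_basket_layout(2, 2)
  truth <- generate_planted_network(4, "random", m = 2, seed = 1)
  cfg <- sim_config(duration_s = 60, seed = 13)
  rec <- simulate_coupled_af(lay, truth, cfg)
  ff <- add_ventricular_farfield(rec, cfg)
  peaks <- detect_r_peaks(ff$ecg, fs)
  tmpl <- build_qrst_template(ff$ecg, peaks, fs)
  expect_gte(cor(tmpl$waveform, ff$template), 0.99)
})

test_that("subtraction is local, skips edge beats, and handles degenerate input", {
  set.seed(1)
  x <- rnorm(5 * fs)
  tmpl <- structure(list(waveform = sin(seq(0, pi, length.out = 440)),
                         pre_r_ms = 50, post_r_ms = 400, fs_hz = fs,
                         n_beats = 2),
                    class = "qrst_template")
  peaks <- c(30, 2 * fs)    # first beat truncated at the left edge
  expect_message(y <- subtract_qrst(x, peaks, tmpl, scale = "per_beat"),
                 "truncated")
  pre_n <- round(0.05 * fs)
  touched <- (2 * fs - pre_n):(2 * fs - pre_n + 439)
  expect_identical(y[-touched], x[-touched])   # bit-identical outside beats
  expect_false(identical(y[touched], x[touched]))

  # zero template and no peaks are identities
  tmpl0 <- tmpl; tmpl0$waveform <- numeric(440)
  expect_identical(subtract_qrst(x, peaks, tmpl0), x)
  expect_warning(y2 <- subtract_qrst(x, integer(0), tmpl), "no R peaks")
  expect_identical(y2, x)
})

test_that("subtracting the injected template removes almost all ventricular energy", {
  set.seed(2)
  n <- 20 * fs
  atr <- rnorm(n)                      # stand-in atrial background
  w <- ventricular_template(fs)
  pre_n <- round(0.05 * fs)
  peaks <- seq(2 * fs, 18 * fs, by = round(0.8 * fs))
  contam <- atr
  for (r in peaks) {
    idx <- (r - pre_n):(r - pre_n + length(w) - 1)
    contam[idx] <- contam[idx] + 1.3 * w
  }
  tmpl <- structure(list(waveform = w, pre_r_ms = 50, post_r_ms = 400,
                         fs_hz = fs, n_beats = length(peaks)),
                    class = "qrst_template")
  clean <- subtract_qrst(contam, peaks, tmpl, scale = "global")
  resid <- sum((clean - atr)^2) / sum((contam - atr)^2)
  expect_lt(resid, 0.01)               # < 1% of injected energy remains
})

test_that("full far-field pipeline recovers the clean recording within 5% RMS", {
  lay <- generate_basket_layout(2, 2)
  truth <- generate_planted_network(4, "random", m = 2, seed = 1)
  cfg <- sim_config(duration_s = 60, seed = 3)
  rec <- simulate_coupled_af(lay, truth, cfg)
  ff <- add_ventricular_farfield(rec, cfg)
  clean <- suppressMessages(remove_farfield(ff$recording, ff$ecg))
  rel_rms <- sqrt(sum((clean$data - rec$data)^2) / sum(rec$data^2))
  expect_lt(rel_rms, 0.05)
})

test_that("windowing takes the first n consecutive windows and validates duration", {
  lay <- generate_basket_layout(2, 2)
  truth <- generate_planted_network(4, "random", m = 2, seed = 1)
  rec <- simulate_coupled_af(lay, truth, sim_config(duration_s = 60, seed = 1))
  ws <- segment_windows(rec)
  expect_equal(ws$n_windows, 5)
  expect_true(all(vapply(ws$windows, nrow, 0L) == 9770))
  expect_identical(ws$windows[[1]], rec$data[1:9770, ])
  expect_identical(ws$windows[[5]], rec$data[(4 * 9770 + 1):(5 * 9770), ])

  # exact fit leaves zero remainder; shorter errors
  rec50 <- af_recording(rec$data[1:(50 * 977), ], 977)
  expect_equal(segment_windows(rec50)$n_windows, 5)
  rec49 <- af_recording(rec$data[1:(49 * 977), ], 977)
  expect_error(segment_windows(rec49), class = "afcn_insufficient_duration")
})
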