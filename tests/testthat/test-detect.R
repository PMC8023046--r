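test_that("preprocessing removes DC and stops out-of-band energy", {
  cfg <- detector_config()
  # constant signal: band-pass removes DC entirely
  y <- preprocess(recording(rep(0.5, 2 * FS), FS), cfg)
  expect_lt(max(abs(y)), 1e-6)

  # in-band tone passes nearly unattenuated
  rec <- tone_recording(400, duration = 2)
  y <- preprocess(rec, cfg)
  expect_gte(sqrt(mean(y^2)), 0.9 * sqrt(mean(rec$samples^2)))

  # tone far above the band is crushed (3 kHz against a 100-2000 Hz band)
  rec <- tone_recording(3000, duration = 2)
  y <- preprocess(rec, cfg)
  expect_lt(sqrt(mean(y^2)), 0.05 * sqrt(mean(rec$samples^2)))

  # infeasible band for the sample rate
  expect_error(preprocess(recording(rnorm(1000), 800),
                          detector_config(bandpass = c(100, 2000))),
               "infeasible")
})

test_that("a steady sine produces no crackles", {
  x <- preprocess(tone_recording(400, duration = 2))
  expect_equal(nrow(detect_crackles(x, FS)), 0)
})

test_that("a lone damped transient is found with accurate onset", {
  sp <- sim_spec(snr_db = 16, seed = 31)        # peak ratio ~ 6 over mean
  bg <- simulate_recording(sp)$recording$samples
  w <- 10^(16 / 20) * sqrt(mean(bg^2)) *
    auscultr:::crackle_waveform(800, 0.010, FS)
  onset <- 4.2
  x <- bg
  idx <- round(onset * FS) + seq_along(w)
  x[idx] <- x[idx] + w
  ev <- detect_crackles(preprocess(recording(x, FS)), FS)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "crackle")
  expect_lt(abs(ev$onset_s - onset), 0.005)
  expect_gte(ev$peak_ratio, 2)
})

test_that("a 30 ms burst fails the crackle duration rule", {
  sp <- sim_spec(seed = 32)
  bg <- simulate_recording(sp)$recording$samples
  # sustained 30 ms noise burst well above threshold
  idx <- round(4 * FS) + seq_len(round(0.030 * FS))
  x <- bg
  x[idx] <- x[idx] + 8 * sqrt(mean(bg^2)) * sin(2 * pi * 700 * seq_along(idx) / FS)
  ev <- detect_crackles(preprocess(recording(x, FS)), FS)
  expect_equal(nrow(ev), 0)
})

test_that("a sustained tone is a single wheeze with faithful duration", {
  sp <- sim_spec(wheeze_segments = list(c(3, 1, 400)), snr_db = 20, seed = 7)
  sim <- simulate_recording(sp)
  x <- preprocess(sim$recording)
  ev <- detect_wheezes(x, FS)
  expect_equal(nrow(ev), 1)
  expect_gte(ev$duration_s, 0.8)
  expect_lte(ev$duration_s, 1.2)
  expect_lt(abs(ev$onset_s - 3), 0.1)
})

test_that("short tone bursts and silence yield no wheezes", {
  sp <- sim_spec(seed = 33)
  bg <- simulate_recording(sp)$recording$samples
  burst <- 10 * sqrt(mean(bg^2)) *
    auscultr:::wheeze_waveform(400, 0.200, FS, 0)
  x <- bg
  idx <- round(4 * FS) + seq_along(burst)
  x[idx] <- x[idx] + burst
  expect_equal(nrow(detect_wheezes(preprocess(recording(x, FS)), FS)), 0)
  expect_equal(nrow(detect_wheezes(numeric(0), FS)), 0)
  expect_equal(nrow(detect_crackles(numeric(0), FS)), 0)
  # silence after preprocessing
  expect_equal(nrow(detect_wheezes(rep(0, 9 * FS), FS)), 0)
})

test_that("detection is invariant to positive amplitude scaling", {
  sim <- simulate_recording(sim_spec(n_crackles = 4, snr_db = 15, seed = 11))
  x <- preprocess(sim$recording)
  for (scale in c(0.037, 12.5)) {
    a <- detect_crackles(x, FS)
    b <- detect_crackles(scale * x, FS)
    expect_equal(a$onset_s, b$onset_s)
    expect_equal(a$peak_ratio, b$peak_ratio, tolerance = 1e-9)
  }
  simw <- simulate_recording(
    sim_spec(wheeze_segments = list(c(2, 1.2, 350)), snr_db = 15, seed = 12))
  xw <- preprocess(simw$recording)
  a <- detect_wheezes(xw, FS)
  b <- detect_wheezes(0.01 * xw, FS)
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("emitted events always respect the duration rules", {
  set.seed(77)
  for (i in 1:6) {
    cls <- c("crackle", "wheeze", "normal")[(i - 1) %% 3 + 1]
    sp <- switch(cls,
      crackle = sim_spec(n_crackles = 6, snr_db = 12, seed = 400 + i),
      wheeze = sim_spec(wheeze_segments = list(c(2, 1, 500)), snr_db = 12,
                        seed = 400 + i),
      normal = sim_spec(seed = 400 + i))
    ev <- detect_events(simulate_recording(sp)$recording)
    expect_true(all(ev$duration_s[ev$kind == "crackle"] < 0.020))
    expect_true(all(ev$duration_s[ev$kind == "wheeze"] >= 0.500))
    if (nrow(ev) > 1)                    # sorted, non-overlapping
      expect_true(all(diff(ev$onset_s) >= 0))
  }
})

test_that("rule-based labels summarize the event table", {
  expect_equal(rule_label(NULL), "normal")
  expect_equal(rule_label(data.frame(kind = character(), onset_s = numeric(),
                                     duration_s = numeric())), "normal")
  ev <- data.frame(kind = c("crackle", "crackle", "wheeze"))
  expect_equal(rule_label(ev), "crackle")
  expect_equal(rule_label(data.frame(kind = "wheeze")), "wheeze")
})

test_that("event matching scores recall and false detections", {
  truth <- data.frame(kind = "crackle", onset_s = c(1, 2), duration_s = 0.01)
  det <- data.frame(kind = c("crackle", "crackle", "wheeze"),
                    onset_s = c(1.002, 5, 2), duration_s = c(0.01, 0.01, 0.6))
  m <- match_events(truth, det)
  expect_equal(m$n_matched, 1)
  expect_equal(m$recall, 0.5)
  expect_equal(m$false_events, 2)
})
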