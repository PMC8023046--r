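# Seeded synthetic auscultation generator.
#
# The simulator emulates the statistical structure the detector assumes:
# breath-cycle-modulated band-limited background noise, with injected crackle
# transients (damped sinusoids shorter than 20 ms) and wheeze tones (sustained
# narrowband events of at least 500 ms). Every injection is logged with its
# onset, duration and peak ratio so detector and classifier performance can be
# scored against exact ground truth.

#' Specification for one synthetic recording
#'
#' @param duration recording length in seconds (default 9, enough for at
#'   least two breathing cycles).
#' @param sample_rate Hz (default 8000).
#' @param breath_cycle breathing period in seconds (default 3); the
#'   background is amplitude-modulated by a raised sinusoid of this period.
#' @param background_band Hz pair for the background noise band
#'   (default `c(100, 1000)`; the noise is pink-weighted inside the band).
#' @param snr_db event strength in decibels: injected event peak amplitude
#'   relative to background RMS (default 20).
#' @param n_crackles number of crackle transients to inject (default 0).
#' @param crackle_duration crackle length in seconds (default 0.010; must be
#'   below 0.020).
#' @param wheeze_segments list of `c(onset_s, duration_s, frequency_hz)`
#'   triples (default none); every duration must be at least 0.5 s.
#' @param modulation_depth depth of the breath-envelope modulation in
#'   `[0, 1)` (default 0.6).
#' @param contaminant if `TRUE`, add short speech/cry-like tone bursts to the
#'   background (off by default).
#' @param seed integer seed; identical specs give bit-identical recordings.
#' @return an object of class `sim_spec`.
#' @export
sim_spec <- function(duration = 9.0, sample_rate = 8000, breath_cycle = 3.0,
                     background_band = c(100, 1000), snr_db = 20,
                     n_crackles = 0, crackle_duration = 0.010,
                     wheeze_segments = NULL, modulation_depth = 0.6,
                     contaminant = FALSE, seed = 1L) {
  if (duration / breath_cycle < 2)
    stop("duration must cover at least two breathing cycles")
  if (crackle_duration >= 0.020)
    stop("crackle_duration must be below 0.020 s")
  if (n_crackles > 0 && length(wheeze_segments) > 0)
    stop("a recording may carry crackles or wheezes, not both ",
         "(mixed recordings are excluded)")
  if (length(background_band) != 2 || background_band[1] >= background_band[2])
    stop("background_band must be an increasing Hz pair")
  if (background_band[2] > sample_rate / 2)
    stop("background_band exceeds the Nyquist frequency")
  if (modulation_depth < 0 || modulation_depth >= 1)
    stop("modulation_depth must lie in [0, 1)")
  for (w in wheeze_segments) {
    if (length(w) != 3) stop("each wheeze segment is c(onset, duration, freq)")
    if (w[2] < 0.5) stop("wheeze duration must be at least 0.5 s")
    if (w[1] < 0 || w[1] + w[2] > duration)
      stop("wheeze segment lies outside [0, duration)")
  }
  structure(list(duration = duration, sample_rate = sample_rate,
                 breath_cycle = breath_cycle,
                 background_band = background_band, snr_db = snr_db,
                 n_crackles = as.integer(n_crackles),
                 crackle_duration = crackle_duration,
                 wheeze_segments = wheeze_segments,
                 modulation_depth = modulation_depth,
                 contaminant = isTRUE(contaminant),
                 seed = as.integer(seed)),
            class = "sim_spec")
}

# pink-weighted band-passed Gaussian noise, unit RMS before modulation
sim_background <- function(n, fs, band) {
  x <- rnorm(n)
  f <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1) * fs / n
  w <- ifelse(abs(f) >= band[1] & abs(f) <= band[2],
              1 / sqrt(pmax(abs(f), 1)), 0)
  x <- Re(fft(fft(x) * w, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

# raised-sinusoid breath envelope, period `cycle`, mean-one-ish, depth d
breath_envelope <- function(n, fs, cycle, depth) {
  t <- (0:(n - 1)) / fs
  (1 - depth) + depth * 0.5 * (1 - cos(2 * pi * t / cycle))
}

# damped sinusoid crackle prototype, unit peak
crackle_waveform <- function(f0, dur, fs) {
  t <- seq(0, dur, by = 1 / fs)
  a <- exp(-t / (dur / 5)) * sin(2 * pi * f0 * t)
  a / max(abs(a))
}

# tone with 50 ms raised-cosine on/off ramps, unit peak
wheeze_waveform <- function(f0, dur, fs, phase) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  a <- sin(2 * pi * f0 * t + phase)
  ramp <- min(0.050, dur / 4)
  nr <- round(ramp * fs)
  if (nr > 0) {
    up <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
    a[seq_len(nr)] <- a[seq_len(nr)] * up
    a[(length(a) - nr + 1):length(a)] <- a[(length(a) - nr + 1):length(a)] * rev(up)
  }
  a
}

#' Simulate one auscultation recording with ground-truth events
#'
#' The background is pink-weighted band-passed noise, amplitude-modulated by a
#' raised-sinusoid breath envelope. Crackles are exponentially damped
#' sinusoids (centre frequency drawn uniformly from 200-2000 Hz) scaled so
#' the event peak is `10^(snr_db/20)` times the background RMS; wheezes are
#' amplitude-ramped tones at the requested frequencies and the same peak
#' scale. The returned event log matches the injections exactly.
#'
#' @param spec a [sim_spec()].
#' @return a list with elements `recording` (a [recording()]) and `events`
#'   (data.frame `kind,onset_s,duration_s,peak_ratio`; `peak_ratio` is the
#'   injected peak amplitude over the background mean absolute amplitude).
#' @export
simulate_recording <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed, {
    fs <- spec$sample_rate
    n <- round(spec$duration * fs)
    bg <- sim_background(n, fs, spec$background_band) *
      breath_envelope(n, fs, spec$breath_cycle, spec$modulation_depth)
    bg <- bg / sqrt(mean(bg^2))          # unit RMS after modulation
    if (spec$contaminant) {
      for (k in seq_len(3)) {            # brief speech/cry-like tone bursts
        f0 <- runif(1, 300, 600)
        on <- runif(1, 0, spec$duration - 0.3)
        burst <- 0.8 * wheeze_waveform(f0, 0.25, fs, runif(1, 0, 2 * pi))
        i <- round(on * fs) + seq_along(burst)
        bg[i] <- bg[i] + burst
      }
    }
    mean_abs_bg <- mean(abs(bg))
    peak_amp <- 10^(spec$snr_db / 20)    # relative to unit background RMS
    x <- bg
    events <- list()

    if (spec$n_crackles > 0) {
      # non-overlapping onsets, kept clear of the recording edges
      guard <- 0.1
      onsets <- sort(runif(spec$n_crackles, guard,
                           spec$duration - guard - spec$crackle_duration))
      min_sep <- 0.050
      for (k in seq_along(onsets)[-1])
        if (onsets[k] - onsets[k - 1] < min_sep)
          onsets[k] <- onsets[k - 1] + min_sep
      for (on in onsets) {
        f0 <- runif(1, 200, 2000)
        w <- peak_amp * crackle_waveform(f0, spec$crackle_duration, fs)
        i <- round(on * fs) + seq_along(w)
        x[i] <- x[i] + w
        events[[length(events) + 1]] <-
          data.frame(kind = "crackle", onset_s = on,
                     duration_s = spec$crackle_duration,
                     peak_ratio = peak_amp / mean_abs_bg)
      }
    }
    for (seg in spec$wheeze_segments) {
      w <- peak_amp * wheeze_waveform(seg[3], seg[2], fs, runif(1, 0, 2 * pi))
      i <- round(seg[1] * fs) + seq_along(w)
      x[i] <- x[i] + w
      events[[length(events) + 1]] <-
        data.frame(kind = "wheeze", onset_s = seg[1], duration_s = seg[2],
                   peak_ratio = peak_amp / mean_abs_bg)
    }

    peak <- max(abs(x))
    if (peak > 0.98) x <- x * 0.98 / peak else x <- x / max(peak, 1)
    ev <- if (length(events)) do.call(rbind, events) else
      data.frame(kind = character(), onset_s = numeric(),
                 duration_s = numeric(), peak_ratio = numeric())
    list(recording = recording(x, fs, sprintf("sim%08d", spec$seed)),
         events = ev)
  })
}

#' Build a balanced synthetic corpus on disk
#'
#' Writes `n_per_class` recordings per class (crackle, wheeze, normal) as WAV
#' files, plus a metadata manifest, a ground-truth label table and a
#' per-event annotation table. The class of a recording is the kind of its
#' injected events (normal recordings have none).
#'
#' @param out_dir output directory (created if needed).
#' @param n_per_class recordings per class (at least 1).
#' @param snr_db event strength (see [sim_spec()]); default 20.
#' @param seed integer seed; per-recording seeds are derived from it, so two
#'   corpora with the same seed are identical.
#' @param duration,sample_rate passed to [sim_spec()].
#' @return list with `manifest`, `labels` and `events` data.frames (also
#'   written as `manifest.csv`, `labels.csv`, `events.csv` under `out_dir`).
#' @export
build_corpus <- function(out_dir, n_per_class, snr_db = 20, seed = 1L,
                         duration = 9.0, sample_rate = 8000) {
  stopifnot(n_per_class >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  specs <- corpus_specs(n_per_class, snr_db, seed, duration, sample_rate)
  manifest <- NULL; labels <- NULL; events <- NULL
  with_seed(seed + 1L, {
    # metadata drawn to resemble a pediatric inpatient corpus
    n <- length(specs)
    ages <- round(exp(runif(n, log(1), log(216))))   # 1 month .. 18 years
    sexes <- sample(c("male", "female"), n, replace = TRUE, prob = c(.7, .3))
    locs <- rep_len(1:6, n)
    for (k in seq_len(n)) {
      id <- sprintf("rec%03d_%s", k, specs[[k]]$class)
      sim <- simulate_recording(specs[[k]]$spec)
      p <- file.path(out_dir, paste0(id, ".wav"))
      write_wav(sim$recording, p)
      manifest <- rbind(manifest, data.frame(
        recording_id = id, age_months = ages[k], sex = sexes[k],
        chest_location = locs[k], path = p))
      labels <- rbind(labels, data.frame(recording_id = id,
                                         label = specs[[k]]$class))
      if (nrow(sim$events))
        events <- rbind(events, cbind(recording_id = id, sim$events))
    }
  })
  if (is.null(events))
    events <- data.frame(recording_id = character(), kind = character(),
                         onset_s = numeric(), duration_s = numeric(),
                         peak_ratio = numeric())
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  write.csv(labels, file.path(out_dir, "labels.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(events, file.path(out_dir, "events.csv"), row.names = FALSE,
            quote = FALSE)
  list(manifest = manifest, labels = labels, events = events)
}

# deterministic per-recording sim_specs for a balanced corpus
corpus_specs <- function(n_per_class, snr_db, seed, duration = 9.0,
                         sample_rate = 8000) {
  specs <- list()
  with_seed(seed, {
    k <- 0L
    for (cls in BREATH_CLASSES) {
      for (i in seq_len(n_per_class)) {
        k <- k + 1L
        sub_seed <- (seed * 1000L + k) %% .Machine$integer.max
        if (cls == "crackle") {
          sp <- sim_spec(duration, sample_rate, snr_db = snr_db,
                         n_crackles = sample(4:10, 1), seed = sub_seed)
        } else if (cls == "wheeze") {
          dur_w <- runif(1, 0.8, 1.6)
          on_w <- runif(1, 0.5, duration - dur_w - 0.5)
          f_w <- runif(1, 200, 800)
          sp <- sim_spec(duration, sample_rate, snr_db = snr_db,
                         wheeze_segments = list(c(on_w, dur_w, f_w)),
                         seed = sub_seed)
        } else {
          sp <- sim_spec(duration, sample_rate, snr_db = snr_db,
                         seed = sub_seed)
        }
        specs[[k]] <- list(class = cls, spec = sp)
      }
    }
  })
  specs
}

#' Simulate a balanced corpus in memory
#'
#' Like [build_corpus()] but without disk I/O: returns one list element per
#' recording with its ground-truth events and class. Identical
#' `seed`/`snr_db` give identical audio to [build_corpus()].
#'
#' @inheritParams build_corpus
#' @return list of `list(recording, events, class)`.
#' @export
simulate_corpus <- function(n_per_class, snr_db = 20, seed = 1L,
                            duration = 9.0, sample_rate = 8000) {
  specs <- corpus_specs(n_per_class, snr_db, seed, duration, sample_rate)
  lapply(seq_along(specs), function(k) {
    sim <- simulate_recording(specs[[k]]$spec)
    sim$recording$recording_id <- sprintf("rec%03d_%s", k, specs[[k]]$class)
    list(recording = sim$recording, events = sim$events,
         class = specs[[k]]$class)
  })
}
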