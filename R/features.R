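# Wavelet-packet features.
#
# Full wavelet-packet tree to a given depth with an orthogonal Daubechies
# filter bank, implemented as periodized (circular) convolution-decimation so
# the transform is exactly orthogonal: subband energies sum to the signal
# energy to machine precision. Signals are zero-padded to a multiple of
# 2^depth. Per terminal subband the features are the log of the subband
# energy (floored at 1e-12) and the normalized Shannon entropy of the squared
# coefficients; subbands are reported in natural frequency order.

# orthonormal analysis filters (decomposition low/high pass), full double
# precision
wavelet_filters <- function(wavelet) {
  lo <- switch(wavelet,
    haar = ,
    db1 = c(0.70710678118654746, 0.70710678118654746),
    db4 = c(-0.010597401785069032, 0.032883011666885197,
            0.030841381835560764, -0.18703481171909309,
            -0.027983769416859854, 0.63088076792985892,
            0.71484657055291567, 0.23037781330889651),
    db6 = c(-0.0010773010853084796, 0.0047772575109455108,
            0.00055384220116149613, -0.03158203931748603,
            0.027522865530305727, 0.097501605587323043,
            -0.12976686756726194, -0.22626469396543983,
            0.31525035170919763, 0.75113390802109536,
            0.49462389039845306, 0.11154074335010947),
    stop("unknown wavelet: ", wavelet))
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1)   # quadrature mirror filter
  list(lo = lo, hi = hi)
}

# circular convolution of x with filter h followed by dyadic downsampling
conv_down <- function(x, h) {
  n <- length(x)
  H <- fft(c(h, rep(0, n - length(h))))
  y <- Re(fft(fft(x) * H, inverse = TRUE)) / n
  y[seq(1, n - 1, by = 2)]
}

# full WPD tree: list of terminal-node coefficient vectors in natural
# frequency order. The high-pass/decimate branch mirrors the frequency axis,
# so a node at an odd frequency position hands its children over in swapped
# order.
wpd_tree <- function(x, filt, depth) {
  nodes <- list(x)                      # frequency-ordered nodes of level l
  for (l in seq_len(depth)) {
    nxt <- vector("list", 2 * length(nodes))
    for (i in seq_along(nodes)) {
      a <- conv_down(nodes[[i]], filt$lo)
      d <- conv_down(nodes[[i]], filt$hi)
      if ((i - 1) %% 2 == 0) {          # even frequency position: low first
        nxt[[2 * i - 1]] <- a
        nxt[[2 * i]] <- d
      } else {
        nxt[[2 * i - 1]] <- d
        nxt[[2 * i]] <- a
      }
    }
    nodes <- nxt
  }
  nodes
}

#' Wavelet-packet features of a signal
#'
#' @param x amplitude vector; length must be at least `2^depth`.
#' @param sample_rate Hz (kept as an attribute for band bookkeeping; the
#'   features themselves are rate-agnostic).
#' @param wavelet orthogonal wavelet identifier: `"db6"` (default), `"db4"`,
#'   `"db1"`/`"haar"`.
#' @param depth tree depth (default 4, giving `2 * 2^4 = 32` features).
#' @return named numeric vector: `logE_b00..` log subband energies and
#'   `ent_b00..` normalized Shannon entropies, subbands in natural frequency
#'   order; attribute `feature_names` mirrors the names.
#' @export
wpd_features <- function(x, sample_rate = 8000, wavelet = "db6", depth = 4) {
  x <- as.numeric(x)
  if (length(x) < 2^depth)
    stop("signal too short for depth ", depth, " (need at least ",
         2^depth, " samples)")
  if (!all(is.finite(x))) stop("signal contains non-finite values")
  filt <- wavelet_filters(wavelet)
  m <- 2^depth
  pad <- (m - length(x) %% m) %% m
  if (pad > 0) x <- c(x, rep(0, pad))   # zero-padding preserves energy
  nodes <- wpd_tree(x, filt, depth)

  nb <- length(nodes)
  log_e <- numeric(nb)
  ent <- numeric(nb)
  for (i in seq_len(nb)) {
    c2 <- nodes[[i]]^2
    e <- sum(c2)
    log_e[i] <- log(max(e, 1e-12))
    if (e > 0) {
      p <- c2 / e
      p <- p[p > 0]
      ent[i] <- -sum(p * log(p)) / log(length(c2))
    }                                   # all-zero subband: entropy 0
  }
  idx <- sprintf("b%02d", seq_len(nb) - 1)
  v <- c(stats::setNames(log_e, paste0("logE_", idx)),
         stats::setNames(ent, paste0("ent_", idx)))
  attr(v, "feature_names") <- names(v)
  attr(v, "sample_rate") <- sample_rate
  v
}

# terminal subband energies only (frequency order); used by tests
wpd_energies <- function(x, wavelet = "db6", depth = 4) {
  filt <- wavelet_filters(wavelet)
  m <- 2^depth
  pad <- (m - length(x) %% m) %% m
  if (pad > 0) x <- c(x, rep(0, pad))
  vapply(wpd_tree(x, filt, depth), function(c) sum(c^2), numeric(1))
}

#' Extract the classifier feature vector of a recording
#'
#' Band-pass preprocesses the full recording (the classifier operates at
#' recording granularity) and computes [wpd_features()]. With
#' `hybrid = TRUE`, the detected crackle and wheeze event counts are appended
#' as two extra features (off by default, keeping the feature contract purely
#' wavelet-based).
#'
#' @param rec a [recording()].
#' @param cfg a [detector_config()] used for preprocessing (and event
#'   detection in hybrid mode).
#' @param wavelet,depth passed to [wpd_features()].
#' @param hybrid append detected event counts (default `FALSE`).
#' @return named numeric feature vector.
#' @export
extract_features <- function(rec, cfg = detector_config(), wavelet = "db6",
                             depth = 4, hybrid = FALSE) {
  x <- preprocess(rec, cfg)
  v <- wpd_features(x, rec$sample_rate, wavelet, depth)
  if (hybrid) {
    ev <- rbind(detect_crackles(x, rec$sample_rate, cfg),
                detect_wheezes(x, rec$sample_rate, cfg))
    v <- c(v, n_crackles = sum(ev$kind == "crackle"),
           n_wheezes = sum(ev$kind == "wheeze"))
  }
  v
}

#' Write/read a feature table
#'
#' CSV with `recording_id` followed by one named column per feature.
#'
#' @param features data.frame (rows recordings, first column `recording_id`).
#' @param path CSV path.
#' @return the data.frame (read) or `path` invisibly (write).
#' @export
write_features <- function(features, path) {
  write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  f <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(f)[1] != "recording_id")
    stop("feature table must start with a recording_id column")
  f
}
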