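# shared fixtures, built in code at test time

FS <- 8000

tone_recording <- function(freq, duration = 9, amp = 0.5, fs = FS) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  recording(amp * sin(2 * pi * freq * t), fs)
}

# independent brute-force oracle for the specialist consensus rules,
# written as a direct transcription of the decision flow (kept deliberately
# different in structure from the package implementation)
oracle_specialist <- function(labs, policy = "adjudicate") {
  n_ind <- sum(labs == "indeterminate")
  if (n_ind == 0 && labs[1] == labs[2] && labs[2] == labs[3])
    return("accepted")
  if (n_ind >= 2) return("rejected")
  non_ind <- labs[labs != "indeterminate"]
  counts <- table(non_ind)
  if (any(counts == 2)) {
    if (n_ind == 1 && policy == "reject") return("rejected")
    return("needs_adjudication")
  }
  "rejected"
}

all_triples <- function() {
  labs <- c("crackle", "wheeze", "normal", "indeterminate")
  expand.grid(a = labs, b = labs, c = labs, stringsAsFactors = FALSE)
}

# labelled feature clusters for classifier tests: three well-separated
# Gaussian blobs in 5 dimensions
separable_clusters <- function(n_per_class = 10, seed = 1, spread = 0.1) {
  set.seed(seed)
  centers <- rbind(crackle = c(5, 0, 0, 0, 0),
                   wheeze = c(0, 5, 0, 0, 0),
                   normal = c(0, 0, 5, 0, 0))
  x <- NULL
  y <- character()
  for (cls in rownames(centers)) {
    pts <- matrix(rnorm(n_per_class * 5, sd = spread), ncol = 5, byrow = TRUE)
    pts <- sweep(pts, 2, centers[cls, ], "+")
    x <- rbind(x, pts)
    y <- c(y, rep(cls, n_per_class))
  }
  colnames(x) <- paste0("f", 1:5)
  rownames(x) <- sprintf("r%02d", seq_len(nrow(x)))
  list(x = x, y = stats::setNames(y, rownames(x)))
}

# fixed 60-item two-rater label pair with contingency table
# [[20,5,3],[4,15,2],[1,2,8]] in category order a,b,c (rows rater 1)
kappa_fixture <- function() {
  tab <- matrix(c(20, 5, 3, 4, 15, 2, 1, 2, 8), 3, byrow = TRUE)
  cats <- c("a", "b", "c")
  a <- rep(rep(cats, each = 3), times = as.vector(t(tab)))
  b <- rep(rep(cats, times = 3), times = as.vector(t(tab)))
  list(a = a, b = b, tab = tab, cats = cats)
}
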