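# Evaluation statistics: confusion matrices, per-class and macro metrics,
# Cohen's (weighted) kappa with asymptotic CI, Kendall's W with tie
# correction, Pearson chi-square.
#
# All percentages are computed at full precision; rounding (half-up, one
# decimal) happens only in the reporting layer. Undefined quantities (zero
# denominators) propagate as NA, never silently as 0.

as_label_vector <- function(x, what = "labels") {
  if (is.data.frame(x)) {
    if (!all(c("recording_id", "label") %in% names(x)))
      stop(what, " data.frame needs recording_id and label columns")
    stats::setNames(as.character(x$label), x$recording_id)
  } else if (!is.null(names(x))) {
    stats::setNames(as.character(x), names(x))
  } else as.character(x)
}

#' Three-class confusion matrix
#'
#' Rows are gold-standard classes, columns predicted classes, in the order
#' crackle, wheeze, normal.
#'
#' @param gs,pred gold-standard and predicted labels: data.frames
#'   (`recording_id`,`label`) or named character vectors over the same
#'   recording ids (unnamed vectors are matched by position).
#' @param classes class order (default crackle, wheeze, normal).
#' @return integer matrix of class `confusion3`.
#' @export
confusion <- function(gs, pred, classes = BREATH_CLASSES) {
  g <- as_label_vector(gs, "gs")
  p <- as_label_vector(pred, "pred")
  if (!is.null(names(g)) && !is.null(names(p))) {
    only_g <- setdiff(names(g), names(p))
    only_p <- setdiff(names(p), names(g))
    if (length(only_g) || length(only_p))
      stop("recording ids do not match; only in gs: ",
           paste(only_g, collapse = ", "), "; only in pred: ",
           paste(only_p, collapse = ", "))
    p <- p[names(g)]
  } else if (length(g) != length(p)) {
    stop("label tables differ in length")
  }
  bad <- setdiff(c(g, p), classes)
  if (length(bad)) stop("labels outside the class set: ",
                        paste(unique(bad), collapse = ", "))
  m <- table(factor(g, levels = classes), factor(p, levels = classes))
  structure(matrix(as.integer(m), nrow = length(classes),
                   dimnames = list(gs = classes, pred = classes)),
            class = c("confusion3", "matrix"))
}

#' One-vs-rest per-class metrics
#'
#' Reduces the 3x3 matrix to a binary problem for `class`: TP is the
#' diagonal cell, FN the rest of its row, FP the rest of its column, TN the
#' remainder. Sensitivity (recall), precision, specificity and F1 (harmonic
#' mean of sensitivity and precision) are returned as percentages; a zero
#' denominator yields `NA`.
#'
#' @param cm a confusion matrix from [confusion()].
#' @param class target class name.
#' @return list with `sensitivity`, `precision`, `specificity`, `f1` (0-100
#'   or `NA`).
#' @export
class_metrics <- function(cm, class) {
  stopifnot(class %in% rownames(cm))
  i <- match(class, rownames(cm))
  tp <- cm[i, i]
  fn <- sum(cm[i, ]) - tp
  fp <- sum(cm[, i]) - tp
  tn <- sum(cm) - tp - fn - fp
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  sens <- pct(tp, tp + fn)
  prec <- pct(tp, tp + fp)
  list(sensitivity = sens,
       precision = prec,
       specificity = pct(tn, tn + fp),
       f1 = f1_score(sens, prec))
}

#' F1 score from sensitivity and precision
#'
#' Harmonic mean, `2*s*p/(s+p)`, on the percentage scale. `NA` when either
#' input is `NA` or both are zero.
#'
#' @param sensitivity,precision percentages (0-100).
#' @return F1 percentage or `NA`.
#' @export
f1_score <- function(sensitivity, precision) {
  if (is.na(sensitivity) || is.na(precision)) return(NA_real_)
  if (sensitivity + precision == 0) return(NA_real_)
  2 * sensitivity * precision / (sensitivity + precision)
}

#' Mean metrics over the two adventitious classes
#'
#' Component-wise arithmetic mean of crackle and wheeze metrics (the normal
#' class is excluded, as in the conventional summary row). An undefined
#' component propagates `NA`.
#'
#' @param m_crackle,m_wheeze metric lists from [class_metrics()].
#' @return list with the averaged `sensitivity`, `precision`, `specificity`,
#'   `f1`.
#' @export
macro_mean <- function(m_crackle, m_wheeze) {
  avg <- function(a, b) if (is.na(a) || is.na(b)) NA_real_ else (a + b) / 2
  list(sensitivity = avg(m_crackle$sensitivity, m_wheeze$sensitivity),
       precision = avg(m_crackle$precision, m_wheeze$precision),
       specificity = avg(m_crackle$specificity, m_wheeze$specificity),
       f1 = avg(m_crackle$f1, m_wheeze$f1))
}

#' Overall accuracy of a confusion matrix
#'
#' @param cm confusion matrix.
#' @return percentage, `100 * trace / total`.
#' @export
accuracy <- function(cm) {
  total <- sum(cm)
  if (total < 1) stop("empty confusion matrix")
  100 * sum(diag(cm)) / total
}

#' Cohen's kappa (optionally weighted) with 95% confidence interval
#'
#' Chance-corrected agreement between two raters over the same items,
#' `kappa = (po - pe) / (1 - pe)` with agreement weights: `none` (identity,
#' for nominal categories; the default), `linear` or `quadratic` over the
#' given category order. The confidence interval is `kappa +/- 1.96 * SE`
#' with the asymptotic standard error of Fleiss, Cohen and Everitt.
#'
#' @param a,b label tables (data.frames `recording_id,label` or named/plain
#'   character vectors over the same items).
#' @param weighting `"none"`, `"linear"` or `"quadratic"`.
#' @param categories category order (default: the sorted union of observed
#'   labels); required for the spacing of linear/quadratic weights.
#' @param conf_level confidence level (default 0.95).
#' @return list with `kappa`, `se`, `ci` (length-2), `po`, `pe`,
#'   `weighting`. `kappa` is `NA` when `pe = 1` (both raters constant and
#'   equal).
#' @export
cohens_kappa <- function(a, b, weighting = c("none", "linear", "quadratic"),
                         categories = NULL, conf_level = 0.95) {
  weighting <- match.arg(weighting)
  av <- as_label_vector(a, "a")
  bv <- as_label_vector(b, "b")
  if (!is.null(names(av)) && !is.null(names(bv))) {
    if (!setequal(names(av), names(bv)))
      stop("item ids do not match between raters")
    bv <- bv[names(av)]
  } else if (length(av) != length(bv)) stop("label tables differ in length")
  if (is.null(categories)) categories <- sort(unique(c(av, bv)))
  k <- length(categories)
  if (k < 2) stop("need at least 2 observed categories")
  n <- length(av)
  p <- table(factor(av, levels = categories),
             factor(bv, levels = categories)) / n

  d <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  w <- switch(weighting, none = (d == 0) * 1, linear = 1 - d,
              quadratic = 1 - d^2)
  pi_ <- rowSums(p)
  pj_ <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(pi_, pj_))
  if (1 - pe < .Machine$double.eps^0.5)
    return(list(kappa = NA_real_, se = NA_real_, ci = c(NA_real_, NA_real_),
                po = po, pe = pe, weighting = weighting))
  kap <- (po - pe) / (1 - pe)

  # asymptotic variance (Fleiss, Cohen & Everitt): row/column expected
  # weights use the opposite margin
  wi <- as.numeric(w %*% pj_)   # E_j w[i,j] under column margin
  wj <- as.numeric(pi_ %*% w)   # E_i w[i,j] under row margin
  term <- outer(wi, wj, "+")
  v <- (sum(p * (w - term * (1 - kap))^2) - (kap - pe * (1 - kap))^2) /
    (n * (1 - pe)^2)
  se <- sqrt(max(v, 0))
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(kappa = kap, se = se, ci = c(kap - z * se, kap + z * se),
       po = po, pe = pe, weighting = weighting)
}

#' Kendall's coefficient of concordance (W) with tie correction
#'
#' Agreement among m raters over n subjects. Categorical labels are embedded
#' as ordinal codes via `category_order` (an arbitrary but fixed embedding;
#' the default order is normal < crackle < wheeze and should be reported
#' alongside the statistic), then mid-ranked per rater with the standard tie
#' correction: `W = 12 S / (m^2 (n^3 - n) - m T)`.
#'
#' @param ratings matrix (raters x subjects) of labels or numeric scores.
#' @param category_order embedding order for character labels.
#' @return list with `W`, `S`, `T` (tie correction), `m`, `n`. `W` is `NA`
#'   when every rater ties all subjects (zero variance).
#' @export
kendalls_w <- function(ratings,
                       category_order = c("normal", "crackle", "wheeze")) {
  if (is.data.frame(ratings)) ratings <- as.matrix(ratings)
  if (is.character(ratings)) {
    codes <- match(ratings, category_order)
    if (anyNA(codes)) stop("labels outside category_order")
    ratings <- matrix(codes, nrow = nrow(ratings))
  }
  m <- nrow(ratings)
  n <- ncol(ratings)
  if (m < 2 || n < 2) stop("need at least 2 raters and 2 subjects")
  rk <- t(apply(ratings, 1, rank, ties.method = "average"))
  tie_t <- sum(apply(rk, 1, function(r) {
    t_g <- table(r)
    sum(t_g^3 - t_g)
  }))
  r_j <- colSums(rk)
  s <- sum((r_j - mean(r_j))^2)
  denom <- m^2 * (n^3 - n) - m * tie_t
  if (denom <= 0)
    return(list(W = NA_real_, S = s, T = tie_t, m = m, n = n))
  list(W = 12 * s / denom, S = s, T = tie_t, m = m, n = n)
}

#' Pearson chi-square test of independence
#'
#' Wraps [stats::chisq.test()] without continuity correction; all expected
#' counts must be positive.
#'
#' @param tab an r x c contingency table of counts.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal in contingency table")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Full metric report for a confusion matrix
#'
#' @param cm confusion matrix from [confusion()].
#' @return nested list: overall accuracy, per-class metrics, and the mean
#'   over the adventitious classes (all full precision).
#' @export
metrics_report <- function(cm) {
  per_class <- lapply(stats::setNames(nm = rownames(cm)),
                      function(cls) class_metrics(cm, cls))
  list(n = sum(cm),
       accuracy = accuracy(cm),
       per_class = per_class,
       adventitious_mean = macro_mean(per_class$crackle, per_class$wheeze),
       confusion = unclass(cm))
}

#' Reporting table of per-class metrics
#'
#' One row per adventitious class plus their mean, columns sensitivity,
#' precision, specificity and F1, rounded half-up to one decimal: the layout
#' of a standard performance table.
#'
#' @param cm confusion matrix.
#' @param digits decimals (default 1).
#' @return data.frame with rownames crackle, wheeze, mean.
#' @export
metrics_table <- function(cm, digits = 1) {
  rep_ <- metrics_report(cm)
  rows <- list(crackle = rep_$per_class$crackle,
               wheeze = rep_$per_class$wheeze,
               mean = rep_$adventitious_mean)
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(sensitivity = round_half_up(r$sensitivity, digits),
               precision = round_half_up(r$precision, digits),
               specificity = round_half_up(r$specificity, digits),
               f1 = round_half_up(r$f1, digits))))
  rownames(out) <- names(rows)
  out
}
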