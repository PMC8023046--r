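labels_from_matrix <- function(m, classes = c("crackle", "wheeze", "normal")) {
  gs <- character(0)
  pred <- character(0)
  for (i in seq_along(classes)) for (j in seq_along(classes)) {
    gs <- c(gs, rep(classes[i], m[i, j]))
    pred <- c(pred, rep(classes[j], m[i, j]))
  }
  ids <- sprintf("r%04d", seq_along(gs))
  list(gs = stats::setNames(gs, ids), pred = stats::setNames(pred, ids))
}

test_that("confusion matrices count gold-standard rows against predictions", {
  lp <- labels_from_matrix(diag(c(10, 20, 30)))
  cm <- confusion(lp$gs, lp$pred)
  expect_equal(diag(cm), c(crackle = 10, wheeze = 20, normal = 30))
  expect_equal(sum(cm) - sum(diag(cm)), 0)

  # swapping all crackle/wheeze predictions moves the counts off-diagonal
  swapped <- ifelse(lp$pred == "crackle", "wheeze",
                    ifelse(lp$pred == "wheeze", "crackle", lp$pred))
  cm2 <- confusion(lp$gs, stats::setNames(swapped, names(lp$pred)))
  expect_equal(cm2["crackle", "wheeze"], 10)
  expect_equal(cm2["wheeze", "crackle"], 20)
  expect_equal(cm2["crackle", "crackle"] + cm2["wheeze", "wheeze"], 0)

  # random 100-recording fixture: total and cells match a brute-force count
  set.seed(12)
  g <- sample(c("crackle", "wheeze", "normal"), 100, replace = TRUE)
  p <- sample(c("crackle", "wheeze", "normal"), 100, replace = TRUE)
  cm3 <- confusion(g, p)
  expect_equal(sum(cm3), 100)
  brute <- matrix(0L, 3, 3,
                  dimnames = list(c("crackle", "wheeze", "normal"),
                                  c("crackle", "wheeze", "normal")))
  for (k in 1:100) brute[g[k], p[k]] <- brute[g[k], p[k]] + 1L
  expect_equal(unclass(cm), unclass(cm)[rownames(cm), colnames(cm)])
  expect_true(all(unclass(cm3) == brute))

  expect_error(confusion(stats::setNames(g, paste0("a", 1:100)),
                         stats::setNames(p, paste0("b", 1:100))),
               "do not match")
})

test_that("per-class one-vs-rest reductions partition the total", {
  set.seed(13)
  m <- matrix(sample(0:30, 9), 3,
              dimnames = list(c("crackle", "wheeze", "normal"),
                              c("crackle", "wheeze", "normal")))
  lp <- labels_from_matrix(m)
  cm <- confusion(lp$gs, lp$pred)
  for (cls in rownames(cm)) {
    i <- match(cls, rownames(cm))
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- sum(cm) - tp - fn - fp
    expect_equal(tp + fn + fp + tn, sum(cm))
    mt <- class_metrics(cm, cls)
    expect_equal(mt$sensitivity, 100 * tp / (tp + fn))
    expect_equal(mt$specificity, 100 * tn / (tn + fp))
  }
})

test_that("F1 reproduces the printed-table harmonic means", {
  expect_equal(round_half_up(f1_score(81.1, 80.6)), 80.8)  # printed as 80.9
  expect_equal(round_half_up(f1_score(86.4, 76.0)), 80.9)
  expect_equal(round_half_up(f1_score(92.9, 76.5)), 83.9)
  expect_equal(round_half_up(f1_score(93.1, 75.0)), 83.1)
  expect_equal(round_half_up(f1_score(86.5, 85.7)), 86.1)
  expect_equal(round_half_up(f1_score(100.0, 46.2)), 63.2)
  # F1 lies between its inputs and equals them when they coincide
  expect_equal(f1_score(70, 70), 70)
  set.seed(14)
  for (i in 1:50) {
    s <- runif(1, 1, 100)
    p <- runif(1, 1, 100)
    f <- f1_score(s, p)
    expect_gte(f, min(s, p))
    expect_lte(f, max(s, p))
  }
  expect_true(is.na(f1_score(NA, 50)))
  expect_true(is.na(f1_score(0, 0)))
})

test_that("degenerate denominators yield NA, not exceptions or zeros", {
  m <- matrix(c(0, 0, 0, 5, 10, 2, 3, 1, 9), 3, byrow = TRUE,
              dimnames = list(c("crackle", "wheeze", "normal"),
                              c("crackle", "wheeze", "normal")))
  lp <- labels_from_matrix(m)
  cm <- confusion(lp$gs, lp$pred)
  mt <- class_metrics(cm, "crackle")   # empty gold-standard row
  expect_true(is.na(mt$sensitivity))
  expect_true(is.na(mt$f1))
  mm <- macro_mean(mt, class_metrics(cm, "wheeze"))
  expect_true(is.na(mm$sensitivity))
})

test_that("the adventitious mean row averages crackle and wheeze only", {
  mc <- list(sensitivity = 81.1, precision = 80.6, specificity = 94.1,
             f1 = f1_score(81.1, 80.6))
  mw <- list(sensitivity = 86.4, precision = 76.0, specificity = 83.0,
             f1 = f1_score(86.4, 76.0))
  mm <- macro_mean(mc, mw)
  expect_equal(round_half_up(mm$sensitivity), 83.8)
  expect_equal(round_half_up(mm$precision), 78.3)
  expect_equal(round_half_up(mm$specificity), 88.6)
  expect_identical(macro_mean(mc, mc)[c("sensitivity", "precision")],
                   mc[c("sensitivity", "precision")])
})

test_that("accuracy is the trace fraction", {
  lp <- labels_from_matrix(diag(c(10, 20, 30)))
  expect_equal(accuracy(confusion(lp$gs, lp$pred)), 100)
  lp <- labels_from_matrix(matrix(1, 3, 3))
  expect_equal(round_half_up(accuracy(confusion(lp$gs, lp$pred))), 33.3)
  # 627-recording fixture with 487 correct: the full-corpus worked example
  m627 <- matrix(c(129, 0, 30, 5, 176, 23, 26, 56, 182), 3, byrow = TRUE)
  lp <- labels_from_matrix(m627)
  cm <- confusion(lp$gs, lp$pred)
  expect_equal(sum(cm), 627)
  expect_equal(sum(diag(cm)), 487)
  expect_equal(round_half_up(accuracy(cm)), 77.7)
  expect_equal(round_half_up(class_metrics(cm, "crackle")$sensitivity), 81.1)
  expect_equal(round_half_up(class_metrics(cm, "crackle")$precision), 80.6)
  expect_error(accuracy(matrix(0, 3, 3)), "empty")
})

test_that("kappa matches a hand-computed po/pe oracle on a fixed fixture", {
  fx <- kappa_fixture()
  r <- cohens_kappa(fx$a, fx$b, weighting = "none", categories = fx$cats)
  # independent oracle: po and pe straight from the contingency table
  n <- sum(fx$tab)
  po <- sum(diag(fx$tab)) / n
  pe <- sum(rowSums(fx$tab) * colSums(fx$tab)) / n^2
  expect_equal(r$kappa, (po - pe) / (1 - pe), tolerance = 1e-10)
  expect_equal(r$po, po, tolerance = 1e-12)
  expect_equal(r$pe, pe, tolerance = 1e-12)
})

test_that("kappa and its CI agree with an independent implementation", {
  # expected values computed with statsmodels.stats.inter_rater.cohens_kappa
  # on the same 60-item table
  fx <- kappa_fixture()
  cases <- list(
    none = c(0.555555555556, 0.090939411007, 0.377317585207, 0.733793525904),
    linear = c(0.570552147239, 0.094612373118, 0.385115303436, 0.755988991042),
    quadratic = c(0.586894586895, 0.111343201285, 0.368665922454,
                  0.805123251336))
  for (w in names(cases)) {
    r <- cohens_kappa(fx$a, fx$b, weighting = w, categories = fx$cats)
    expect_equal(r$kappa, cases[[w]][1], tolerance = 1e-9)
    expect_equal(r$se, cases[[w]][2], tolerance = 1e-9)
    expect_equal(r$ci, cases[[w]][3:4], tolerance = 1e-9)
  }
})

test_that("kappa boundary behaviour: identity, independence, degeneracy", {
  a <- rep(c("crackle", "wheeze", "normal"), times = c(10, 20, 30))
  expect_equal(cohens_kappa(a, a)$kappa, 1)
  x <- rep(rep(c("a", "b"), each = 10), 2)
  y <- rep(rep(c("a", "b"), times = c(10, 10)), each = 2)[1:40]
  # explicit independence table [[10,10],[10,10]]
  x <- c(rep("a", 20), rep("b", 20))
  y <- rep(c("a", "b"), 20)
  expect_equal(cohens_kappa(x, y)$kappa, 0)
  # both raters constant and equal: pe = 1, undefined
  expect_true(is.na(suppressWarnings(
    cohens_kappa(rep("a", 10), rep("a", 10),
                 categories = c("a", "b"))$kappa)))
  # invariance under consistent relabelling
  map <- c(crackle = "K", wheeze = "W", normal = "N")
  b <- sample(c("crackle", "wheeze", "normal"), 60, replace = TRUE)
  expect_equal(cohens_kappa(a, b)$kappa,
               cohens_kappa(unname(map[a]), unname(map[b]))$kappa,
               tolerance = 1e-12)
})

test_that("Kendall's W handles perfect agreement, reversal and ties", {
  expect_equal(kendalls_w(rbind(1:3, 1:3, 1:3))$W, 1)
  expect_equal(kendalls_w(rbind(1:3, 3:1))$W, 0)
  # hand-computed tied example: 3 raters x 4 subjects,
  # codes A=(1,2,2,3) B=(1,1,2,3) C=(2,1,2,3)
  # ranks: A=(1,2.5,2.5,4) B=(1.5,1.5,3,4) C=(2.5,1,2.5,4)
  # Rj=(5,5,8,12), S=33, T=18 -> W = 12*33/(9*60-54) = 396/486
  r <- kendalls_w(rbind(c(1, 2, 2, 3), c(1, 1, 2, 3), c(2, 1, 2, 3)))
  expect_equal(r$S, 33)
  expect_equal(r$T, 18)
  expect_equal(r$W, 396 / 486, tolerance = 1e-12)
  # label input via the categorical embedding
  labs <- rbind(c("normal", "crackle", "crackle", "wheeze"),
                c("normal", "normal", "crackle", "wheeze"),
                c("crackle", "normal", "crackle", "wheeze"))
  expect_equal(kendalls_w(labs)$W, 396 / 486, tolerance = 1e-12)
  # invariance under subject permutation
  perm <- c(3, 1, 4, 2)
  expect_equal(kendalls_w(labs[, perm])$W, kendalls_w(labs)$W)
  # zero variance: undefined
  expect_true(is.na(kendalls_w(rbind(c(1, 1, 1), c(2, 2, 2)))$W))
})

test_that("chi-square matches hand arithmetic and scales with counts", {
  tab <- matrix(c(15, 15, 15, 15), 2)
  r <- chi_square(tab)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  r <- chi_square(matrix(c(20, 10, 10, 20), 2))
  expect_equal(r$statistic, 20 / 3, tolerance = 1e-10)  # = 6.667
  expect_equal(r$df, 1)
  set.seed(15)
  t1 <- matrix(sample(5:30, 6), 2)
  expect_equal(chi_square(3 * t1)$statistic, 3 * chi_square(t1)$statistic,
               tolerance = 1e-10)
  expect_error(chi_square(matrix(c(0, 0, 5, 5), 2)), "marginal")
})

test_that("report and table layers expose full and rounded views", {
  m627 <- matrix(c(129, 0, 30, 5, 176, 23, 26, 56, 182), 3, byrow = TRUE)
  lp <- labels_from_matrix(m627)
  cm <- confusion(lp$gs, lp$pred)
  rep_ <- metrics_report(cm)
  expect_equal(rep_$n, 627)
  expect_equal(round_half_up(rep_$accuracy), 77.7)
  tab <- metrics_table(cm)
  expect_equal(rownames(tab), c("crackle", "wheeze", "mean"))
  expect_equal(tab["crackle", "sensitivity"], 81.1)
  expect_equal(tab["mean", "sensitivity"],
               round_half_up((rep_$per_class$crackle$sensitivity +
                              rep_$per_class$wheeze$sensitivity) / 2))
})

test_that("reporting rounds ties away from zero", {
  expect_equal(round_half_up(83.75), 83.8)
  expect_equal(round_half_up(88.55), 88.6)
  expect_equal(round_half_up(-1.25), -1.3)
  expect_equal(round_half_up(2.345, 2), 2.35)
})
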