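test_that("ROC handles perfect separation, complete ties, and anchors the curve", {
  perfect <- rocCurve(c(2, 3, 0, 1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(auc(perfect), 1)
  expect_equal(perfect@sens[1], 0); expect_equal(perfect@spec[1], 1)
  expect_equal(perfect@sens[length(perfect@sens)], 1)
  expect_equal(perfect@spec[length(perfect@spec)], 0)
  flat <- rocCurve(rep(1, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(auc(flat), 0.5)
  expect_error(rocCurve(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("trapezoidal AUC equals pairwise concordance and complements on negation", {
  concordance <- function(s, l) {
    pos <- s[l]; neg <- s[!l]
    tot <- 0
    for (p in pos) for (n in neg)
      tot <- tot + (p > n) + 0.5 * (p == n)
    tot / (length(pos) * length(neg))
  }
  set.seed(30)
  for (i in 1:20) {
    n <- sample(6:30, 1)
    s <- sample(0:10, n, replace = TRUE)   # heavy ties
    l <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(l) || all(l)) next
    a <- auc(rocCurve(s, l))
    expect_equal(a, concordance(s, l), tolerance = 1e-12)
    expect_equal(a + auc(rocCurve(-s, l)), 1, tolerance = 1e-12)
    # strictly monotone transform leaves the AUC unchanged
    expect_equal(auc(rocCurve(exp(s / 3), l)), a, tolerance = 1e-12)
  }
})

test_that("Youden cutpoint matches the brute-force sweep and breaks ties to specificity", {
  bruteYouden <- function(s, l) {
    thr <- c(Inf, sort(unique(s), decreasing = TRUE))
    J <- vapply(thr, function(t)
      mean(s[l] >= t) + mean(s[!l] < t) - 1, numeric(1))
    max(J)
  }
  cp <- optimalCutpoint(rocCurve(c(1, 2, 3, 4, 0, 1, 2),
                                 c(rep(TRUE, 4), rep(FALSE, 3))))
  expect_equal(cp$youden,
               bruteYouden(c(1, 2, 3, 4, 0, 1, 2),
                           c(rep(TRUE, 4), rep(FALSE, 3))))
  set.seed(31)
  for (i in 1:20) {
    s <- sample(0:8, 20, replace = TRUE)
    l <- sample(c(TRUE, FALSE), 20, replace = TRUE)
    if (!any(l) || all(l)) next
    expect_equal(optimalCutpoint(rocCurve(s, l))$youden,
                 bruteYouden(s, l), tolerance = 1e-12)
  }
  # perfect separation: tie on J = 1 resolved toward higher specificity
  cp2 <- optimalCutpoint(rocCurve(c(10, 11, 0, 1),
                                  c(TRUE, TRUE, FALSE, FALSE)))
  expect_equal(cp2$youden, 1)
  expect_equal(cp2$spec, 1)
  # flat curve: degenerate cutpoint at the extreme threshold
  cp3 <- optimalCutpoint(rocCurve(rep(1, 6), rep(c(TRUE, FALSE), 3)))
  expect_equal(cp3$youden, 0)
  expect_equal(cp3$spec, 1)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(32)
  s <- rnorm(60); l <- rep(c(TRUE, FALSE), 30)
  a <- auc(rocCurve(s, l))
  b <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                      direction = "<")))
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("clinical screen applies the p and missingness rules with reasons", {
  set.seed(33)
  n <- 60
  ph <- data.frame(sample_id = sprintf("s%d", 1:n),
                   group = rep(c("nonresponder", "responder"), each = n / 2))
  cl <- data.frame(
    sample_id = ph$sample_id,
    same = rnorm(n, 10, 2),                       # no group difference
    strong = c(rnorm(n / 2, 20, 2), rnorm(n / 2, 10, 2)),
    gappy = c(rnorm(n / 2, 20, 2), rnorm(n / 2, 10, 2)),
    empty = c(rep(NA_real_, n / 2), rnorm(n / 2)))
  cl$gappy[sample(which(ph$group == "nonresponder"), 0.4 * n / 2)] <- NA
  scr <- clinicalFeatureScreen(cl, ph)
  expect_true("strong" %in% scr$selected)
  expect_false("same" %in% scr$selected)
  expect_false("gappy" %in% scr$selected)         # p small but 40% missing
  rep_g <- scr$report[scr$report$variable == "gappy", ]
  expect_match(rep_g$reason, "missingness")
  rep_e <- scr$report[scr$report$variable == "empty", ]
  expect_match(rep_e$reason, "fewer than 2")
  # identical distributions: t near 0, p near 1
  rep_s <- scr$report[scr$report$variable == "same", ]
  expect_gt(rep_s$p, 0.05)
})

test_that("bagged composite model: separable data, determinism, degenerate inputs", {
  set.seed(34)
  n <- 60
  X <- data.frame(a = c(rnorm(n / 2, 5), rnorm(n / 2, -5)),
                  b = rnorm(n))
  y <- rep(c("nonresponder", "responder"), each = n / 2)
  m1 <- trainComposite(X, y, n_trees = 25L, seed = 99L)
  expect_equal(auc(rocCurve(predictComposite(m1, X), y,
                            positive = "nonresponder")), 1)
  m2 <- trainComposite(X, y, n_trees = 25L, seed = 99L)
  expect_identical(oobScores(m1), oobScores(m2))
  expect_identical(predictComposite(m1, X), predictComposite(m2, X))
  expect_error(trainComposite(X, rep("nonresponder", n)), "single-class")
  X_bad <- X; X_bad$c <- NA_real_
  expect_error(trainComposite(X_bad, y), "non-finite feature")
  # median imputation freezes training medians
  X_na <- X; X_na$b[1:5] <- NA
  m3 <- trainComposite(X_na, y, n_trees = 10L, seed = 1L)
  expect_equal(unname(m3@imputation_values["b"]),
               median(X_na$b, na.rm = TRUE))
})

test_that("permuted labels give a null out-of-bag AUC band", {
  set.seed(35)
  n <- 200
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  inband <- replicate(50, {
    y <- sample(rep(c("nonresponder", "responder"), each = n / 2))
    m <- trainComposite(X, y, n_trees = 25L,
                        seed = sample.int(1e6, 1))
    a <- auc(rocCurve(oobScores(m), y, positive = "nonresponder"))
    a >= 0.35 && a <= 0.65
  })
  expect_gte(mean(inband), 0.90)
})

test_that("clinical screen on the study parameters selects the six laboratory markers", {
  hits <- sapply(1:25, function(sd) {
    spec <- cohortSpec(n_null_snps = 1L, planted = NULL, seed = sd)
    cl <- simulateClinical(spec)
    ph <- data.frame(sample_id = cl$sample_id,
                     group = rep(c("nonresponder", "responder"),
                                 c(50, 280)))
    scr <- clinicalFeatureScreen(cl, ph)
    c("CRP", "NE_pct", "PLT", "ALB", "ESR", "Hb") %in% scr$selected
  })
  expect_true(all(rowMeans(hits) > 0.5))
})

test_that("genotype-only cohorts: composite tracks the wGRS-only model; null cohorts sit at chance", {
  # ablation: clinical signal removed (equal group means)
  cp <- kdClinicalParams()
  cp$mean_nr <- cp$mean_r
  gaps <- vapply(1:5, function(sd) {
    co <- simulateCohort(cohortSpec(n_null_snps = 50L, clinical_params = cp,
                                    seed = sd))
    ev <- evaluateModels(co, truthPanel(co), seed = sd)
    ev$auc_composite - ev$auc_wgrs_oob
  }, numeric(1))
  expect_lt(mean(abs(gaps)), 0.05)

  # all-null cohort scored with an arbitrary fixed panel: chance-level AUCs
  in_band <- vapply(1:5, function(sd) {
    co <- simulateCohort(cohortSpec(n_null_snps = 12L, planted = NULL,
                                    clinical_params = cp, seed = 100 + sd))
    v <- variantInfo(cohortGenotype(co))[1:9, ]
    panel <- makePanel(v$chrom, v$pos, v$ref, v$alt,
                       rep("alt", 9), rep(log(2), 9))
    ev <- evaluateModels(co, panel, seed = sd)
    ev$auc_wgrs >= 0.4 && ev$auc_wgrs <= 0.6 &&
      ev$auc_composite >= 0.4 && ev$auc_composite <= 0.6
  }, logical(1))
  expect_gte(mean(in_band), 0.8)
})
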