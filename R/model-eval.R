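#' ROC curve with tie-collapsed operating points
#'
#' Builds the ROC curve of a score against binary labels: one operating
#' point per distinct score value (a sample is called positive when its
#' score is at or above the threshold), anchored at (sens, spec) = (0, 1)
#' by an infinite threshold and reaching (1, 0) at the minimum score. The
#' AUC is the trapezoidal area, equal to the tie-corrected concordance
#' probability (concordant pairs + half of tied pairs over all
#' positive-negative pairs).
#'
#' @param scores numeric scores, or a \code{\linkS4class{ScoreSet}}.
#' @param labels logical (\code{TRUE} = positive) or a vector with the
#'   positive level named by \code{positive}; ignored for a
#'   \code{ScoreSet}, whose \code{group} column is used.
#' @param positive the positive class label (default
#'   \code{"nonresponder"} for a \code{ScoreSet}).
#' @return a \code{\linkS4class{ROCCurve}}.
#' @export
rocCurve <- function(scores, labels = NULL, positive = "nonresponder") {
  if (is(scores, "ScoreSet")) {
    s <- scoreTable(scores)
    labels <- s$group == positive
    scores <- s$score
  } else if (!is.logical(labels)) {
    labels <- labels == positive
  }
  stopifnot(length(scores) == length(labels))
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (!any(labels) || all(labels))
    stop("undefined ROC: need both classes present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!labels] < t), numeric(1))
  fpr <- 1 - spec
  a <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  new("ROCCurve", thresholds = thr, sens = sens, spec = spec, auc = a)
}

#' Youden-optimal operating point of an ROC curve
#'
#' Returns the threshold maximizing Youden's J = sens + spec - 1, with
#' ties broken toward higher specificity, then lower threshold. On a flat
#' (uninformative) curve J is 0 everywhere and the tie-break lands on the
#' extreme high-specificity threshold — a degenerate but well-defined
#' cutpoint.
#'
#' @param curve a \code{\linkS4class{ROCCurve}}.
#' @return one-row \code{data.frame}: \code{threshold}, \code{sens},
#'   \code{spec}, \code{youden}.
#' @export
optimalCutpoint <- function(curve) {
  stopifnot(is(curve, "ROCCurve"))
  J <- curve@sens + curve@spec - 1
  best <- which(J == max(J))
  best <- best[order(-curve@spec[best], curve@thresholds[best])][1]
  data.frame(threshold = curve@thresholds[best], sens = curve@sens[best],
             spec = curve@spec[best], youden = J[best],
             criterion = "youden")
}

#' Screen clinical variables for group differences and adequate data
#'
#' For every laboratory variable, runs a two-sample pooled-variance
#' (Student's) t-test between non-responders and responders on the
#' non-missing values and computes the per-group missingness fraction. A
#' variable is selected when \code{p < alpha} AND its missingness in the
#' non-responder group is below \code{max_missing}. Variables with fewer
#' than two non-missing values in either group are excluded with a
#' recorded reason.
#'
#' @param clinical clinical table (\code{sample_id} + numeric variables).
#' @param phenotype phenotype table with \code{sample_id}, \code{group}.
#' @param alpha significance threshold (default 0.05).
#' @param max_missing maximum tolerated missingness fraction in the
#'   non-responder group (default 0.30).
#' @param welch use Welch's unequal-variance t-test instead of the pooled
#'   Student's test.
#' @return list with \code{selected} (character vector of variable names)
#'   and \code{report} (per-variable \code{data.frame}, sorted by
#'   non-responder missingness then p).
#' @export
clinicalFeatureScreen <- function(clinical, phenotype, alpha = 0.05,
                                  max_missing = 0.30, welch = FALSE) {
  cl <- as.data.frame(clinical)
  ph <- as.data.frame(phenotype)
  grp <- ph$group[match(cl$sample_id, ph$sample_id)]
  vars <- setdiff(names(cl), "sample_id")
  rows <- lapply(vars, function(v) {
    x_nr <- cl[[v]][grp == "nonresponder"]
    x_r <- cl[[v]][grp == "responder"]
    miss_nr <- mean(is.na(x_nr)); miss_r <- mean(is.na(x_r))
    x_nr <- x_nr[!is.na(x_nr)]; x_r <- x_r[!is.na(x_r)]
    if (length(x_nr) < 2L || length(x_r) < 2L)
      return(data.frame(variable = v, mean_nr = NA, mean_r = NA,
                        t = NA, p = NA, miss_nr = miss_nr, miss_r = miss_r,
                        selected = FALSE,
                        reason = "fewer than 2 values in a group",
                        stringsAsFactors = FALSE))
    tt <- stats::t.test(x_nr, x_r, var.equal = !welch)
    sel <- tt$p.value < alpha && miss_nr < max_missing
    data.frame(variable = v, mean_nr = mean(x_nr), mean_r = mean(x_r),
               t = unname(tt$statistic), p = tt$p.value,
               miss_nr = miss_nr, miss_r = miss_r, selected = sel,
               reason = if (sel) "" else if (tt$p.value >= alpha)
                 sprintf("p >= %g", alpha) else
                 sprintf("missingness >= %g", max_missing),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  report <- report[order(report$miss_nr, report$p), ]
  rownames(report) <- NULL
  list(selected = report$variable[report$selected], report = report)
}

#' Train the composite bagged-tree risk model
#'
#' Fits bootstrap-aggregated classification trees on the wGRS plus
#' laboratory features: each of \code{n_trees} trees is grown on a
#' bootstrap resample with \code{rpart} at its default complexity
#' (\code{minsplit} 20, \code{cp} 0.01, no cross-validation pruning) and
#' predictions are aggregated by averaging the trees' class
#' probabilities. The bootstrap is stratified by class (each resample
#' keeps the observed class counts): with a 50/280-style imbalance, plain
#' bootstrap lets the resample's class proportion vary, and since a tree's
#' probabilities are leaf class proportions this variation leaks into the
#' out-of-bag scores as a spurious anti-correlation with the left-out
#' sample's label; stratification removes that artifact so null features
#' give chance-level out-of-bag AUC. Missing feature values are imputed
#' with the per-feature
#' training medians, which are frozen into the model for prediction time.
#' The per-sample training score is the out-of-bag aggregated probability;
#' the out-of-bag misclassification rate is recorded. The same seed and
#' data always reproduce the identical model.
#'
#' The default of 100 trees trades a few seconds of fitting for stable
#' out-of-bag scores: each sample is out-of-bag in about \code{0.368 *
#' n_trees} trees, and the out-of-bag score granularity scales inversely
#' with that count — too few trees makes the score too coarse to rank
#' samples on an ROC curve.
#'
#' @param features \code{data.frame} of numeric features (rows = samples).
#' @param labels two-level vector of class labels.
#' @param n_trees number of bagged trees (default 100).
#' @param seed integer RNG seed.
#' @param positive positive class label (default \code{"nonresponder"}).
#' @return a \code{\linkS4class{CompositeModel}}.
#' @export
trainComposite <- function(features, labels, n_trees = 100L, seed = 1L,
                           positive = "nonresponder") {
  features <- as.data.frame(features)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop("single-class training set")
  if (min(table(labels)) < 10L)
    stop("need >= 10 samples per class")
  med <- vapply(features, function(col) stats::median(col, na.rm = TRUE),
                numeric(1))
  if (any(!is.finite(med)))
    stop("non-finite feature after imputation: ",
         paste(names(med)[!is.finite(med)], collapse = ", "))
  for (v in names(features)) {
    miss <- is.na(features[[v]])
    features[[v]][miss] <- med[v]
    if (any(!is.finite(features[[v]])))
      stop("non-finite feature after imputation: ", v)
  }
  y <- factor(labels, levels = c(setdiff(unique(labels), positive),
                                 positive))
  n <- nrow(features)
  n_trees <- as.integer(n_trees)
  df <- cbind(.y = y, features)
  set.seed(as.integer(seed))
  trees <- vector("list", n_trees)
  oob_prob <- matrix(NA_real_, n, n_trees)
  class_idx <- split(seq_len(n), y)
  for (t in seq_len(n_trees)) {
    idx <- unlist(lapply(class_idx, function(ci)
      ci[sample.int(length(ci), length(ci), replace = TRUE)]),
      use.names = FALSE)
    fit <- rpart::rpart(.y ~ ., data = df[idx, , drop = FALSE],
                        method = "class",
                        control = rpart::rpart.control(xval = 0))
    trees[[t]] <- fit
    oob <- setdiff(seq_len(n), idx)
    if (length(oob))
      oob_prob[oob, t] <- stats::predict(
        fit, features[oob, , drop = FALSE], type = "prob")[, positive]
  }
  oob_score <- rowMeans(oob_prob, na.rm = TRUE)
  # a sample in every bootstrap sample has no out-of-bag trees; fall back
  # to the all-tree score (vanishingly rare beyond ~20 trees)
  never_oob <- !is.finite(oob_score)
  forest <- list(trees = trees, oob_scores = oob_score)
  model <- new("CompositeModel", forest = forest,
               feature_names = names(features), imputation_values = med,
               n_trees = n_trees, seed = as.integer(seed),
               oob_error = NA_real_, positive_class = positive)
  if (any(never_oob))
    model@forest$oob_scores[never_oob] <-
      predictComposite(model, features[never_oob, , drop = FALSE])
  model@oob_error <-
    mean((model@forest$oob_scores >= 0.5) != (y == positive))
  model
}

#' Composite-model scores
#'
#' \code{oobScores} returns the out-of-bag aggregated probability of the
#' positive class for every training sample — the internally validated
#' score stream used for the headline ROC. \code{predictComposite} scores
#' new (or the training) data with all trees; on training data this is the
#' resubstitution score, which is optimistically biased.
#'
#' @param model a \code{\linkS4class{CompositeModel}}.
#' @return numeric vector of scores in [0, 1].
#' @export
oobScores <- function(model) {
  stopifnot(is(model, "CompositeModel"))
  unname(model@forest$oob_scores)
}

#' @rdname oobScores
#' @param newdata \code{data.frame} with the model's feature columns;
#'   missing values are filled with the frozen training medians.
#' @export
predictComposite <- function(model, newdata) {
  stopifnot(is(model, "CompositeModel"))
  newdata <- as.data.frame(newdata)[, model@feature_names, drop = FALSE]
  for (v in model@feature_names) {
    miss <- is.na(newdata[[v]])
    newdata[[v]][miss] <- model@imputation_values[v]
  }
  probs <- vapply(model@forest$trees, function(fit)
    stats::predict(fit, newdata, type = "prob")[, model@positive_class],
    numeric(nrow(newdata)))
  if (nrow(newdata) == 1L) mean(probs) else rowMeans(probs)
}

#' End-to-end model evaluation: wGRS alone and the composite model
#'
#' Scores the patient samples with the panel wGRS, compares the score
#' distributions of non-responders and responders (Wilcoxon rank-sum),
#' screens the clinical variables, trains the composite bagged-tree model
#' on the wGRS plus the selected laboratory variables, and reports ROC
#' curves with Youden cutpoints for (i) the wGRS alone and (ii) the
#' composite scores. The composite is evaluated on out-of-bag votes to
#' avoid resubstitution optimism; resubstitution numbers are also
#' reported, flagged as such. Because the raw wGRS ROC is computed
#' in-sample (its panel and weights were selected on the same cohort, so
#' its AUC carries selection optimism), the report also includes an
#' equal-footing baseline: the same bagged model ablated to the single
#' wGRS feature, evaluated out-of-bag (\code{auc_wgrs_oob}). The fair
#' composite-vs-wGRS comparison is \code{auc_composite} against
#' \code{auc_wgrs_oob}. Fever duration, though typically significant
#' and low-missingness, is excluded from the composite features by default
#' so the feature set is the six laboratory variables; set
#' \code{include_fever = TRUE} to add it.
#'
#' @param cohort a \code{\linkS4class{SyntheticCohort}}, or a list with
#'   elements \code{genotype} (\code{GenotypeMatrix}), \code{phenotype}
#'   and \code{clinical} (data frames).
#' @param panel a \code{\linkS4class{SNPPanel}}.
#' @param n_trees bagged trees in the composite model (default 100).
#' @param seed RNG seed for the composite fit.
#' @param alpha_clinical,max_missing clinical screen thresholds.
#' @param include_fever include fever duration among composite features.
#' @return list: \code{auc_wgrs} / \code{cut_wgrs} (raw wGRS score,
#'   in-sample), \code{auc_wgrs_oob} (wGRS-only bagged model, out-of-bag),
#'   \code{wilcoxon}, \code{screen}, \code{auc_composite} /
#'   \code{cut_composite} (out-of-bag), \code{auc_composite_resub} /
#'   \code{cut_composite_resub} (resubstitution, optimistic), the
#'   \code{ROCCurve}s, the fitted \code{model}, and \code{scores}
#'   (per-sample table).
#' @export
evaluateModels <- function(cohort, panel, n_trees = 100L, seed = 1L,
                           alpha_clinical = 0.05, max_missing = 0.30,
                           include_fever = FALSE) {
  if (is(cohort, "SyntheticCohort"))
    cohort <- list(genotype = cohortGenotype(cohort),
                   phenotype = cohortPhenotype(cohort),
                   clinical = cohortClinical(cohort))
  ph <- as.data.frame(cohort$phenotype)
  patients <- ph[ph$group %in% c("nonresponder", "responder"), ]

  ss <- scoreCohort(cohort$genotype, panel, patients)
  st <- scoreTable(ss)
  roc_w <- rocCurve(ss, positive = "nonresponder")
  cut_w <- optimalCutpoint(roc_w)
  wil <- groupCompare(ss)

  screen <- clinicalFeatureScreen(cohort$clinical, patients,
                                  alpha = alpha_clinical,
                                  max_missing = max_missing)
  feats <- screen$selected
  if (!include_fever) feats <- setdiff(feats, "Fever_days")

  cl <- as.data.frame(cohort$clinical)
  m <- match(st$sample_id, cl$sample_id)
  X <- data.frame(wgrs = st$score)
  for (v in feats) X[[v]] <- cl[[v]][m]
  model <- trainComposite(X, st$group, n_trees = n_trees, seed = seed)
  model_w <- trainComposite(X[, "wgrs", drop = FALSE], st$group,
                            n_trees = n_trees, seed = seed)

  oob <- oobScores(model)
  roc_c <- rocCurve(oob, st$group, positive = "nonresponder")
  cut_c <- optimalCutpoint(roc_c)
  roc_wo <- rocCurve(oobScores(model_w), st$group,
                     positive = "nonresponder")
  resub <- predictComposite(model, X)
  roc_r <- rocCurve(resub, st$group, positive = "nonresponder")
  cut_r <- optimalCutpoint(roc_r)

  list(auc_wgrs = auc(roc_w), cut_wgrs = cut_w,
       auc_wgrs_oob = auc(roc_wo),
       wilcoxon = wil, screen = screen,
       clinical_features = feats,
       auc_composite = auc(roc_c), cut_composite = cut_c,
       auc_composite_resub = auc(roc_r), cut_composite_resub = cut_r,
       roc_wgrs = roc_w, roc_composite = roc_c,
       model = model,
       scores = data.frame(st, composite_oob = oob,
                           composite_resub = resub))
}
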