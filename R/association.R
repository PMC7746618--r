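#' Allelic 2x2 association test
#'
#' Tests a 2x2 allele-count table \code{[case-risk, case-nonrisk;
#' control-risk, control-nonrisk]}. The odds ratio is the cross-product
#' \eqn{ad/bc}, with the Haldane-Anscombe correction (+0.5 to every cell)
#' applied for the OR and its CI only when any cell is zero — never for the
#' exact test. The p value comes from the chi-square test without
#' continuity correction, falling back to Fisher's exact test when any
#' expected cell count is below \code{fisher_threshold}. The 95\% CI is
#' \eqn{\exp(\ln \mathrm{OR} \pm 1.96\sqrt{1/a + 1/b + 1/c + 1/d})} on the
#' (possibly corrected) cells.
#'
#' @param a,b case risk-allele and non-risk-allele counts.
#' @param c,d control risk-allele and non-risk-allele counts.
#' @param fisher_threshold expected-count threshold for the exact-test
#'   fallback (default 5).
#' @return list with \code{or}, \code{ci95} (length-2), \code{p},
#'   \code{test} (\code{"chisq"} or \code{"fisher"}) and the \code{counts}.
#' @examples
#' allelicTest(10, 90, 5, 95)$or   # 950/450
#' @export
allelicTest <- function(a, b, c, d, fisher_threshold = 5) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0)) stop("negative allele counts")
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("undefined test: empty margin in the 2x2 table")
  cc <- if (any(counts == 0)) counts + 0.5 else counts
  or <- (cc["a"] * cc["d"]) / (cc["b"] * cc["c"])
  se <- sqrt(sum(1 / cc))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < fisher_threshold)) {
    p <- stats::fisher.test(tab)$p.value
    test <- "fisher"
  } else {
    p <- stats::chisq.test(tab, correct = FALSE)$p.value
    test <- "chisq"
  }
  list(or = unname(or), ci95 = unname(ci), p = min(p, 1), test = test,
       counts = counts)
}

#' Genotype-based association test under a genetic model
#'
#' Tests case-control association of one SNP under the chosen genetic
#' model. \code{allelic} tests the 2x2 allele-count table; \code{dominant}
#' collapses genotypes \{1, 2\} against 0; \code{recessive} collapses
#' \{0, 1\} against 2; \code{codominant} tests the full 2x3 genotype table;
#' \code{log-additive} is the trend-on-dosage logistic model (Wald test on
#' the dosage term). Missing dosages are excluded pairwise.
#'
#' @param dosages numeric 0/1/2/\code{NA} dosage vector (oriented however
#'   the caller counts alleles; the OR refers to the counted allele).
#' @param labels logical or two-level vector, \code{TRUE}/first level =
#'   case.
#' @param model one of \code{"allelic"}, \code{"codominant"},
#'   \code{"dominant"}, \code{"recessive"}, \code{"log-additive"}.
#' @param fisher_threshold see \code{\link{allelicTest}}.
#' @return list with \code{or}, \code{ci95}, \code{p}, \code{model},
#'   \code{test}, \code{counts}.
#' @export
genotypeTest <- function(dosages, labels,
                         model = c("allelic", "codominant", "dominant",
                                   "recessive", "log-additive"),
                         fisher_threshold = 5) {
  model <- match.arg(model)
  case <- asCase(labels)
  keep <- !is.na(dosages) & !is.na(case)
  dosages <- dosages[keep]; case <- case[keep]
  if (sum(case) < 2L || sum(!case) < 2L)
    stop("need >= 2 samples with non-missing genotype per group")
  if (length(unique(dosages)) == 1L)
    stop("undefined test: SNP monomorphic in both groups")

  if (model == "allelic") {
    a <- sum(dosages[case]); b <- 2 * sum(case) - a
    cc <- sum(dosages[!case]); dd <- 2 * sum(!case) - cc
    out <- allelicTest(a, b, cc, dd, fisher_threshold)
  } else if (model %in% c("dominant", "recessive")) {
    hit <- if (model == "dominant") dosages >= 1 else dosages == 2
    a <- sum(hit[case]); b <- sum(!hit[case])
    cc <- sum(hit[!case]); dd <- sum(!hit[!case])
    out <- allelicTest(a, b, cc, dd, fisher_threshold)
  } else if (model == "codominant") {
    tab <- table(factor(case, c(TRUE, FALSE)), factor(dosages, 0:2))
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < fisher_threshold)) {
      p <- stats::fisher.test(tab)$p.value; test <- "fisher"
    } else {
      p <- stats::chisq.test(tab, correct = FALSE)$p.value; test <- "chisq"
    }
    al <- genotypeTest(dosages, case, "allelic", fisher_threshold)
    out <- list(or = al$or, ci95 = al$ci95, p = min(p, 1), test = test,
                counts = as.vector(tab))
  } else { # log-additive
    fit <- suppressWarnings(
      stats::glm(case ~ dosages, family = stats::binomial()))
    sm <- summary(fit)$coefficients
    est <- sm["dosages", "Estimate"]; se <- sm["dosages", "Std. Error"]
    out <- list(or = exp(est),
                ci95 = exp(est + c(-1, 1) * stats::qnorm(0.975) * se),
                p = sm["dosages", "Pr(>|z|)"], test = "wald",
                counts = c(n_case = sum(case), n_control = sum(!case)))
  }
  out$model <- model
  out
}

asCase <- function(labels) {
  if (is.logical(labels)) return(labels)
  lv <- unique(stats::na.omit(labels))
  if (length(lv) != 2L) stop("labels must have exactly two levels")
  labels == lv[1]
}

#' Covariate-adjusted association p values
#'
#' Wald p values for the dosage term in logistic regressions of case
#' status on dosage plus sex, plus age, and plus both — the adjustment
#' columns of a per-SNP association report. Complete separation or
#' non-convergence is flagged and yields \code{NA} rather than an error.
#'
#' @param dosages 0/1/2/\code{NA} dosage vector.
#' @param labels case-control labels (see \code{\link{genotypeTest}}).
#' @param covariates \code{data.frame} with columns \code{sex} and
#'   \code{age_months} aligned to \code{dosages}.
#' @return list with \code{p_adj_gender}, \code{p_adj_age},
#'   \code{p_adj_both} and logical \code{flagged}.
#' @export
adjustedTest <- function(dosages, labels, covariates) {
  case <- asCase(labels)
  df <- data.frame(case = case, dosage = dosages,
                   sex = covariates$sex, age = covariates$age_months)
  fitp <- function(formula) {
    warned <- FALSE
    fit <- withCallingHandlers(
      stats::glm(formula, data = df, family = stats::binomial()),
      warning = function(w) {
        warned <<- TRUE
        invokeRestart("muffleWarning")
      })
    sm <- summary(fit)$coefficients
    # |log-odds| > 15 in any term marks (quasi-)complete separation
    bad <- warned || !fit$converged ||
      max(abs(sm[, "Estimate"])) > 15
    list(p = if (bad) NA_real_ else sm["dosage", "Pr(>|z|)"], flagged = bad)
  }
  g <- fitp(case ~ dosage + sex)
  a <- fitp(case ~ dosage + age)
  b <- fitp(case ~ dosage + sex + age)
  list(p_adj_gender = g$p, p_adj_age = a$p, p_adj_both = b$p,
       flagged = g$flagged || a$flagged || b$flagged)
}

#' Scan every common variant for case-control association
#'
#' Tests every variant with MAF above \code{maf_min} (computed over the
#' samples of the comparison) under the configured genetic model and
#' returns one record per testable variant, sorted by p ascending with
#' ties broken by |ln OR| descending, then genomic input order. Raw p
#' values drive downstream selection, as in the original two-stage design;
#' a Bonferroni-adjusted column is included for transparency only.
#'
#' @param x a \code{\linkS4class{GenotypeMatrix}}.
#' @param phenotype phenotype \code{data.frame}
#'   (\code{\link{readPhenotypeTable}}) covering the samples of \code{x}.
#' @param comparison \code{"nonresponder-vs-responder"} or
#'   \code{"nonresponder-vs-control"}; non-responders are the cases.
#' @param model genetic model, see \code{\link{genotypeTest}}.
#' @param maf_min minimum minor allele frequency (default 0.01; the scan
#'   keeps variants with MAF strictly above this).
#' @param adjust if \code{TRUE}, add sex/age-adjusted p-value columns
#'   (slower; fits three logistic models per SNP).
#' @return \code{data.frame}, one row per tested variant: variant key,
#'   coordinates, alleles, annotations, \code{maf}, \code{alt_freq},
#'   \code{or} (ALT vs REF), \code{ci_lo}, \code{ci_hi}, \code{p},
#'   \code{p_bonf}, \code{test}, optional adjusted p's, and \code{note}
#'   for variants reported untestable.
#' @export
associationScan <- function(x, phenotype,
                            comparison = c("nonresponder-vs-responder",
                                           "nonresponder-vs-control"),
                            model = "allelic", maf_min = 0.01,
                            adjust = FALSE) {
  comparison <- match.arg(comparison)
  ref_group <- if (comparison == "nonresponder-vs-responder")
    "responder" else "control"
  ph <- as.data.frame(phenotype)
  ph <- ph[ph$group %in% c("nonresponder", ref_group), ]
  if (!nrow(ph) || !any(ph$group == "nonresponder") ||
      !any(ph$group == ref_group))
    stop("comparison groups empty for ", comparison)
  sub <- x[, intersect(colnames(x), ph$sample_id)]
  case <- ph$group[match(colnames(sub), ph$sample_id)] == "nonresponder"

  d <- dosages(sub)
  v <- variantInfo(sub)
  af <- altFreqs(as(sub, "GenotypeMatrix"))
  maf <- pmin(af, 1 - af)
  testable <- !is.na(maf) & maf > maf_min
  if (!any(testable)) {
    warning("no variants pass the MAF filter (maf > ", maf_min, ")")
    return(emptyScan())
  }
  idx <- which(testable)
  rows <- lapply(idx, function(i) {
    rec <- tryCatch(genotypeTest(d[i, ], case, model),
                    error = function(e) conditionMessage(e))
    base <- data.frame(
      variant = rownames(v)[i], chrom = v$chrom[i], pos = v$pos[i],
      rsid = v$rsid[i], ref = v$ref[i], alt = v$alt[i],
      gene = v$gene[i], region = v$region[i],
      maf = maf[i], alt_freq = af[i], order = i,
      stringsAsFactors = FALSE)
    if (is.character(rec)) {
      base$or <- NA_real_; base$ci_lo <- NA_real_; base$ci_hi <- NA_real_
      base$p <- NA_real_; base$test <- NA_character_; base$note <- rec
    } else {
      base$or <- rec$or; base$ci_lo <- rec$ci95[1]; base$ci_hi <- rec$ci95[2]
      base$p <- rec$p; base$test <- rec$test; base$note <- ""
    }
    if (adjust && !is.character(rec)) {
      cov <- ph[match(colnames(sub), ph$sample_id),
                c("sex", "age_months"), drop = FALSE]
      names(cov) <- c("sex", "age_months")
      adj <- adjustedTest(d[i, ], case, cov)
      base$p_adj_gender <- adj$p_adj_gender
      base$p_adj_age <- adj$p_adj_age
      base$p_adj_both <- adj$p_adj_both
    }
    base
  })
  out <- do.call(rbind, rows)
  out$p_bonf <- pmin(stats::p.adjust(out$p, "bonferroni"), 1)
  o <- order(out$p, -abs(log(out$or)), out$order, na.last = TRUE)
  out <- out[o, ]
  out$comparison <- comparison
  rownames(out) <- NULL
  out
}

emptyScan <- function() {
  data.frame(variant = character(), chrom = character(), pos = integer(),
             rsid = character(), ref = character(), alt = character(),
             gene = character(), region = character(), maf = numeric(),
             alt_freq = numeric(), order = integer(), or = numeric(),
             ci_lo = numeric(), ci_hi = numeric(), p = numeric(),
             test = character(), note = character(), p_bonf = numeric(),
             comparison = character(), stringsAsFactors = FALSE)
}
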