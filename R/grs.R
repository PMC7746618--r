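#' Weighted genetic risk score
#'
#' The wGRS of a sample is \eqn{\sum_k w_k G_k}, where \eqn{w_k =
#' \ln(\mathrm{OR}_k)} is the frozen panel weight of SNP \eqn{k} and
#' \eqn{G_k \in \{0, 1, 2\}} its oriented risk-allele count. The dosage
#' input must already be oriented to count risk alleles and aligned to the
#' panel order (\code{\link{scoreCohort}} does both for whole cohorts).
#'
#' @param panel a \code{\linkS4class{SNPPanel}}.
#' @param dosages oriented risk-allele counts: a numeric vector of length
#'   \code{nrow(panelEntries(panel))}, or a matrix with panel SNPs in rows
#'   and samples in columns.
#' @return a numeric score (or one per sample column).
#' @examples
#' # two SNPs with OR 2 and 3; a heterozygote + risk-homozygote sample
#' log(2) * 1 + log(3) * 2
#' @export
wgrs <- function(panel, dosages) {
  w <- panelEntries(panel)$weight
  if (is.matrix(dosages)) {
    if (nrow(dosages) != length(w))
      stop("panel/dosage alignment error: ", length(w), " panel SNPs vs ",
           nrow(dosages), " dosage rows")
    as.vector(crossprod(dosages, w))
  } else {
    if (length(dosages) != length(w))
      stop("panel/dosage alignment error: ", length(w), " panel SNPs vs ",
           length(dosages), " dosages")
    sum(w * dosages)
  }
}

#' Score every sample of a cohort with the panel wGRS
#'
#' Extracts the panel SNPs from the genotype matrix, orients dosages to
#' count risk alleles, handles missing genotypes, and returns per-sample
#' scores with group labels. A missing genotype at a panel SNP is imputed
#' as \eqn{2 f_k}, twice the risk-allele frequency recorded in the panel
#' from the reference (healthy-control) group — keeping scores comparable
#' across samples with different missingness; when the panel records no
#' frequency the observed frequency across the scored samples is used. In
#' strict mode samples with any missing panel genotype are dropped
#' instead.
#'
#' @param x a \code{\linkS4class{GenotypeMatrix}}.
#' @param panel a \code{\linkS4class{SNPPanel}}.
#' @param phenotype phenotype table with \code{sample_id} and \code{group}.
#' @param strict drop samples with missing panel genotypes instead of
#'   imputing.
#' @return a \code{\linkS4class{ScoreSet}} with provenance \code{"wgrs"};
#'   per-sample imputation counts are in
#'   \code{metadata} field \code{n_imputed} of the score table attribute
#'   \code{attr(scoreTable(.), "n_imputed")}.
#' @export
scoreCohort <- function(x, panel, phenotype, strict = FALSE) {
  e <- panelEntries(panel)
  missing <- setdiff(e$variant, rownames(x))
  if (length(missing))
    stop("panel SNP(s) absent from genotype matrix: ",
         paste(missing, collapse = ", "))
  ph <- as.data.frame(phenotype)
  ids <- intersect(colnames(x), ph$sample_id)
  if (!length(ids)) stop("no phenotyped samples in the genotype matrix")
  d <- dosages(x)[e$variant, ids, drop = FALSE]
  d <- orientDosages(d, e$risk_allele)
  n_imputed <- colSums(is.na(d))
  if (strict) {
    keep <- n_imputed == 0L
    d <- d[, keep, drop = FALSE]
    ids <- ids[keep]
    n_imputed <- n_imputed[keep]
  } else if (any(is.na(d))) {
    f <- e$risk_freq
    obs <- rowSums(d, na.rm = TRUE) / (2 * rowSums(!is.na(d)))
    f[is.na(f)] <- obs[is.na(f)]
    for (k in which(rowSums(is.na(d)) > 0))
      d[k, is.na(d[k, ])] <- 2 * f[k]
  }
  scores <- wgrs(panel, d)
  tab <- DataFrame(sample_id = ids, score = scores,
                   group = ph$group[match(ids, ph$sample_id)],
                   n_imputed = unname(n_imputed))
  new("ScoreSet", scores = tab, provenance = "wgrs")
}

#' Wilcoxon rank-sum comparison of score distributions
#'
#' Two-sided rank-sum test between two groups of scores, with midranks for
#' ties. The exact distribution is enumerated when both groups have at
#' most \code{exact_max} samples and there are no ties; otherwise the
#' normal approximation with continuity correction (0.5) and tie-corrected
#' variance is used.
#'
#' @param scores a \code{\linkS4class{ScoreSet}}.
#' @param groups the two group labels to compare (first vs second;
#'   default non-responders vs responders).
#' @param exact_max size bound for exact enumeration (default 10).
#' @return list with \code{U} (rank-sum statistic of the first group),
#'   \code{z} (normal deviate, \code{NA} when exact), \code{p},
#'   \code{exact}, \code{n} and group \code{medians}.
#' @export
groupCompare <- function(scores,
                         groups = c("nonresponder", "responder"),
                         exact_max = 10L) {
  s <- scoreTable(scores)
  g1 <- s$score[s$group == groups[1]]
  g2 <- s$score[s$group == groups[2]]
  if (!length(g1) || !length(g2))
    stop("undefined test: group '",
         groups[which(c(length(g1), length(g2)) == 0)[1]], "' is empty")
  ties <- anyDuplicated(c(g1, g2)) > 0L
  use_exact <- length(g1) <= exact_max && length(g2) <= exact_max && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(g1, g2, alternative = "two.sided",
                       exact = use_exact, correct = TRUE))
  U <- unname(wt$statistic)
  p <- wt$p.value
  z <- NA_real_
  if (!use_exact) {
    n1 <- length(g1); n2 <- length(g2)
    r <- rank(c(g1, g2))
    nties <- table(r)
    mu <- n1 * n2 / 2
    sigma <- sqrt((n1 * n2 / 12) *
                  ((n1 + n2 + 1) -
                   sum(nties^3 - nties) / ((n1 + n2) * (n1 + n2 - 1))))
    diff <- U - mu
    z <- if (is.finite(sigma) && sigma > 0)
      (diff - sign(diff) * 0.5) / sigma else 0
    # degenerate all-tied data: U sits at its null mean, p is 1 by convention
    if (!is.finite(p)) p <- if (diff == 0) 1 else NA_real_
  }
  list(U = U, z = z, p = p, exact = use_exact,
       n = c(length(g1), length(g2)),
       medians = stats::setNames(c(stats::median(g1), stats::median(g2)),
                                 groups))
}
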