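#' Accessors for the core classes
#'
#' Small accessor layer so user code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @describeIn accessors the variants-by-samples dosage matrix (ALT-allele
#'   counts 0/1/2, \code{NA} = missing call).
#' @export
dosages <- function(x) {
  stopifnot(is(x, "GenotypeMatrix"))
  assay(x, "dosage")
}

#' @describeIn accessors variant metadata as a \code{data.frame}
#'   (chrom, pos, rsid, ref, alt, gene, region, quality annotations).
#' @export
variantInfo <- function(x) {
  stopifnot(is(x, "GenotypeMatrix"))
  gr <- rowRanges(x)
  out <- cbind(
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               pos = GenomicRanges::start(gr),
               stringsAsFactors = FALSE),
    as.data.frame(mcols(gr)))
  rownames(out) <- names(gr)
  out
}

#' @describeIn accessors per-sample sex, named by sample id.
#' @export
sampleSex <- function(x) {
  stopifnot(is(x, "GenotypeMatrix"))
  stats::setNames(colData(x)$sex, colnames(x))
}

#' @describeIn accessors panel entries as a \code{data.frame}.
#' @export
panelEntries <- function(x) {
  stopifnot(is(x, "SNPPanel"))
  as.data.frame(x@entries)
}

#' @describeIn accessors selection parameters recorded in a panel.
#' @export
panelParams <- function(x) {
  stopifnot(is(x, "SNPPanel"))
  x@params
}

#' @describeIn accessors scores as a \code{data.frame}
#'   (sample_id, score, group).
#' @export
scoreTable <- function(x) {
  stopifnot(is(x, "ScoreSet"))
  as.data.frame(x@scores)
}

#' @describeIn accessors score provenance (\code{"wgrs"} or
#'   \code{"composite"}).
#' @export
scoreProvenance <- function(x) {
  stopifnot(is(x, "ScoreSet"))
  x@provenance
}

#' @describeIn accessors genotype component of a synthetic cohort.
#' @export
cohortGenotype <- function(x) {
  stopifnot(is(x, "SyntheticCohort"))
  x@genotype
}

#' @describeIn accessors phenotype table of a synthetic cohort.
#' @export
cohortPhenotype <- function(x) {
  stopifnot(is(x, "SyntheticCohort"))
  as.data.frame(x@phenotype)
}

#' @describeIn accessors clinical table of a synthetic cohort.
#' @export
cohortClinical <- function(x) {
  stopifnot(is(x, "SyntheticCohort"))
  as.data.frame(x@clinical)
}

#' @describeIn accessors ground-truth parameters of the planted SNPs.
#' @export
cohortTruth <- function(x) {
  stopifnot(is(x, "SyntheticCohort"))
  as.data.frame(x@truth)
}

#' @describeIn accessors area under an ROC curve.
#' @export
auc <- function(x) {
  stopifnot(is(x, "ROCCurve"))
  x@auc
}

#' @describeIn accessors ROC operating points as a \code{data.frame}
#'   (threshold, sens, spec).
#' @export
rocPoints <- function(x) {
  stopifnot(is(x, "ROCCurve"))
  data.frame(threshold = x@thresholds, sens = x@sens, spec = x@spec)
}

setMethod("show", "SNPPanel", function(object) {
  e <- object@entries
  cat(sprintf("SNPPanel with %d risk lo%s\n", nrow(e),
              if (nrow(e) == 1) "cus" else "ci"))
  p <- object@params
  if (length(p))
    cat(sprintf("  selection: maf > %s, stage alpha %s, final p < %s, k_max %s\n",
                p$maf_min, p$alpha_stage, p$p_final, p$k_max))
  if (nrow(e)) {
    show_n <- min(nrow(e), 9L)
    df <- as.data.frame(e[seq_len(show_n),
                          c("chrom", "pos", "rsid", "risk_allele",
                            "weight", "p_stage1", "p_stage2")])
    df$weight <- signif(df$weight, 4)
    print(df, row.names = FALSE)
    if (nrow(e) > show_n) cat(sprintf("  ... and %d more\n", nrow(e) - show_n))
  }
})

setMethod("show", "ScoreSet", function(object) {
  s <- object@scores
  cat(sprintf("ScoreSet (%s) with %d samples\n", object@provenance, nrow(s)))
  for (g in unique(s$group))
    cat(sprintf("  %-13s n=%3d  median score %.4g\n", g,
                sum(s$group == g), stats::median(s$score[s$group == g])))
})

setMethod("show", "SyntheticCohort", function(object) {
  ph <- object@phenotype
  cat("SyntheticCohort\n")
  cat(sprintf("  samples: %d (%s)\n", nrow(ph),
              paste(sprintf("%s=%d", names(table(ph$group)),
                            as.integer(table(ph$group))), collapse = ", ")))
  cat(sprintf("  variants: %d (%d planted)\n",
              nrow(object@genotype), nrow(object@truth)))
  cat(sprintf("  clinical variables: %d\n", ncol(object@clinical) - 1L))
})

setMethod("show", "ROCCurve", function(object) {
  cat(sprintf("ROCCurve: %d operating points, AUC = %.4f\n",
              length(object@thresholds), object@auc))
})

setMethod("show", "CompositeModel", function(object) {
  cat(sprintf("CompositeModel: %d bagged trees on %d features (seed %d)\n",
              object@n_trees, length(object@feature_names), object@seed))
  cat(sprintf("  features: %s\n",
              paste(object@feature_names, collapse = ", ")))
  cat(sprintf("  out-of-bag error: %.4f\n", object@oob_error))
})
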