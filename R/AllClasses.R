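#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   rowRanges colData colData<- rowData
NULL

#' Genotype matrix with variant metadata and sample sex
#'
#' A container for hard-called biallelic SNP genotypes, stored as a
#' \code{RangedSummarizedExperiment} with a single \code{"dosage"} assay
#' (variants in rows, samples in columns) counting copies of the ALT allele
#' (0, 1, 2 or \code{NA} for a missing call). Variant metadata (rsid, REF,
#' ALT, optional gene / functional-region annotation and the GATK quality
#' annotations QD, FS, MQ, MQRankSum, ReadPosRankSum) live in
#' \code{rowRanges}; per-sample sex lives in \code{colData$sex}.
#'
#' Coordinates are 1-based and fully closed, matching VCF. Chromosome Y
#' genotypes are kept in diploid coding for all samples (the upstream
#' genotyper emitted diploid calls there); sex-stratified genotype
#' frequencies can be inspected with \code{\link{genotypeFrequencies}}.
#'
#' @slot .  inherits all slots from \code{RangedSummarizedExperiment}.
#' @seealso \code{\link{GenotypeMatrix}} (constructor),
#'   \code{\link{readGenotypeVcf}}, \code{\link{hardFilterVariants}}
#' @export
setClass("GenotypeMatrix",
         contains = "RangedSummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  if (!"dosage" %in% names(assays(object)))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- assay(object, "dosage")
    bad <- d[!is.na(d)]
    if (length(bad) && !all(bad %in% c(0, 1, 2)))
      msg <- c(msg, "non-missing dosages must be 0, 1 or 2")
  }
  if (!"sex" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain a 'sex' column")
  else {
    sx <- colData(object)$sex
    if (!all(sx %in% c("male", "female") | is.na(sx)))
      msg <- c(msg, "sex must be 'male', 'female' or NA")
  }
  rd <- rowData(object)
  for (col in c("rsid", "ref", "alt"))
    if (!col %in% colnames(rd))
      msg <- c(msg, sprintf("rowData must contain '%s'", col))
  if ("ref" %in% colnames(rd) && "alt" %in% colnames(rd)) {
    if (any(rd$ref == rd$alt))
      msg <- c(msg, "ref and alt alleles must differ")
    if (!all(nchar(rd$ref) == 1L & nchar(rd$alt) == 1L))
      msg <- c(msg, "only single-nucleotide ref/alt alleles are allowed")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosage numeric matrix of ALT-allele counts, variants in rows and
#'   samples in columns; entries 0/1/2 or \code{NA}.
#' @param variants \code{data.frame} (or \code{DataFrame}) with one row per
#'   variant: columns \code{chrom}, \code{pos}, \code{rsid}, \code{ref},
#'   \code{alt}, optionally \code{gene}, \code{region} and the quality
#'   annotations \code{QD}, \code{FS}, \code{MQ}, \code{MQRankSum},
#'   \code{ReadPosRankSum} (any may be \code{NA}).
#' @param sex character vector, one of \code{"male"}/\code{"female"} per
#'   sample (recycled if length 1).
#' @return a \code{\linkS4class{GenotypeMatrix}}.
#' @examples
#' gm <- GenotypeMatrix(
#'   dosage = rbind(snp1 = c(0, 1, 2)),
#'   variants = data.frame(chrom = "1", pos = 100L, rsid = "rs1",
#'                         ref = "A", alt = "G"),
#'   sex = c("male", "female", "male"))
#' dosages(gm)
#' @export
GenotypeMatrix <- function(dosage, variants, sex) {
  dosage <- as.matrix(dosage)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  stopifnot(nrow(dosage) == nrow(variants))
  if (any(variants$pos < 1L))
    stop("variant positions must be >= 1 (1-based coordinates)")
  sex <- rep_len(as.character(sex), ncol(dosage))
  for (col in c("gene", "region"))
    if (!col %in% names(variants)) variants[[col]] <- NA_character_
  for (col in c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum"))
    if (!col %in% names(variants)) variants[[col]] <- NA_real_
  gr <- GRanges(seqnames = as.character(variants$chrom),
                ranges = IRanges(start = as.integer(variants$pos), width = 1L))
  mcols(gr) <- DataFrame(
    variants[, c("rsid", "ref", "alt", "gene", "region",
                 "QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum")])
  vid <- variantKeys(variants)
  rownames(dosage) <- vid
  names(gr) <- vid
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("S%04d", seq_len(ncol(dosage)))
  se <- SummarizedExperiment(
    assays = list(dosage = dosage), rowRanges = gr,
    colData = DataFrame(sex = sex, row.names = colnames(dosage)))
  new("GenotypeMatrix", se)
}

# canonical variant key: chrom:pos:ref:alt (never rsid alone)
variantKeys <- function(v) {
  paste(as.character(v$chrom), as.integer(v$pos), v$ref, v$alt, sep = ":")
}

#' Panel of selected risk loci with ln(OR) weights
#'
#' Holds the risk loci surviving two-stage selection, with the risk-allele
#' orientation resolved at selection time and the per-SNP weight frozen as
#' \eqn{w_k = \ln(\mathrm{OR}_k)} of the risk allele versus the non-risk
#' allele. Downstream scoring never re-estimates the weights.
#'
#' @slot entries \code{DataFrame} with columns \code{chrom}, \code{pos},
#'   \code{rsid}, \code{ref}, \code{alt}, \code{risk_allele} (\code{"alt"} or
#'   \code{"ref"}), \code{weight}, \code{p_stage1}, \code{p_stage2},
#'   \code{or_stage1}, \code{risk_freq} (reference-group risk-allele
#'   frequency used to impute missing genotypes, may be \code{NA}).
#' @slot params list of the selection thresholds used
#'   (\code{maf_min}, \code{alpha_stage}, \code{p_final}, \code{k_max},
#'   \code{r2_max}).
#' @seealso \code{\link{rankAndTrim}}, \code{\link{wgrs}}
#' @export
setClass("SNPPanel",
         representation(entries = "DataFrame", params = "list"))

setValidity("SNPPanel", function(object) {
  e <- object@entries
  need <- c("chrom", "pos", "rsid", "ref", "alt", "risk_allele",
            "weight", "p_stage1", "p_stage2")
  miss <- setdiff(need, colnames(e))
  if (length(miss))
    return(sprintf("panel entries lack column(s): %s",
                   paste(miss, collapse = ", ")))
  if (nrow(e)) {
    if (!all(e$risk_allele %in% c("ref", "alt")))
      return("risk_allele must be 'ref' or 'alt'")
    if (!all(is.finite(e$weight)) || any(e$weight == 0))
      return("weights must be finite and nonzero")
  }
  TRUE
})

#' Per-sample risk scores with group labels
#'
#' One score per sample (a wGRS or a composite-model probability), together
#' with the sample's phenotype group, feeding the Wilcoxon group comparison
#' and ROC analysis.
#'
#' @slot scores \code{DataFrame} with columns \code{sample_id},
#'   \code{score}, \code{group}.
#' @slot provenance \code{"wgrs"} or \code{"composite"}.
#' @seealso \code{\link{scoreCohort}}, \code{\link{groupCompare}},
#'   \code{\link{rocCurve}}
#' @export
setClass("ScoreSet",
         representation(scores = "DataFrame", provenance = "character"))

setValidity("ScoreSet", function(object) {
  s <- object@scores
  if (!all(c("sample_id", "score", "group") %in% colnames(s)))
    return("scores need columns sample_id, score, group")
  if (anyDuplicated(s$sample_id))
    return("one score per sample: duplicated sample_id")
  if (nrow(s) && !all(is.finite(s$score)))
    return("scores must be finite")
  if (!object@provenance %in% c("wgrs", "composite"))
    return("provenance must be 'wgrs' or 'composite'")
  TRUE
})

#' A simulated case-control cohort with ground truth
#'
#' Bundles the simulated genotypes, phenotype and clinical tables with the
#' generating parameters of every planted SNP, so recovery of the planted
#' effects can be tested downstream.
#'
#' @slot genotype \code{\linkS4class{GenotypeMatrix}}.
#' @slot phenotype \code{DataFrame}: \code{sample_id}, \code{group}
#'   (\code{nonresponder}/\code{responder}/\code{control}), \code{sex},
#'   \code{age_months}.
#' @slot clinical \code{DataFrame}: \code{sample_id} plus one column per
#'   laboratory variable, \code{NA} where masked missing.
#' @slot truth \code{DataFrame}: one row per planted SNP with its generating
#'   allele frequencies and odds ratios.
#' @slot spec the \code{\link{cohortSpec}} list that generated the cohort.
#' @export
setClass("SyntheticCohort",
         representation(genotype = "GenotypeMatrix",
                        phenotype = "DataFrame",
                        clinical = "DataFrame",
                        truth = "DataFrame",
                        spec = "list"))

setValidity("SyntheticCohort", function(object) {
  ph <- object@phenotype
  if (!all(c("sample_id", "group", "sex", "age_months") %in% colnames(ph)))
    return("phenotype needs sample_id, group, sex, age_months")
  if (!all(ph$group %in% c("nonresponder", "responder", "control")))
    return("unknown phenotype group label")
  if (anyDuplicated(ph$sample_id))
    return("every sample appears exactly once in the phenotype table")
  if (!identical(sort(colnames(object@genotype)), sort(ph$sample_id)))
    return("genotyped samples and phenotype samples must coincide")
  TRUE
})

#' An ROC curve with tie-collapsed operating points
#'
#' One operating point per distinct score value, anchored at
#' (sensitivity, specificity) = (0, 1) and (1, 0); the AUC is the trapezoidal
#' area, which equals the tie-corrected pairwise concordance probability.
#'
#' @slot thresholds numeric, descending; \code{Inf} anchors the (0, 1) end.
#' @slot sens per-threshold sensitivity (true-positive rate).
#' @slot spec per-threshold specificity (true-negative rate).
#' @slot auc trapezoidal area under the curve.
#' @seealso \code{\link{rocCurve}}, \code{\link{optimalCutpoint}}
#' @export
setClass("ROCCurve",
         representation(thresholds = "numeric", sens = "numeric",
                        spec = "numeric", auc = "numeric"))

setValidity("ROCCurve", function(object) {
  n <- length(object@thresholds)
  if (length(object@sens) != n || length(object@spec) != n)
    return("thresholds, sens and spec must have equal length")
  if (is.unsorted(rev(object@thresholds)))
    return("thresholds must be descending")
  if (is.unsorted(object@sens))
    return("sensitivity must be non-decreasing as the threshold decreases")
  if (object@auc < 0 || object@auc > 1)
    return("auc must lie in [0, 1]")
  TRUE
})

#' Bagged-tree composite risk model
#'
#' A bootstrap-aggregated classification-tree model over the wGRS plus the
#' selected laboratory variables. Per-sample training scores are the
#' out-of-bag vote fractions (in-sample votes from bagged trees are
#' optimistically biased); prediction on new data uses all trees. Median
#' imputation values for missing features are frozen at training time.
#'
#' @slot forest the fitted ensemble (opaque).
#' @slot feature_names features the model was trained on, in order.
#' @slot imputation_values per-feature training medians used to fill
#'   missing values at train and predict time.
#' @slot n_trees number of bagged trees.
#' @slot seed RNG seed the fit was made reproducible with.
#' @slot oob_error out-of-bag misclassification estimate.
#' @slot positive_class label treated as the positive class.
#' @seealso \code{\link{trainComposite}}, \code{\link{predictComposite}}
#' @export
setClass("CompositeModel",
         representation(forest = "ANY", feature_names = "character",
                        imputation_values = "numeric", n_trees = "integer",
                        seed = "integer", oob_error = "numeric",
                        positive_class = "character"))
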