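#' Intersect two association scans (two-stage candidate selection)
#'
#' Stage 1 is the discovery comparison (non-responders vs responders);
#' stage 2 (non-responders vs healthy controls) is corroborative. A variant
#' is a candidate when it passes \code{p < alpha} and \code{maf > maf_min}
#' in BOTH scans. Variants are matched by (chrom, pos, ref, alt) — never by
#' rsid alone.
#'
#' @param scan1,scan2 outputs of \code{\link{associationScan}} over a
#'   shared variant universe.
#' @param alpha per-stage significance threshold (default 0.05).
#' @param maf_min minimum MAF in each scan (default 0.01).
#' @return \code{data.frame} of candidates: the stage-1 record joined with
#'   \code{p_stage2}, \code{or_stage2}, \code{maf_stage2}.
#' @export
selectCandidates <- function(scan1, scan2, alpha = 0.05, maf_min = 0.01) {
  if (!length(intersect(scan1$variant, scan2$variant))) {
    warning("scans share no variants (disjoint universes)")
    return(cbind(emptyScan()[, c("variant", "chrom", "pos", "rsid", "ref",
                                 "alt", "gene", "region", "maf", "or",
                                 "ci_lo", "ci_hi", "p", "order")],
                 data.frame(p_stage2 = numeric(), or_stage2 = numeric(),
                            maf_stage2 = numeric())))
  }
  pass1 <- scan1[!is.na(scan1$p) & scan1$p < alpha & scan1$maf > maf_min, ]
  pass2 <- scan2[!is.na(scan2$p) & scan2$p < alpha & scan2$maf > maf_min, ]
  keep <- pass1$variant %in% pass2$variant
  out <- pass1[keep, c("variant", "chrom", "pos", "rsid", "ref", "alt",
                       "gene", "region", "maf", "or", "ci_lo", "ci_hi",
                       "p", "order")]
  m <- match(out$variant, pass2$variant)
  out$p_stage2 <- pass2$p[m]
  out$or_stage2 <- pass2$or[m]
  out$maf_stage2 <- pass2$maf[m]
  rownames(out) <- NULL
  out
}

#' Rank candidates, apply the final p cut, and freeze panel weights
#'
#' Keeps candidates with stage-1 \code{p < p_final}, ranks by stage-1 p
#' ascending (ties: |ln OR| descending, then genomic order), trims to
#' \code{k_max} loci, resolves the risk-allele orientation (the allele with
#' OR > 1; an OR of exactly 1 is logged and the locus dropped as
#' zero-weight), and freezes the weights \eqn{w_k = \ln(\mathrm{OR}_k)} of
#' the risk allele. When the genotype matrix and phenotype are supplied,
#' the risk-allele frequency in the healthy-control group is recorded per
#' locus for downstream missing-genotype imputation.
#'
#' @param candidates output of \code{\link{selectCandidates}}.
#' @param p_final final stage-1 p threshold (default 3e-3).
#' @param k_max maximum panel size (default 9).
#' @param alpha_stage,maf_min recorded selection parameters (defaults
#'   0.05, 0.01); pass the values used in \code{selectCandidates}.
#' @param genotype,phenotype optional \code{GenotypeMatrix} and phenotype
#'   table used to record reference-group risk-allele frequencies.
#' @return a \code{\linkS4class{SNPPanel}}.
#' @export
rankAndTrim <- function(candidates, p_final = 3e-3, k_max = 9L,
                        alpha_stage = 0.05, maf_min = 0.01,
                        genotype = NULL, phenotype = NULL) {
  if (!nrow(candidates))
    stop("empty panel: no candidates supplied")
  keep <- candidates[candidates$p < p_final, ]
  if (!nrow(keep))
    stop("empty panel: no candidate passed p < ", p_final)
  tie1 <- is.na(keep$or)
  if (any(tie1)) keep <- keep[!tie1, ]
  ties_or1 <- keep$or == 1
  if (any(ties_or1)) {
    warning(sum(ties_or1), " candidate(s) with OR exactly 1 dropped ",
            "(no definable risk allele / zero weight)")
    keep <- keep[!ties_or1, ]
  }
  if (!nrow(keep)) stop("empty panel: all candidates had OR = 1")
  o <- order(keep$p, -abs(log(keep$or)), keep$chrom, keep$pos)
  keep <- keep[o, ]
  keep <- keep[seq_len(min(nrow(keep), k_max)), ]

  risk_allele <- ifelse(keep$or > 1, "alt", "ref")
  weight <- abs(log(keep$or))
  risk_freq <- rep(NA_real_, nrow(keep))
  if (!is.null(genotype)) {
    samp <- colnames(genotype)
    if (!is.null(phenotype)) {
      ph <- as.data.frame(phenotype)
      ctrl <- ph$sample_id[ph$group == "control"]
      if (length(ctrl)) samp <- intersect(samp, ctrl)
    }
    d <- dosages(genotype)[keep$variant, samp, drop = FALSE]
    d <- orientDosages(d, risk_allele)
    nn <- rowSums(!is.na(d))
    risk_freq <- ifelse(nn > 0, rowSums(d, na.rm = TRUE) / (2 * nn),
                        NA_real_)
  }
  entries <- DataFrame(
    variant = keep$variant, chrom = keep$chrom, pos = keep$pos,
    rsid = keep$rsid, ref = keep$ref, alt = keep$alt,
    risk_allele = risk_allele, weight = weight,
    or_stage1 = keep$or, p_stage1 = keep$p, p_stage2 = keep$p_stage2,
    risk_freq = unname(risk_freq))
  new("SNPPanel", entries = entries,
      params = list(maf_min = maf_min, alpha_stage = alpha_stage,
                    p_final = p_final, k_max = k_max, r2_max = NA_real_))
}

#' Pairwise linkage-disequilibrium check over a panel
#'
#' Computes the composite-LD r-squared — the squared Pearson correlation of
#' dosage vectors over pairwise-complete samples — for every pair of panel
#' SNPs, flagging pairs above \code{r2_max}. The check is advisory by
#' default; in strict mode the later-ranked SNP of each flagged pair is
#' dropped from the returned panel. Constant dosage vectors have undefined
#' r-squared, reported as \code{NA}.
#'
#' @param x a \code{\linkS4class{GenotypeMatrix}} containing the panel
#'   SNPs.
#' @param panel a \code{\linkS4class{SNPPanel}}.
#' @param r2_max flag threshold quantifying "strong LD" (default 0.8).
#' @param strict drop the later-ranked SNP of every flagged pair.
#' @return list with \code{r2} (named matrix), \code{flags}
#'   (\code{data.frame} of flagged pairs) and \code{panel} (pruned when
#'   \code{strict}).
#' @export
ldPruneCheck <- function(x, panel, r2_max = 0.8, strict = FALSE) {
  e <- panelEntries(panel)
  missing <- setdiff(e$variant, rownames(x))
  if (length(missing))
    stop("panel SNP(s) absent from genotype matrix: ",
         paste(missing, collapse = ", "))
  d <- dosages(x)[e$variant, , drop = FALSE]
  r2 <- suppressWarnings(
    stats::cor(t(d), use = "pairwise.complete.obs")^2)
  dimnames(r2) <- list(e$variant, e$variant)
  ij <- which(upper.tri(r2), arr.ind = TRUE)
  flagged <- ij[!is.na(r2[ij]) & r2[ij] > r2_max, , drop = FALSE]
  flags <- data.frame(
    snp1 = e$variant[flagged[, 1]], snp2 = e$variant[flagged[, 2]],
    r2 = r2[flagged], stringsAsFactors = FALSE)
  out_panel <- panel
  if (strict && nrow(flags)) {
    drop_idx <- unique(pmax(flagged[, 1], flagged[, 2]))
    out_panel@entries <- panel@entries[-drop_idx, ]
  }
  out_panel@params$r2_max <- r2_max
  list(r2 = r2, flags = flags, panel = out_panel)
}

#' Write / read a panel exchange file
#'
#' The TSV panel file (chrom, pos, rsid, ref, alt, risk_allele, weight,
#' p_stage1, p_stage2, risk_freq) is the exchange format between selection
#' and scoring.
#'
#' @param panel a \code{\linkS4class{SNPPanel}}.
#' @param path TSV path.
#' @export
writePanel <- function(panel, path) {
  writeTsv(panelEntries(panel), path)
}

#' @rdname writePanel
#' @export
readPanel <- function(path) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"variant" %in% names(e))
    e$variant <- paste(e$chrom, e$pos, e$ref, e$alt, sep = ":")
  if (!"risk_freq" %in% names(e)) e$risk_freq <- NA_real_
  if (!"or_stage1" %in% names(e)) e$or_stage1 <- exp(e$weight)
  new("SNPPanel", entries = DataFrame(e), params = list())
}
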