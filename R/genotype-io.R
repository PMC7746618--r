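#' Read a multi-sample VCF of biallelic SNPs into a GenotypeMatrix
#'
#' Loads GT fields from a VCF v4.x file, encoding each genotype as the count
#' of ALT alleles (0/1/2) with \code{./.} as missing. Multiallelic records
#' are rejected (split them upstream, e.g. with \code{bcftools norm});
#' non-SNP (indel) records are dropped with a warning. The INFO keys
#' \code{QD}, \code{FS}, \code{MQ}, \code{MQRankSum}, \code{ReadPosRankSum}
#' are carried into the variant metadata when present, as are \code{GENE}
#' and \code{REGION} annotation keys. Variant order is preserved.
#'
#' @param path path to an (uncompressed or gzipped) VCF file.
#' @param sex optional per-sample sex (\code{"male"}/\code{"female"}), a
#'   vector named by sample id or in VCF sample order; \code{NA} if unknown.
#' @return a \code{\linkS4class{GenotypeMatrix}}.
#' @export
readGenotypeVcf <- function(path, sex = NA_character_) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE),
    error = function(e)
      stop("VCF parse error in '", path, "': ", conditionMessage(e),
           call. = FALSE))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi))
    stop("multiallelic record(s) rejected (split upstream): ",
         paste(sprintf("%s:%s", fix[multi, "CHROM"], fix[multi, "POS"]),
               collapse = ", "))
  snp <- nchar(fix[, "REF"]) == 1L & nchar(alt) == 1L &
    fix[, "REF"] %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (any(!snp)) {
    warning(sum(!snp), " non-SNP record(s) dropped")
    vcf <- vcf[snp, ]
    fix <- fix[snp, , drop = FALSE]
  }
  if (nrow(fix) == 0L) stop("no biallelic SNP records in '", path, "'")

  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))
  dos[gt %in% c("0/0")] <- 0
  dos[gt %in% c("0/1", "1/0")] <- 1
  dos[gt %in% c("1/1")] <- 2
  unknown <- !is.na(gt) & !(gt %in% c("0/0", "0/1", "1/0", "1/1", "./."))
  if (any(unknown))
    stop("unparseable GT value(s), e.g. '", gt[unknown][1], "'")

  getInfo <- function(key) {
    v <- suppressWarnings(
      vcfR::extract.info(vcf, element = key, as.numeric = TRUE))
    if (is.null(v) || length(v) == 0L) rep(NA_real_, nrow(fix)) else v
  }
  getInfoChr <- function(key) {
    v <- vcfR::extract.info(vcf, element = key)
    if (is.null(v) || length(v) == 0L) rep(NA_character_, nrow(fix)) else v
  }
  variants <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    rsid = ifelse(is.na(fix[, "ID"]), ".", fix[, "ID"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    gene = getInfoChr("GENE"), region = getInfoChr("REGION"),
    QD = getInfo("QD"), FS = getInfo("FS"), MQ = getInfo("MQ"),
    MQRankSum = getInfo("MQRankSum"),
    ReadPosRankSum = getInfo("ReadPosRankSum"),
    stringsAsFactors = FALSE)

  samples <- colnames(gt)
  if (!is.null(names(sex)) && length(sex) > 1L) sex <- sex[samples]
  dimnames(dos) <- list(NULL, samples)
  GenotypeMatrix(dos, variants, sex = sex)
}

#' Write a GenotypeMatrix to a VCF v4.2 file
#'
#' Emits one biallelic SNP record per variant with GT genotypes
#' (\code{./.} for missing calls) and the quality / annotation INFO keys
#' that are present. Round-trips through \code{\link{readGenotypeVcf}}.
#'
#' @param x a \code{\linkS4class{GenotypeMatrix}}.
#' @param path output file path (plain text).
#' @return \code{path}, invisibly.
#' @export
writeGenotypeVcf <- function(x, path) {
  stopifnot(is(x, "GenotypeMatrix"))
  v <- variantInfo(x)
  d <- dosages(x)
  info_keys <- c(QD = "Float", FS = "Float", MQ = "Float",
                 MQRankSum = "Float", ReadPosRankSum = "Float",
                 GENE = "String", REGION = "String")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=kdwgrs",
           sprintf('##INFO=<ID=%s,Number=1,Type=%s,Description="%s">',
                   names(info_keys), info_keys, names(info_keys)),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(x)), collapse = "\t"))
  fmtNum <- function(val) sub("\\.?0+$", "", sprintf("%.4f", val))
  info <- vapply(seq_len(nrow(v)), function(i) {
    parts <- character()
    for (k in c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum"))
      if (!is.na(v[[k]][i]))
        parts <- c(parts, sprintf("%s=%s", k, fmtNum(v[[k]][i])))
    if (!is.na(v$gene[i])) parts <- c(parts, sprintf("GENE=%s", v$gene[i]))
    if (!is.na(v$region[i]))
      parts <- c(parts, sprintf("REGION=%s", v$region[i]))
    if (length(parts)) paste(parts, collapse = ";") else "."
  }, character(1))
  gt <- matrix(c("0/0", "0/1", "1/1")[d + 1L], nrow = nrow(d))
  gt[is.na(d)] <- "./."
  body <- paste(v$chrom, v$pos, v$rsid, v$ref, v$alt, ".", ".", info, "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' GATK-style hard filtering of variants by quality annotations
#'
#' Removes a variant when any filter clause is true:
#' \code{QD < 2.0}, \code{FS > 60.0}, \code{MQ < 40.0},
#' \code{MQRankSum < -12.5}, \code{ReadPosRankSum < -8.0}.
#' An absent (NA) annotation never fails its clause — the rank-sum
#' annotations are undefined at sites without heterozygous calls, and
#' discarding those sites would be wrong. All surviving variants keep their
#' order. The per-variant report of failing clauses is stored in
#' \code{metadata(result)$filter_report} (see \code{\link{filterReport}}).
#'
#' @param x a \code{\linkS4class{GenotypeMatrix}} with quality annotations.
#' @return the filtered \code{GenotypeMatrix}.
#' @export
hardFilterVariants <- function(x) {
  stopifnot(is(x, "GenotypeMatrix"))
  v <- variantInfo(x)
  clause <- function(val, test) !is.na(val) & test(val)
  fails <- cbind(
    "QD <2.0"              = clause(v$QD, function(z) z < 2.0),
    "FS >60.0"             = clause(v$FS, function(z) z > 60.0),
    "MQ <40.0"             = clause(v$MQ, function(z) z < 40.0),
    "MQRankSum < -12.5"    = clause(v$MQRankSum, function(z) z < -12.5),
    "ReadPosRankSum < -8.0" = clause(v$ReadPosRankSum, function(z) z < -8.0))
  removed <- rowSums(fails) > 0L
  report <- data.frame(
    variant = rownames(v), rsid = v$rsid, removed = removed,
    clauses = apply(fails, 1L, function(f)
      paste(colnames(fails)[f], collapse = " || ")),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- x[!removed, ]
  out <- as(out, "GenotypeMatrix")
  metadata(out)$filter_report <- report
  out
}

#' Retrieve the hard-filter report
#'
#' @param x a \code{GenotypeMatrix} produced by
#'   \code{\link{hardFilterVariants}}.
#' @return \code{data.frame} with one row per pre-filter variant: its key,
#'   rsid, whether it was removed, and the failing clause(s).
#' @export
filterReport <- function(x) {
  rep <- metadata(x)$filter_report
  if (is.null(rep)) stop("no filter report: run hardFilterVariants() first")
  rep
}

#' Allele frequencies for one variant
#'
#' Computes the ALT-allele frequency over non-missing diploid genotypes,
#' \eqn{\hat p = \sum G / (2 n)}, and the minor allele frequency
#' \eqn{\min(\hat p, 1 - \hat p)}. Chromosome Y sites use the same diploid
#' coding as everything else (the genotyper called them diploid); use
#' \code{\link{genotypeFrequencies}} for the sex-stratified view.
#'
#' @param x a \code{\linkS4class{GenotypeMatrix}}.
#' @param variant variant index or key (row name).
#' @return list with \code{alt_freq}, \code{maf} and \code{n_alleles}
#'   (number of non-missing allele observations).
#' @export
computeMaf <- function(x, variant) {
  d <- dosages(x)[variant, ]
  d <- d[!is.na(d)]
  if (length(d) == 0L)
    stop("allele frequency undefined: all genotypes missing for variant ",
         variant)
  alt_freq <- sum(d) / (2 * length(d))
  list(alt_freq = alt_freq, maf = min(alt_freq, 1 - alt_freq),
       n_alleles = 2L * length(d))
}

# vectorised ALT frequency / MAF over all variants (NAs excluded per row)
altFreqs <- function(x) {
  d <- dosages(x)
  n <- rowSums(!is.na(d))
  af <- rowSums(d, na.rm = TRUE) / (2 * n)
  af[n == 0L] <- NA_real_
  af
}

#' Orient dosages to count the risk allele
#'
#' The risk allele of a SNP is the allele with odds ratio above 1 in the
#' discovery comparison. When the risk allele is ALT the dosage is
#' unchanged; when it is REF the dosage is reflected, \eqn{G \to 2 - G}
#' (missing stays missing). Applying the transform twice returns the
#' original dosages.
#'
#' @param dosage numeric vector or matrix of ALT-allele counts.
#' @param risk_allele \code{"alt"} or \code{"ref"} (recycled over rows when
#'   \code{dosage} is a matrix).
#' @return oriented dosage of the same shape.
#' @export
orientDosages <- function(dosage, risk_allele) {
  if (!all(risk_allele %in% c("ref", "alt")))
    stop("risk_allele must be 'ref' or 'alt'")
  if (is.matrix(dosage)) {
    flip <- rep_len(risk_allele, nrow(dosage)) == "ref"
    dosage[flip, ] <- 2 - dosage[flip, , drop = FALSE]
    dosage
  } else {
    if (risk_allele[1] == "ref") 2 - dosage else dosage
  }
}

#' Sex-stratified genotype frequencies for one variant
#'
#' Reports the relative frequencies of the 0/1/2 genotype classes overall
#' and within each sex — the view in which diploid-coded Y-chromosome sites
#' should be inspected.
#'
#' @param x a \code{\linkS4class{GenotypeMatrix}} with known sample sex.
#' @param variant variant index or key.
#' @return \code{data.frame} with rows \code{all}/\code{male}/\code{female}
#'   and columns \code{g0}, \code{g1}, \code{g2}, \code{n}.
#' @export
genotypeFrequencies <- function(x, variant) {
  d <- dosages(x)[variant, ]
  sx <- sampleSex(x)
  row <- function(keep) {
    dd <- d[keep & !is.na(d)]
    n <- length(dd)
    c(g0 = mean(dd == 0), g1 = mean(dd == 1), g2 = mean(dd == 2), n = n)
  }
  out <- rbind(all = row(rep(TRUE, length(d))),
               male = row(!is.na(sx) & sx == "male"),
               female = row(!is.na(sx) & sx == "female"))
  as.data.frame(out)
}

#' Read / write phenotype and clinical tables
#'
#' Phenotype tables are TSVs with header \code{sample_id}, \code{group}
#' (\code{nonresponder} / \code{responder} / \code{control}), \code{sex},
#' \code{age_months}. Clinical tables are TSVs with \code{sample_id} plus
#' one numeric column per laboratory variable; empty fields and \code{NA}
#' are missing values.
#'
#' @param path TSV file path.
#' @return a \code{data.frame}.
#' @export
readPhenotypeTable <- function(path) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "sex", "age_months")
  miss <- setdiff(need, names(ph))
  if (length(miss))
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(ph$group), c("nonresponder", "responder", "control"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(ph$sample_id)) stop("duplicated sample_id")
  if (any(ph$age_months < 0, na.rm = TRUE)) stop("negative age_months")
  ph
}

#' @rdname readPhenotypeTable
#' @export
readClinicalTable <- function(path) {
  cl <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(cl))
    stop("clinical table lacks a sample_id column")
  num <- setdiff(names(cl), "sample_id")
  for (v in num) {
    cl[[v]] <- suppressWarnings(as.numeric(cl[[v]]))
    if (any(is.infinite(cl[[v]]), na.rm = TRUE))
      stop("non-finite values in clinical variable ", v)
  }
  cl
}

#' @rdname readPhenotypeTable
#' @param x a \code{data.frame} to serialize.
#' @export
writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
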