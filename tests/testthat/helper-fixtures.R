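# shared fixture builders; everything is generated in code

# small GenotypeMatrix from a dosage matrix (variants x samples)
makeGM <- function(dosage, chrom = NULL, pos = NULL, ref = "A", alt = "G",
                   sex = "female", qual = list()) {
  dosage <- as.matrix(dosage)
  nv <- nrow(dosage)
  v <- data.frame(
    chrom = if (is.null(chrom)) rep("1", nv) else chrom,
    pos = if (is.null(pos)) seq_len(nv) * 100L else pos,
    rsid = sprintf("rs%03d", seq_len(nv)),
    ref = rep_len(ref, nv), alt = rep_len(alt, nv),
    stringsAsFactors = FALSE)
  for (k in names(qual)) v[[k]] <- qual[[k]]
  GenotypeMatrix(dosage, v, sex = sex)
}

# phenotype table for a dosage-matrix fixture
makePheno <- function(gm, groups) {
  data.frame(sample_id = colnames(gm), group = groups,
             sex = unname(sampleSex(gm)), age_months = 30,
             stringsAsFactors = FALSE)
}

# a panel straight from entry values, bypassing selection
makePanel <- function(chrom, pos, ref, alt, risk_allele, weight,
                      p1 = 1e-4, p2 = 1e-3, risk_freq = NA_real_) {
  n <- length(weight)
  e <- S4Vectors::DataFrame(
    variant = paste(chrom, pos, ref, alt, sep = ":"),
    chrom = as.character(chrom), pos = as.integer(pos),
    rsid = sprintf("rs%03d", seq_len(n)), ref = ref, alt = alt,
    risk_allele = risk_allele, weight = weight,
    or_stage1 = exp(ifelse(risk_allele == "alt", weight, -weight)),
    p_stage1 = rep_len(p1, n), p_stage2 = rep_len(p2, n),
    risk_freq = rep_len(risk_freq, n))
  new("SNPPanel", entries = e,
      params = list(maf_min = 0.01, alpha_stage = 0.05, p_final = 3e-3,
                    k_max = n, r2_max = 0.8))
}

# panel derived from a synthetic cohort's ground truth (true weights)
truthPanel <- function(cohort) {
  tr <- cohortTruth(cohort)
  w <- abs(log(tr$or))
  keep <- w > 0
  tr <- tr[keep, ]
  e <- S4Vectors::DataFrame(
    variant = tr$variant, chrom = tr$chrom,
    pos = as.integer(sub("^[^:]+:(\\d+):.*$", "\\1", tr$variant)),
    rsid = tr$rsid,
    ref = sub("^[^:]+:\\d+:([ACGT]):.*$", "\\1", tr$variant),
    alt = sub(".*:([ACGT])$", "\\1", tr$variant),
    risk_allele = tr$risk_allele, weight = abs(log(tr$or)),
    or_stage1 = tr$or, p_stage1 = 1e-4, p_stage2 = 1e-3,
    risk_freq = ifelse(tr$risk_allele == "alt", tr$freq_control,
                       1 - tr$freq_control))
  new("SNPPanel", entries = e, params = list())
}

# text of a small valid VCF
toyVcfLines <- function() {
  c("##fileformat=VCFv4.2",
    '##INFO=<ID=QD,Number=1,Type=Float,Description="QD">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "A1", "A2", "A3", sep = "\t"),
    paste("1", "100", "rs1", "A", "G", ".", ".", "QD=20", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "200", "rs2", "C", "T", ".", ".", "QD=15", "GT",
          "./.", "0/1", "0/0", sep = "\t"))
}
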