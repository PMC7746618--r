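#' Default clinical-variable parameters
#'
#' Per-variable group means, shared SD, and per-group missingness fractions
#' for the laboratory variables of the study cohort (IVIG non-responders vs
#' responders): fever duration, platelet count, C-reactive protein, albumin,
#' erythrocyte sedimentation rate, hemoglobin, neutrophil and lymphocyte
#' percentages and counts, total protein, bilirubin, creatine kinase,
#' calcium, phosphate, ferritin, BNP, IL-2 receptor, IgM, CH50 and C1.
#' One SD is printed per variable and is used for both groups.
#'
#' @return \code{data.frame} with columns \code{variable}, \code{mean_nr},
#'   \code{mean_r}, \code{sd}, \code{miss_nr}, \code{miss_r} (fractions).
#' @export
kdClinicalParams <- function() {
  p <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
variable    mean_nr  mean_r   sd       miss_nr miss_r
Fever_days  11.91    7.79     2.96     0.10    0.0286
PLT         315.46   361.38   121.27   0.12    0.0393
CRP         103.78   65.59    46.04    0.14    0.0357
ALB         33.62    36.22    3.86     0.16    0.0607
ESR         71.15    88.24    29.13    0.18    0.0786
Hb          105.81   109.55   10.59    0.20    0.1321
NE_pct      72.96    64.82    15.69    0.28    0.0393
HCT         31.36    32.51    2.86     0.30    0.0429
LY_pct      19.85    26.17    13.06    0.30    0.0393
LYM         2.62     3.52     2.05     0.30    0.0464
TP          59.00    63.37    6.29     0.32    0.0643
TBil        18.56    9.80     12.61    0.40    0.1607
CK          34.59    56.73    66.16    0.42    0.1786
Ca          2.22     2.29     0.12     0.50    0.2500
P           1.07     1.30     0.28     0.50    0.2536
SF          218.00   149.99   90.26    0.56    0.3429
BNP         2975.17  782.36   1210.82  0.60    0.3679
IL2R        84383.11 43036.82 48547.54 0.72    0.4893
IgM         0.84     1.12     0.49     0.74    0.6357
CH50        50.19    58.98    9.37     0.78    0.6393
C1          173.67   207.37   53.43    0.80    0.0286
")
  p
}

#' Default planted risk SNPs
#'
#' The 14 loci used as the generator's planted effects: chromosome,
#' position, rsid, nearby gene, functional region, REF/ALT alleles, the
#' baseline ALT-allele frequency and the allelic odds ratio (ALT vs REF) of
#' the non-responder vs responder comparison. ORs below 1 mark loci whose
#' ALT allele is protective (the REF allele is then the risk allele). The
#' three chromosome-Y loci are generated in the same diploid coding the
#' genotyper emitted.
#'
#' By default the same allelic OR is planted against the healthy-control
#' group, so that both selection stages see the signal; per-SNP
#' \code{or_control} can be edited before passing the table to
#' \code{\link{cohortSpec}}.
#'
#' @return \code{data.frame} with one row per planted SNP.
#' @export
kdPlantedSnps <- function() {
  s <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
chrom pos       rsid        gene   region         ref alt base_freq or
1     40229368  rs2463260   PPIE   exonic         A   G   0.06      3.35
1     167408670 rs840016    CD247  intronic       C   T   0.02      3.77
3     38534142  rs77317995  ACVR2B UTR3           T   A   0.36      0.46
5     180053090 rs56401579  FLT4   intronic       G   A   0.04      3.33
5     180053097 rs56193546  FLT4   intronic       C   T   0.04      3.33
7     148480990 rs10271133  CUL1   intronic       C   T   0.05      3.58
7     148487395 rs2007404   CUL1   intronic       T   C   0.11      2.62
10    6066195   rs12358961  IL2RA  intronic       T   A   0.07      2.94
15    66727597  rs16949924  MAP2K1 intronic       G   C   0.05      2.97
20    36989335  rs2232595   LBP    intronic       C   T   0.02      3.74
22    50705059  rs742185    MAPK11 intronic       A   G   0.09      2.87
Y     21153275  rs6530599   CD24   ncRNA_intronic A   G   0.57      0.55
Y     21153459  rs6530600   CD24   ncRNA_intronic A   G   0.57      0.55
Y     21153474  rs1136210   CD24   ncRNA_intronic A   G   0.57      0.55
")
  s$or_control <- s$or
  s
}

#' Specification of a synthetic case-control cohort
#'
#' Collects every generator parameter: group sizes (default 50 IVIG
#' non-responders, 280 responders, 105 healthy controls), male fraction
#' (default 211/330), per-group age distributions in months, the number of
#' null background SNPs, the planted SNP table, the clinical-variable
#' parameters, and the RNG seed. A single seed governs a hierarchical
#' stream (genotypes / clinical / sex / age) so each sub-generator is
#' independently reproducible.
#'
#' @param n_nonresponder,n_responder,n_control group sizes.
#' @param male_fraction probability a sample is male.
#' @param age_params named list of \code{c(mean, sd)} in months per group.
#' @param n_null_snps number of background SNPs with identical allele
#'   frequency in all groups (frequencies drawn uniformly on
#'   \code{null_freq_range}).
#' @param null_freq_range range of baseline frequencies for null SNPs.
#' @param planted \code{data.frame} like \code{\link{kdPlantedSnps}()}:
#'   columns \code{chrom}, \code{pos}, \code{rsid}, \code{ref}, \code{alt},
#'   \code{base_freq} (baseline ALT frequency in responders and, via
#'   \code{or_control}, controls), \code{or} (allelic OR, non-responders vs
#'   responders), \code{or_control} (allelic OR, non-responders vs
#'   controls); optional \code{gene}, \code{region}. \code{NULL} for none.
#' @param clinical_params \code{data.frame} like
#'   \code{\link{kdClinicalParams}()}; \code{NULL} for no clinical table.
#' @param seed integer RNG seed.
#' @return a validated \code{cohort_spec} list.
#' @export
cohortSpec <- function(n_nonresponder = 50L, n_responder = 280L,
                       n_control = 105L, male_fraction = 211 / 330,
                       age_params = list(nonresponder = c(30.5, 24.5),
                                         responder = c(34.3, 27.3),
                                         control = c(34.3, 27.3)),
                       n_null_snps = 500L,
                       null_freq_range = c(0.05, 0.5),
                       planted = kdPlantedSnps(),
                       clinical_params = kdClinicalParams(),
                       seed = 1L) {
  spec <- list(n_nonresponder = as.integer(n_nonresponder),
               n_responder = as.integer(n_responder),
               n_control = as.integer(n_control),
               male_fraction = male_fraction, age_params = age_params,
               n_null_snps = as.integer(n_null_snps),
               null_freq_range = null_freq_range,
               planted = planted, clinical_params = clinical_params,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validateCohortSpec(spec)
  spec
}

validateCohortSpec <- function(spec) {
  with(spec, {
    if (any(c(n_nonresponder, n_responder, n_control) < 1L))
      stop("invalid spec: all group sizes must be >= 1")
    if (male_fraction < 0 || male_fraction > 1)
      stop("invalid spec: male_fraction outside [0, 1]")
    if (!is.null(planted) && nrow(planted)) {
      if (any(planted$base_freq <= 0 | planted$base_freq >= 1))
        stop("invalid spec: planted base_freq outside (0, 1)")
      if (any(planted$or <= 0) || any(planted$or_control <= 0))
        stop("invalid spec: odds ratios must be > 0")
    }
    if (!is.null(clinical_params) && nrow(clinical_params)) {
      if (any(clinical_params$sd < 0))
        stop("invalid spec: negative clinical sd")
      if (any(clinical_params$miss_nr < 0 | clinical_params$miss_nr >= 1 |
              clinical_params$miss_r < 0 | clinical_params$miss_r >= 1))
        stop("invalid spec: missingness outside [0, 1)")
    }
  })
  invisible(spec)
}

# sub-seeds of the hierarchical stream; stream in 1..5
subSeed <- function(seed, stream) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(2147483646L, 5L)[stream]
}

#' Case-group allele frequency implied by an allelic odds ratio
#'
#' For baseline (control-arm) allele frequency \eqn{p} and target allelic
#' odds ratio OR, the case-arm frequency is
#' \eqn{p' = \mathrm{OR}\,p / (1 + p(\mathrm{OR} - 1))}.
#'
#' @param p baseline allele frequency in (0, 1).
#' @param or allelic odds ratio (> 0).
#' @return the case-group allele frequency.
#' @export
riskFreq <- function(p, or) {
  out <- (or * p) / (1 + p * (or - 1))
  if (any(out <= 0 | out >= 1))
    stop("invalid spec: derived case allele frequency outside (0, 1)")
  out
}

#' Simulate genotypes for a cohort specification
#'
#' Null SNPs draw Hardy-Weinberg genotypes at one frequency shared by all
#' groups; planted SNPs use the baseline frequency for responders, the
#' frequency implied by the target allelic OR (\code{\link{riskFreq}}) for
#' non-responders, and the frequency implied by \code{or_control} for
#' healthy controls. Quality annotations are drawn from passing ranges so
#' the default cohort survives \code{\link{hardFilterVariants}} intact.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @return list with \code{genotype} (a
#'   \code{\linkS4class{GenotypeMatrix}}), \code{groups} (per-sample group
#'   labels) and \code{truth} (per-planted-SNP generating parameters).
#' @export
simulateGenotypes <- function(spec) {
  validateCohortSpec(spec)
  set.seed(subSeed(spec$seed, 1L))
  n <- c(nonresponder = spec$n_nonresponder, responder = spec$n_responder,
         control = spec$n_control)
  groups <- rep(names(n), n)
  ntot <- sum(n)

  planted <- spec$planted
  n_planted <- if (is.null(planted)) 0L else nrow(planted)
  n_null <- spec$n_null_snps

  null_freq <- if (n_null)
    stats::runif(n_null, spec$null_freq_range[1], spec$null_freq_range[2])
  else numeric()

  freq_by_group <- matrix(NA_real_, nrow = n_planted + n_null, ncol = 3L,
                          dimnames = list(NULL, names(n)))
  if (n_planted) {
    p_resp <- planted$base_freq
    odds_case <- local({
      pc <- riskFreq(p_resp, planted$or)
      pc / (1 - pc)
    })
    p_case <- odds_case / (1 + odds_case)
    odds_ctrl <- odds_case / planted$or_control
    p_ctrl <- odds_ctrl / (1 + odds_ctrl)
    freq_by_group[seq_len(n_planted), ] <- cbind(p_case, p_resp, p_ctrl)
  }
  if (n_null)
    freq_by_group[n_planted + seq_len(n_null), ] <-
      matrix(null_freq, nrow = n_null, ncol = 3L)

  dos <- matrix(NA_real_, nrow = n_planted + n_null, ncol = ntot)
  for (g in names(n)) {
    idx <- which(groups == g)
    dos[, idx] <- stats::rbinom(length(idx) * nrow(dos), 2L,
                                rep(freq_by_group[, g], length(idx)))
  }

  nv <- nrow(dos)
  variants <- data.frame(
    chrom = c(if (n_planted) as.character(planted$chrom),
              if (n_null) as.character(sample(1:22, n_null, replace = TRUE))),
    pos = c(if (n_planted) planted$pos,
            if (n_null) sample.int(5e7, n_null)),
    rsid = c(if (n_planted) planted$rsid,
             if (n_null) sprintf("null_%04d", seq_len(n_null))),
    ref = c(if (n_planted) planted$ref,
            if (n_null) sample(c("A", "C", "G", "T"), n_null, replace = TRUE)),
    alt = "N", gene = NA_character_, region = NA_character_,
    QD = stats::runif(nv, 10, 35), FS = stats::runif(nv, 0, 20),
    MQ = stats::runif(nv, 50, 60), MQRankSum = stats::runif(nv, -3, 3),
    ReadPosRankSum = stats::runif(nv, -3, 3), stringsAsFactors = FALSE)
  if (n_planted) {
    variants$alt[seq_len(n_planted)] <- planted$alt
    if ("gene" %in% names(planted))
      variants$gene[seq_len(n_planted)] <- planted$gene
    if ("region" %in% names(planted))
      variants$region[seq_len(n_planted)] <- planted$region
  }
  # give null SNPs an alt differing from ref
  null_rows <- n_planted + seq_len(n_null)
  if (n_null) {
    alts <- vapply(variants$ref[null_rows], function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
    variants$alt[null_rows] <- alts
  }
  # avoid duplicate null positions colliding with planted keys
  variants$pos <- as.integer(variants$pos)

  sex <- simulateSex(spec, groups)
  gm <- GenotypeMatrix(dos, variants,
                       sex = stats::setNames(sex, NULL))
  colnames(gm) <- sprintf("S%04d", seq_len(ntot))

  truth <- if (n_planted)
    DataFrame(variant = variantKeys(variants[seq_len(n_planted), ]),
              rsid = planted$rsid, chrom = as.character(planted$chrom),
              base_freq = planted$base_freq,
              freq_nonresponder = freq_by_group[seq_len(n_planted), 1L],
              freq_control = freq_by_group[seq_len(n_planted), 3L],
              or = planted$or, or_control = planted$or_control,
              risk_allele = ifelse(planted$or >= 1, "alt", "ref"))
  else DataFrame(variant = character(), rsid = character(),
                 chrom = character(), base_freq = numeric(),
                 freq_nonresponder = numeric(), freq_control = numeric(),
                 or = numeric(), or_control = numeric(),
                 risk_allele = character())
  list(genotype = gm, groups = groups, truth = truth)
}

simulateSex <- function(spec, groups) {
  set.seed(subSeed(spec$seed, 3L))
  ifelse(stats::runif(length(groups)) < spec$male_fraction, "male", "female")
}

simulateAges <- function(spec, groups) {
  set.seed(subSeed(spec$seed, 4L))
  ap <- spec$age_params
  age <- numeric(length(groups))
  for (g in unique(groups)) {
    idx <- groups == g
    age[idx] <- pmax(stats::rnorm(sum(idx), ap[[g]][1], ap[[g]][2]), 0)
  }
  round(age, 1)
}

#' Simulate the clinical laboratory table
#'
#' Each variable is drawn from a group-specific normal with the configured
#' mean and (shared) SD, then masked missing completely at random: within
#' each group a fixed number of samples, \code{round(rate * n)}, is masked
#' at uniformly random positions, so every simulated cohort reproduces the
#' configured per-group missingness percentages exactly (the rates are
#' observed properties of the emulated cohort, not sampling
#' probabilities). Only the two patient groups receive clinical values;
#' laboratory panels were not part of the healthy-control workup.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @param sample_ids,groups sample ids and group labels (patients are the
#'   \code{nonresponder} / \code{responder} samples); when omitted, ids and
#'   groups are laid out exactly as \code{\link{simulateCohort}} does.
#' @return \code{data.frame}: \code{sample_id} plus one column per
#'   variable; \code{NA} marks masked values.
#' @export
simulateClinical <- function(spec, sample_ids = NULL, groups = NULL) {
  validateCohortSpec(spec)
  if (is.null(groups))
    groups <- rep(c("nonresponder", "responder", "control"),
                  c(spec$n_nonresponder, spec$n_responder, spec$n_control))
  if (is.null(sample_ids))
    sample_ids <- sprintf("S%04d", seq_along(groups))
  set.seed(subSeed(spec$seed, 2L))
  patient <- groups %in% c("nonresponder", "responder")
  ids <- sample_ids[patient]
  grp <- groups[patient]
  cp <- spec$clinical_params
  out <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  if (is.null(cp) || !nrow(cp)) return(out)
  for (i in seq_len(nrow(cp))) {
    mu <- ifelse(grp == "nonresponder", cp$mean_nr[i], cp$mean_r[i])
    val <- stats::rnorm(length(ids), mu, cp$sd[i])
    for (g in c("nonresponder", "responder")) {
      idx <- which(grp == g)
      rate <- if (g == "nonresponder") cp$miss_nr[i] else cp$miss_r[i]
      n_miss <- round(rate * length(idx))
      if (n_miss > 0L)
        val[sample(idx, n_miss)] <- NA_real_
    }
    out[[cp$variable[i]]] <- val
  }
  out
}

#' Simulate a full synthetic cohort
#'
#' Composes the genotype, clinical, sex and age generators into a
#' \code{\linkS4class{SyntheticCohort}}. The same seed always produces an
#' identical cohort (and identical serialized files via
#' \code{\link{writeCohort}}).
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @return a \code{\linkS4class{SyntheticCohort}}.
#' @examples
#' co <- simulateCohort(cohortSpec(n_null_snps = 10L, seed = 7L))
#' co
#' @export
simulateCohort <- function(spec) {
  g <- simulateGenotypes(spec)
  groups <- g$groups
  ids <- colnames(g$genotype)
  phenotype <- DataFrame(sample_id = ids, group = groups,
                         sex = unname(sampleSex(g$genotype)),
                         age_months = simulateAges(spec, groups))
  clinical <- DataFrame(simulateClinical(spec, ids, groups),
                        check.names = FALSE)
  new("SyntheticCohort", genotype = g$genotype, phenotype = phenotype,
      clinical = clinical, truth = g$truth, spec = unclass(spec))
}

#' Serialize a synthetic cohort to disk
#'
#' Writes \code{genotypes.vcf}, \code{phenotype.tsv}, \code{clinical.tsv}
#' and \code{truth.tsv} into a directory.
#'
#' @param cohort a \code{\linkS4class{SyntheticCohort}}.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "SyntheticCohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGenotypeVcf(cohortGenotype(cohort), file.path(dir, "genotypes.vcf"))
  writeTsv(cohortPhenotype(cohort), file.path(dir, "phenotype.tsv"))
  writeTsv(cohortClinical(cohort), file.path(dir, "clinical.tsv"))
  writeTsv(cohortTruth(cohort), file.path(dir, "truth.tsv"))
  invisible(dir)
}
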