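test_that("VCF genotypes become ALT-allele dosages with ./. as missing", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(toyVcfLines(), path)
  gm <- readGenotypeVcf(path, sex = c("male", "female", "female"))
  d <- dosages(gm)
  expect_equal(unname(d[1, ]), c(0, 1, 2))
  expect_equal(unname(d[2, ]), c(NA, 1, 0))
  # missing excluded from allele counts
  expect_equal(computeMaf(gm, 2)$n_alleles, 4L)
  expect_equal(computeMaf(gm, 2)$alt_freq, 0.25)
  expect_equal(variantInfo(gm)$QD, c(20, 15))
})

test_that("multiallelic records are rejected with the offending record named", {
  path <- withr::local_tempfile(fileext = ".vcf")
  lines <- toyVcfLines()
  lines[5] <- paste("1", "100", "rs1", "A", "G,T", ".", ".", "QD=20", "GT",
                    "0/0", "0/1", "1/1", sep = "\t")
  writeLines(lines, path)
  expect_error(readGenotypeVcf(path), "multiallelic.*1:100")
})

test_that("a simulated matrix round-trips through write/read VCF", {
  set.seed(42)
  d <- matrix(sample(c(0, 1, 2, NA), 20, replace = TRUE), nrow = 5)
  gm <- makeGM(d, chrom = c("1", "2", "3", "X", "Y"),
               pos = c(100L, 200L, 300L, 400L, 500L),
               ref = c("A", "C", "G", "T", "A"),
               alt = c("G", "T", "A", "C", "C"),
               qual = list(QD = c(10, 20, NA, 5, 8), FS = c(1, 2, 3, NA, 5)))
  path <- withr::local_tempfile(fileext = ".vcf")
  writeGenotypeVcf(gm, path)
  gm2 <- readGenotypeVcf(path)
  expect_equal(unname(dosages(gm2)), unname(dosages(gm)))
  v1 <- variantInfo(gm); v2 <- variantInfo(gm2)
  expect_equal(v2$chrom, v1$chrom)
  expect_equal(v2$pos, v1$pos)
  expect_equal(v2$ref, v1$ref)
  expect_equal(v2$alt, v1$alt)
  expect_equal(v2$QD, v1$QD)
  expect_equal(v2$FS, v1$FS)
})

test_that("hard filter removes variants per clause, keeps NA annotations, is idempotent", {
  qual <- list(QD = c(1.5, 10, 10, NA, 10),
               FS = c(3, 3, 3, 3, 3),
               MQ = c(60, 60, 60, 60, 60),
               MQRankSum = c(0, 0, -13, NA, 0),
               ReadPosRankSum = c(0, 0, 0, 0, -9))
  gm <- makeGM(matrix(0:1, nrow = 5, ncol = 4), qual = qual)
  out <- hardFilterVariants(gm)
  rep <- filterReport(out)
  expect_equal(nrow(out), 2L)           # variants 2 and 4 survive
  expect_true(rep$removed[1])
  expect_match(rep$clauses[1], "QD <2.0")
  expect_true(rep$removed[3])
  expect_match(rep$clauses[3], "MQRankSum < -12.5")
  expect_false(rep$removed[4])          # absent annotations never fail
  expect_true(rep$removed[5])
  expect_match(rep$clauses[5], "ReadPosRankSum < -8.0")
  # idempotence
  out2 <- hardFilterVariants(out)
  expect_equal(dosages(out2), dosages(out))
  expect_false(any(filterReport(out2)$removed))
})

test_that("allele frequencies follow the diploid definition", {
  gm <- makeGM(rbind(c(0, 1, 2, 1), c(0, 0, 0, 0), c(0, 2, NA, NA)))
  expect_equal(computeMaf(gm, 1), list(alt_freq = 0.5, maf = 0.5,
                                       n_alleles = 8L))
  expect_equal(computeMaf(gm, 2)$alt_freq, 0)
  expect_equal(computeMaf(gm, 2)$maf, 0)
  expect_equal(computeMaf(gm, 3)$alt_freq, 0.5)
  gm_all_na <- makeGM(matrix(NA_real_, 1, 3))
  expect_error(computeMaf(gm_all_na, 1), "all genotypes missing")
})

test_that("maf is bounded and invariant under sample permutation", {
  set.seed(1)
  for (i in 1:20) {
    d <- matrix(sample(c(0, 1, 2, NA), 30, replace = TRUE,
                       prob = c(.4, .3, .2, .1)), nrow = 3)
    if (all(is.na(d[1, ]))) next
    gm <- makeGM(d)
    m <- computeMaf(gm, 1)
    expect_gte(m$maf, 0); expect_lte(m$maf, 0.5)
    perm <- sample(ncol(d))
    gm_p <- makeGM(d[, perm, drop = FALSE])
    expect_equal(computeMaf(gm_p, 1)$alt_freq, m$alt_freq)
  }
})

test_that("risk-allele orientation reflects ref-risk dosages and is an involution", {
  expect_equal(orientDosages(c(0, 1, 2), "ref"), c(2, 1, 0))
  expect_equal(orientDosages(c(0, 1, 2), "alt"), c(0, 1, 2))
  d <- matrix(c(0, 1, 2, NA, 1, 0), nrow = 2)
  ra <- c("ref", "alt")
  expect_equal(orientDosages(orientDosages(d, ra), ra), d)
})

test_that("sex-stratified genotype frequencies are reported for diploid-coded Y sites", {
  d <- rbind(c(0, 1, 1, 2, 0, 1))
  gm <- makeGM(d, chrom = "Y",
               sex = c("male", "male", "male", "female", "female", "female"))
  gf <- genotypeFrequencies(gm, 1)
  expect_equal(gf["male", "g1"], 2 / 3)
  expect_equal(gf["female", "g2"], 1 / 3)
  expect_equal(gf["all", "n"], 6)
})

test_that("phenotype and clinical table readers validate structure", {
  ph <- data.frame(sample_id = c("a", "b"), group = c("responder", "control"),
                   sex = c("male", "female"), age_months = c(20, 30))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeTsv(ph, path)
  expect_equal(readPhenotypeTable(path), ph)
  ph_bad <- ph; ph_bad$group[1] <- "mystery"
  writeTsv(ph_bad, path)
  expect_error(readPhenotypeTable(path), "unknown group")
  cl <- data.frame(sample_id = c("a", "b"), CRP = c(100, NA))
  writeTsv(cl, path)
  expect_equal(readClinicalTable(path)$CRP, c(100, NA))
})
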