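test_that("case allele frequency follows the odds-ratio closed form", {
  expect_equal(riskFreq(0.2, 1), 0.2)
  expect_equal(riskFreq(0.2, 3), 0.6 / 1.4)
  expect_error(cohortSpec(planted = data.frame(
    chrom = "1", pos = 1L, rsid = "x", ref = "A", alt = "G",
    base_freq = 1.2, or = 2, or_control = 2)), "invalid spec")
})

test_that("invalid cohort specifications are rejected", {
  expect_error(cohortSpec(n_nonresponder = 0), "group sizes")
  cp <- kdClinicalParams(); cp$sd[1] <- -1
  expect_error(cohortSpec(clinical_params = cp), "negative clinical sd")
  cp <- kdClinicalParams(); cp$miss_nr[1] <- 1
  expect_error(cohortSpec(clinical_params = cp), "missingness")
  pl <- kdPlantedSnps(); pl$or[1] <- -2
  expect_error(cohortSpec(planted = pl), "odds ratios")
})

test_that("the default cohort has the study group sizes and is seed-deterministic", {
  spec <- cohortSpec(n_null_snps = 25L, seed = 7L)
  co1 <- simulateCohort(spec)
  co2 <- simulateCohort(spec)
  ph <- cohortPhenotype(co1)
  expect_equal(unname(table(ph$group)[c("nonresponder", "responder",
                                        "control")]),
               c(50L, 280L, 105L), ignore_attr = TRUE)
  expect_identical(dosages(cohortGenotype(co1)),
                   dosages(cohortGenotype(co2)))
  expect_identical(cohortClinical(co1), cohortClinical(co2))
  expect_identical(cohortPhenotype(co1), cohortPhenotype(co2))

  # serialized artifacts are byte-identical across runs
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeCohort(co1, d1); writeCohort(co2, d2)
  for (f in c("genotypes.vcf", "phenotype.tsv", "clinical.tsv", "truth.tsv"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
})

test_that("sex assignment matches the configured male fraction", {
  spec <- cohortSpec(n_nonresponder = 5000L, n_responder = 4000L,
                     n_control = 1000L, n_null_snps = 1L,
                     planted = NULL, clinical_params = NULL, seed = 11L)
  co <- simulateCohort(spec)
  frac <- mean(cohortPhenotype(co)$sex == "male")
  p <- 211 / 330
  se <- sqrt(p * (1 - p) / 10000)
  expect_lt(abs(frac - p), 3 * se)
})

test_that("clinical generator reproduces configured means, SDs and missingness", {
  cp <- data.frame(variable = c("CRP", "FLAT"),
                   mean_nr = c(103.78, 5), mean_r = c(65.59, 5),
                   sd = c(46.04, 0), miss_nr = c(0.14, 0),
                   miss_r = c(0.0357, 0))
  spec <- cohortSpec(n_nonresponder = 10000L, n_responder = 2000L,
                     n_control = 1L, n_null_snps = 1L, planted = NULL,
                     clinical_params = cp, seed = 5L)
  cl <- simulateClinical(spec)
  grp <- rep(c("nonresponder", "responder"), c(10000, 2000))
  crp_nr <- cl$CRP[grp == "nonresponder"]
  # mean within 3 standard errors of the configured value
  expect_lt(abs(mean(crp_nr, na.rm = TRUE) - 103.78),
            3 * 46.04 / sqrt(sum(!is.na(crp_nr))))
  # missingness within the binomial 99% CI around 0.14
  miss <- mean(is.na(crp_nr))
  expect_lt(abs(miss - 0.14), 2.576 * sqrt(0.14 * 0.86 / 10000))
  # sd = 0 gives the constant mean
  expect_true(all(cl$FLAT == 5))
})

test_that("planted SNPs obey Hardy-Weinberg proportions within each group", {
  pl <- data.frame(chrom = "1", pos = 1000L, rsid = "rsP", ref = "A",
                   alt = "G", base_freq = 0.3, or = 3, or_control = 3)
  spec <- cohortSpec(n_nonresponder = 4000L, n_responder = 4000L,
                     n_control = 4000L, n_null_snps = 0L, planted = pl,
                     clinical_params = NULL, seed = 9L)
  g <- simulateGenotypes(spec)
  d <- dosages(g$genotype)[1, ]
  for (grp in c("nonresponder", "responder", "control")) {
    dd <- d[g$groups == grp]
    p <- mean(dd) / 2
    exp_counts <- length(dd) * c((1 - p)^2, 2 * p * (1 - p), p^2)
    obs <- tabulate(dd + 1, 3)
    chi <- sum((obs - exp_counts)^2 / exp_counts)
    expect_lt(chi, qchisq(0.999, df = 1))   # 1 df: freq estimated
  }
  # planted case frequency is shifted as requested
  tr <- as.data.frame(g$truth)
  expect_equal(tr$freq_nonresponder, riskFreq(0.3, 3))
  expect_equal(tr$freq_control, 0.3)
})

test_that("null cohorts give uniform association p values", {
  spec <- cohortSpec(n_nonresponder = 400L, n_responder = 400L,
                     n_control = 2L, n_null_snps = 2000L, planted = NULL,
                     null_freq_range = c(0.1, 0.5),
                     clinical_params = NULL, seed = 13L)
  co <- simulateCohort(spec)
  scan <- associationScan(cohortGenotype(co), cohortPhenotype(co),
                          "nonresponder-vs-responder")
  p <- scan$p[!is.na(scan$p)]
  expect_gt(length(p), 1900)
  ks <- suppressWarnings(ks.test(p, "punif"))
  # 1% critical value of the one-sample KS statistic
  expect_lt(unname(ks$statistic), 1.63 / sqrt(length(p)))
})
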