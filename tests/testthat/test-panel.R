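toyScan <- function(p, or = NULL, maf = 0.2) {
  n <- length(p)
  data.frame(variant = sprintf("1:%d:A:G", seq_len(n) * 100),
             chrom = "1", pos = seq_len(n) * 100L,
             rsid = sprintf("s%d", seq_len(n)), ref = "A", alt = "G",
             gene = NA, region = NA, maf = rep_len(maf, n),
             alt_freq = rep_len(maf, n), order = seq_len(n),
             or = if (is.null(or)) rep(2, n) else or,
             ci_lo = 1, ci_hi = 4, p = p, test = "chisq", note = "",
             p_bonf = pmin(p * n, 1), stringsAsFactors = FALSE)
}

test_that("candidate selection is the keyed intersection of both significant sets", {
  s1 <- toyScan(c(0.01, 0.2, 0.03))
  s2 <- toyScan(c(0.04, 0.01, 0.2))
  cand <- selectCandidates(s1, s2)
  expect_equal(cand$rsid, "s1")
  # idempotence on identical scans
  cand2 <- selectCandidates(s1, s1)
  expect_setequal(cand2$rsid, c("s1", "s3"))
  # MAF gate applies in both scans
  s2b <- s2; s2b$maf[1] <- 0.005
  expect_equal(nrow(selectCandidates(s1, s2b)), 0L)
  # disjoint universes warn
  s3 <- toyScan(0.01); s3$variant <- "9:1:A:G"
  expect_warning(selectCandidates(s1, s3), "disjoint")
})

test_that("rank-and-trim applies the final p cut, the size cap and the tie-breaks", {
  p <- c(seq(1e-5, 2.9e-3, length.out = 9), 0.01, 0.02, 0.04)
  cand <- toyScan(p)
  cand$p_stage2 <- 0.01; cand$or_stage2 <- 2; cand$maf_stage2 <- 0.2
  panel <- rankAndTrim(cand)
  expect_equal(nrow(panelEntries(panel)), 9L)
  expect_true(all(panelEntries(panel)$p_stage1 < 3e-3))
  # disabling the filters keeps everything
  all_panel <- rankAndTrim(cand, p_final = 1, k_max = Inf)
  expect_equal(nrow(panelEntries(all_panel)), 12L)
  # equal p and equal |ln OR|: genomic order decides
  tie <- toyScan(c(1e-4, 1e-4), or = c(2, 0.5))
  tie$p_stage2 <- 1e-3; tie$or_stage2 <- tie$or; tie$maf_stage2 <- 0.2
  tp <- panelEntries(rankAndTrim(tie, k_max = 2))
  expect_equal(tp$pos, c(100L, 200L))
  expect_equal(tp$risk_allele, c("alt", "ref"))
  expect_equal(tp$weight, c(log(2), log(2)))
  # empty panel halts
  expect_error(rankAndTrim(toyScan(0.5) |> transform(p_stage2 = 0.01)),
               "empty panel")
})

test_that("weights are ln(OR) oriented to the risk allele", {
  cand <- toyScan(c(1e-4, 1e-4), or = c(3.77, 0.46))
  cand$p_stage2 <- 1e-3; cand$or_stage2 <- cand$or; cand$maf_stage2 <- 0.2
  e <- panelEntries(rankAndTrim(cand))
  expect_equal(e$risk_allele, c("alt", "ref"))
  expect_equal(e$weight, c(log(3.77), abs(log(0.46))))
})

test_that("selection is monotone in its thresholds", {
  set.seed(8)
  p1 <- runif(40, 0, 0.1); p2 <- runif(40, 0, 0.1)
  s1 <- toyScan(p1); s2 <- toyScan(p2)
  c_loose <- selectCandidates(s1, s2, alpha = 0.1)
  c_tight <- selectCandidates(s1, s2, alpha = 0.02)
  expect_true(all(c_tight$variant %in% c_loose$variant))
  if (nrow(c_loose)) {
    pa <- panelEntries(rankAndTrim(c_loose, p_final = 0.2, k_max = Inf))
    pb <- panelEntries(rankAndTrim(c_loose, p_final = 0.05, k_max = Inf))
    expect_true(all(pb$variant %in% pa$variant))
  }
})

test_that("LD r2 is 1 on the diagonal and for duplicated dosage columns", {
  set.seed(9)
  d <- matrix(rbinom(300, 2, 0.4), nrow = 3)
  d <- rbind(d, d[3, ])                      # duplicate SNP
  gm <- makeGM(d)
  v <- variantInfo(gm)
  panel <- makePanel(v$chrom, v$pos, v$ref, v$alt,
                     rep("alt", 4), rep(log(2), 4))
  chk <- ldPruneCheck(gm, panel)
  expect_equal(unname(diag(chk$r2)), rep(1, 4))
  expect_equal(nrow(chk$flags), 1L)
  expect_equal(chk$flags$r2, 1)
  # strict mode drops the later-ranked SNP of the flagged pair
  strict <- ldPruneCheck(gm, panel, strict = TRUE)
  expect_equal(nrow(panelEntries(strict$panel)), 3L)
  # constant dosage: undefined r2 reported as NA
  d2 <- rbind(rbinom(100, 2, 0.4), rep(2, 100))
  gm2 <- makeGM(d2)
  v2 <- variantInfo(gm2)
  p2 <- makePanel(v2$chrom, v2$pos, v2$ref, v2$alt, c("alt", "alt"),
                  c(log(2), log(2)))
  expect_true(is.na(ldPruneCheck(gm2, p2)$r2[1, 2]))
})

test_that("independently simulated SNPs show negligible pairwise LD", {
  set.seed(10)
  d <- matrix(rbinom(9 * 1000, 2, 0.3), nrow = 9)
  gm <- makeGM(d)
  v <- variantInfo(gm)
  panel <- makePanel(v$chrom, v$pos, v$ref, v$alt,
                     rep("alt", 9), rep(log(2), 9))
  chk <- ldPruneCheck(gm, panel)
  off <- chk$r2[upper.tri(chk$r2)]
  expect_lt(max(off), 0.8)
  expect_lt(mean(off), 0.05)
  expect_equal(nrow(chk$flags), 0L)
})

test_that("panels round-trip through the TSV exchange format", {
  panel <- makePanel(c("1", "7"), c(100L, 200L), c("A", "T"), c("G", "C"),
                     c("alt", "ref"), c(log(3.5), log(2.2)),
                     risk_freq = 0.1)
  path <- withr::local_tempfile(fileext = ".tsv")
  writePanel(panel, path)
  panel2 <- readPanel(path)
  expect_equal(panelEntries(panel2)$weight, panelEntries(panel)$weight)
  expect_equal(panelEntries(panel2)$risk_allele,
               panelEntries(panel)$risk_allele)
  expect_equal(panelEntries(panel2)$variant, panelEntries(panel)$variant)
})
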