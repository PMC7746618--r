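#' Pipeline configuration
#'
#' Bundles the inputs (either a \code{\link{cohortSpec}} to simulate, or
#' paths to a genotype VCF, phenotype TSV and clinical TSV), every stage
#' threshold, the seed and the output directory. All thresholds default to
#' the study's stated values: MAF > 0.01, per-stage alpha 0.05, final
#' p < 3e-3, panel size 9, LD flag at r-squared 0.8, clinical screen at
#' p < 0.05 with missingness < 0.30, and 100 bagged trees.
#'
#' @param cohort_spec a \code{\link{cohortSpec}} (mutually exclusive with
#'   \code{input}).
#' @param input list with paths \code{vcf}, \code{phenotype},
#'   \code{clinical}.
#' @param maf_min,alpha_stage,p_final,k_max,r2_max,alpha_clinical,max_missing,n_trees
#'   stage thresholds.
#' @param seed integer seed for every stochastic stage.
#' @param out_dir output directory for all stage artifacts.
#' @return a validated \code{pipeline_config} list.
#' @export
pipelineConfig <- function(cohort_spec = NULL, input = NULL,
                           maf_min = 0.01, alpha_stage = 0.05,
                           p_final = 3e-3, k_max = 9L, r2_max = 0.8,
                           alpha_clinical = 0.05, max_missing = 0.30,
                           n_trees = 100L, seed = 1L,
                           out_dir = "kdwgrs_run") {
  if (is.null(cohort_spec) && is.null(input))
    stop("provide either a cohort_spec or input file paths")
  stopifnot(maf_min >= 0, maf_min < 0.5,
            alpha_stage > 0, alpha_stage <= 1,
            p_final > 0, p_final <= 1, k_max >= 1,
            r2_max > 0, r2_max <= 1,
            alpha_clinical > 0, alpha_clinical <= 1,
            max_missing > 0, max_missing <= 1, n_trees >= 1)
  cfg <- list(cohort_spec = if (!is.null(cohort_spec)) unclass(cohort_spec),
              input = input,
              thresholds = list(maf_min = maf_min,
                                alpha_stage = alpha_stage,
                                p_final = p_final, k_max = as.integer(k_max),
                                r2_max = r2_max,
                                alpha_clinical = alpha_clinical,
                                max_missing = max_missing,
                                n_trees = as.integer(n_trees)),
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Serialize / deserialize a pipeline configuration as JSON
#'
#' Configurations round-trip unchanged (up to numeric representation).
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param path JSON file path.
#' @export
writePipelineConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(cfg$cohort_spec)) {
    cs <- cfg$cohort_spec
    cs$age_params <- lapply(cs$age_params, as.numeric)
    cfg$cohort_spec <- do.call(cohortSpec, cs)
  }
  do.call(pipelineConfig,
          c(cfg[c("cohort_spec", "input", "seed", "out_dir")],
            cfg$thresholds))
}

stageLog <- function(stage, t0, ...) {
  message(sprintf("[%s] %s (%.2fs)", stage,
                  paste(sprintf("%s=%s", names(list(...)), list(...)),
                        collapse = " "),
                  as.numeric(Sys.time()) - t0))
}

#' Run the full pipeline
#'
#' Executes simulate (or load) -> hard filter -> association scans (both
#' comparisons) -> two-stage selection -> LD check -> wGRS scoring and
#' Wilcoxon comparison -> composite-model evaluation, writing every
#' intermediate artifact into the output directory together with a
#' \code{manifest.json} recording the seed, thresholds and per-stage
#' record counts. Any stage failure halts the run, names the stage, and
#' leaves a machine-readable \code{error.json}. Repeated runs with the
#' same configuration produce identical artifacts.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return the manifest, invisibly (a list; also written as JSON).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  manifest <- list(package = "kdwgrs",
                   version = as.character(utils::packageVersion("kdwgrs")),
                   seed = config$seed, thresholds = th,
                   counts = list(), outputs = list())
  fail <- function(stage, e) {
    err <- list(stage = stage, message = conditionMessage(e))
    jsonlite::write_json(err, file.path(config$out_dir, "error.json"),
                         auto_unbox = TRUE)
    stop("pipeline halted at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  }
  run <- function(stage, expr) {
    t0 <- as.numeric(Sys.time())
    out <- tryCatch(expr, error = function(e) fail(stage, e))
    list(out = out, t0 = t0)
  }

  # -- inputs ---------------------------------------------------------
  st <- run("simulate", {
    if (!is.null(config$cohort_spec)) {
      cs <- config$cohort_spec
      if (!inherits(cs, "cohort_spec"))
        cs <- do.call(cohortSpec,
                      cs[intersect(names(cs), names(formals(cohortSpec)))])
      co <- simulateCohort(cs)
      writeCohort(co, config$out_dir)
      list(genotype = cohortGenotype(co),
           phenotype = cohortPhenotype(co),
           clinical = cohortClinical(co))
    } else {
      ph <- readPhenotypeTable(config$input$phenotype)
      gm <- readGenotypeVcf(config$input$vcf)
      sx <- ph$sex[match(colnames(gm), ph$sample_id)]
      colData(gm)$sex <- sx
      list(genotype = gm, phenotype = ph,
           clinical = readClinicalTable(config$input$clinical))
    }
  })
  cohort <- st$out
  n_total <- nrow(cohort$genotype)
  stageLog("simulate", st$t0, samples = ncol(cohort$genotype),
           snps = n_total)
  manifest$counts$n_snps_total <- n_total
  manifest$counts$n_samples <- ncol(cohort$genotype)

  st <- run("filter", hardFilterVariants(cohort$genotype))
  filtered <- st$out
  writeTsv(filterReport(filtered),
           file.path(config$out_dir, "filter_report.tsv"))
  stageLog("filter", st$t0, kept = nrow(filtered),
           removed = n_total - nrow(filtered))
  manifest$counts$n_snps_post_filter <- nrow(filtered)

  st <- run("scan", {
    s1 <- associationScan(filtered, cohort$phenotype,
                          "nonresponder-vs-responder",
                          maf_min = th$maf_min)
    s2 <- associationScan(filtered, cohort$phenotype,
                          "nonresponder-vs-control",
                          maf_min = th$maf_min)
    list(s1 = s1, s2 = s2)
  })
  scan1 <- st$out$s1; scan2 <- st$out$s2
  writeTsv(scan1, file.path(config$out_dir, "scan_stage1.tsv"))
  writeTsv(scan2, file.path(config$out_dir, "scan_stage2.tsv"))
  n_sig1 <- sum(scan1$p < th$alpha_stage, na.rm = TRUE)
  n_sig2 <- sum(scan2$p < th$alpha_stage, na.rm = TRUE)
  stageLog("scan", st$t0, stage1_sig = n_sig1, stage2_sig = n_sig2)
  manifest$counts$n_stage1_significant <- n_sig1
  manifest$counts$n_stage2_significant <- n_sig2

  st <- run("select", {
    cand <- selectCandidates(scan1, scan2, alpha = th$alpha_stage,
                             maf_min = th$maf_min)
    panel <- rankAndTrim(cand, p_final = th$p_final, k_max = th$k_max,
                         alpha_stage = th$alpha_stage,
                         maf_min = th$maf_min,
                         genotype = filtered,
                         phenotype = cohort$phenotype)
    ld <- ldPruneCheck(filtered, panel, r2_max = th$r2_max)
    list(cand = cand, panel = panel, ld = ld)
  })
  panel <- st$out$panel
  writePanel(panel, file.path(config$out_dir, "panel.tsv"))
  utils::write.table(st$out$ld$r2, file.path(config$out_dir, "panel_r2.tsv"),
                     sep = "\t", quote = FALSE)
  stageLog("select", st$t0, candidates = nrow(st$out$cand),
           panel = nrow(panelEntries(panel)),
           ld_flags = nrow(st$out$ld$flags))
  manifest$counts$n_candidates <- nrow(st$out$cand)
  manifest$counts$n_panel <- nrow(panelEntries(panel))
  manifest$counts$n_ld_flagged_pairs <- nrow(st$out$ld$flags)

  st <- run("score", {
    ph <- cohort$phenotype
    patients <- ph[ph$group %in% c("nonresponder", "responder"), ]
    ss <- scoreCohort(filtered, panel, patients)
    list(ss = ss, wil = groupCompare(ss))
  })
  writeTsv(scoreTable(st$out$ss), file.path(config$out_dir, "wgrs_scores.tsv"))
  jsonlite::write_json(st$out$wil,
                       file.path(config$out_dir, "wgrs_wilcoxon.json"),
                       auto_unbox = TRUE, digits = NA)
  stageLog("score", st$t0, scored = nrow(scoreTable(st$out$ss)),
           wilcoxon_p = signif(st$out$wil$p, 3))
  manifest$counts$n_scored <- nrow(scoreTable(st$out$ss))
  manifest$wilcoxon_p <- st$out$wil$p

  st <- run("evaluate", evaluateModels(
    cohort, panel, n_trees = th$n_trees, seed = config$seed,
    alpha_clinical = th$alpha_clinical, max_missing = th$max_missing))
  ev <- st$out
  writeTsv(ev$screen$report,
           file.path(config$out_dir, "clinical_screen.tsv"))
  writeTsv(rocPoints(ev$roc_wgrs),
           file.path(config$out_dir, "roc_wgrs.tsv"))
  writeTsv(rocPoints(ev$roc_composite),
           file.path(config$out_dir, "roc_composite.tsv"))
  writeTsv(ev$scores, file.path(config$out_dir, "model_scores.tsv"))
  report <- list(
    auc_wgrs = ev$auc_wgrs, cut_wgrs = ev$cut_wgrs,
    auc_wgrs_oob = ev$auc_wgrs_oob,
    auc_composite_oob = ev$auc_composite,
    cut_composite_oob = ev$cut_composite,
    auc_composite_resub = ev$auc_composite_resub,
    cut_composite_resub = ev$cut_composite_resub,
    clinical_features = ev$clinical_features,
    wilcoxon = ev$wilcoxon[c("U", "z", "p", "exact", "medians")],
    seed = config$seed, n_trees = th$n_trees)
  jsonlite::write_json(report,
                       file.path(config$out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  stageLog("evaluate", st$t0, auc_wgrs = signif(ev$auc_wgrs, 3),
           auc_composite = signif(ev$auc_composite, 3))
  manifest$counts$n_clinical_selected <- length(ev$clinical_features)
  manifest$evaluation <- report[c("auc_wgrs", "auc_wgrs_oob",
                                  "auc_composite_oob",
                                  "auc_composite_resub")]
  manifest$outputs <- sort(setdiff(list.files(config$out_dir),
                                   c("manifest.json", "error.json")))

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
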