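.cfgGet <- function(cfg, key, default = NULL, required = FALSE) {
  if (!is.null(cfg[[key]]) && !is.na(cfg[[key]])) return(cfg[[key]])
  if (required)
    stop(sprintf("configuration error: missing required key '%s'", key))
  default
}

#' Run the full two-sample MR analysis from a config file
#'
#' Executes filter, LD pruning (when an LD file is given), harmonization,
#' the causal estimators (likelihood, IVW, weighted median, Egger and
#' Egger-SIMEX), MR-PRESSO, and the leave-one-out / funnel diagnostics,
#' writing every table plus a machine-readable run manifest to the output
#' directory. Any stage failure stops with a non-zero status from
#' \code{Rscript}; tables from completed stages are retained and the
#' manifest records the failed stage.
#'
#' @param config path to a DCF-format key-value file, or a named list.
#'   Required keys: \code{exposure_file}, \code{outcome_file}. Optional:
#'   \code{ld_file}, \code{p_threshold} (5e-8), \code{info_threshold}
#'   (0.7), \code{r2_threshold} (0.1), \code{maf_threshold} (0.4),
#'   \code{n_sim_presso} (10000), \code{n_boot} (10000), \code{seed} (1),
#'   \code{output_dir}.
#' @param outputDir overrides the config's \code{output_dir}.
#' @return Invisibly, a list with the instrument, the estimates, the
#'   PRESSO result and the manifest.
#' @export
runPipeline <- function(config, outputDir = NULL) {
  cfg <- if (is.character(config)) {
    dcf <- read.dcf(config)
    stats::setNames(as.list(dcf[1, ]), colnames(dcf))
  } else config
  expFile <- .cfgGet(cfg, "exposure_file", required = TRUE)
  outFile <- .cfgGet(cfg, "outcome_file", required = TRUE)
  dir <- outputDir %||% .cfgGet(cfg, "output_dir", required = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pThr <- as.numeric(.cfgGet(cfg, "p_threshold", 5e-8))
  infoThr <- as.numeric(.cfgGet(cfg, "info_threshold", 0.7))
  r2Thr <- as.numeric(.cfgGet(cfg, "r2_threshold", 0.1))
  mafThr <- as.numeric(.cfgGet(cfg, "maf_threshold", 0.4))
  nSim <- as.integer(.cfgGet(cfg, "n_sim_presso", 10000L))
  nBoot <- as.integer(.cfgGet(cfg, "n_boot", 10000L))
  seed <- as.integer(.cfgGet(cfg, "seed", 1L))
  ldFile <- .cfgGet(cfg, "ld_file")

  manifest <- list(
    package = "summaryMR",
    version = as.character(utils::packageVersion("summaryMR")),
    inputs = list(exposure_file = expFile, outcome_file = outFile,
                  ld_file = ldFile),
    thresholds = list(p = pThr, info = infoThr, ld_r2 = r2Thr,
                      palindromic_maf = mafThr),
    seed = seed, n_sim_presso = nSim, n_boot = nBoot,
    stages = list())
  writeManifest <- function()
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      writeManifest()
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "completed")
    writeManifest()
    res
  }
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)

  exposure <- stage("read_exposure", readSumstats(expFile))
  outcome <- stage("read_outcome", readSumstats(outFile))
  exposure <- stage("filter", filterInstrument(exposure, pThr, infoThr))
  if (!is.null(ldFile))
    exposure <- stage("prune_ld",
                      pruneLD(exposure, readLDMatrix(ldFile), r2Thr))
  inst <- stage("harmonize", {
    i <- harmonize(exposure, outcome, mafAmbiguousThreshold = mafThr)
    writeInstrument(i, file.path(dir, "instrument.tsv"))
    writeExclusions(i, file.path(dir, "exclusions.tsv"))
    i
  })
  ests <- stage("estimate", {
    lik <- mrLikelihood(inst)
    ivw <- mrIVW(inst)
    wm <- mrWeightedMedian(inst, nBoot = nBoot, seed = seed)
    eg <- mrEgger(inst)
    egx <- mrEggerSimex(inst, seed = seed)
    tab <- forestTable(
      list(lik, ivw, wm,
           .causalEstimate("egger", eg@slope, eg@slopeSE, nSNP = nSNP(inst)),
           .causalEstimate("egger_simex", egx@slope, egx@slopeSE,
                           nSNP = nSNP(inst))),
      labels = c("likelihood", "ivw", "weighted_median", "egger",
                 "egger_simex"))
    tab$p_egger_intercept <- c(NA, NA, NA, eg@interceptP, egx@interceptP)
    tab$p_snp_heterogeneity <- c(lik@pHet, ivw@pHet, NA, NA, NA)
    wt(tab, "estimates.tsv")
    list(likelihood = lik, ivw = ivw, weighted_median = wm, egger = eg,
         egger_simex = egx)
  })
  presso <- stage("presso", {
    p <- mrPresso(inst, nSim = nSim, seed = seed)
    wt(data.frame(rsid = names(outlierP(p)), p_outlier = outlierP(p),
                  is_outlier = names(outlierP(p)) %in% outlierSNPs(p)),
       "presso_outliers.tsv")
    wt(data.frame(rss_observed = p@rssObserved, n_sim = p@nSim,
                  p_global = p@pGlobal,
                  n_outliers = length(outlierSNPs(p))), "presso.tsv")
    p
  })
  stage("diagnostics", {
    wt(leaveOneOut(inst), "leave_one_out.tsv")
    wt(funnelData(inst), "funnel.tsv")
  })
  invisible(list(instrument = inst, estimates = ests, presso = presso,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
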