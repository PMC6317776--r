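#' @name accessors
#' @title Accessors for summaryMR S4 objects
#' @description Slot accessors: \code{snps()}, \code{nSNP()},
#'   \code{betaExposure()}, \code{seExposure()}, \code{betaOutcome()},
#'   \code{seOutcome()}, \code{eaf()}, \code{harmonyFlag()},
#'   \code{exclusions()}, \code{theta()}, \code{se()}, \code{ci()},
#'   \code{orSD()}, \code{pValue()}, \code{methodName()},
#'   \code{causalEstimate()}, \code{pGlobal()}, \code{outlierSNPs()},
#'   \code{outlierP()}.
#' @param x a summaryMR object.
#' @return The slot contents; \code{ci()} returns c(low, high) on the
#'   log-odds scale; \code{orSD()} returns exp(theta).
NULL

#' @rdname accessors
#' @export
setGeneric("snps", function(x) standardGeneric("snps"))
#' @rdname accessors
#' @export
setGeneric("nSNP", function(x) standardGeneric("nSNP"))
#' @rdname accessors
#' @export
setGeneric("betaExposure", function(x) standardGeneric("betaExposure"))
#' @rdname accessors
#' @export
setGeneric("seExposure", function(x) standardGeneric("seExposure"))
#' @rdname accessors
#' @export
setGeneric("betaOutcome", function(x) standardGeneric("betaOutcome"))
#' @rdname accessors
#' @export
setGeneric("seOutcome", function(x) standardGeneric("seOutcome"))
#' @rdname accessors
#' @export
setGeneric("eaf", function(x) standardGeneric("eaf"))
#' @rdname accessors
#' @export
setGeneric("harmonyFlag", function(x) standardGeneric("harmonyFlag"))
#' @rdname accessors
#' @export
setGeneric("exclusions", function(x) standardGeneric("exclusions"))
#' @rdname accessors
#' @export
setGeneric("theta", function(x) standardGeneric("theta"))
#' @rdname accessors
#' @export
setGeneric("se", function(x) standardGeneric("se"))
#' @rdname accessors
#' @export
setGeneric("ci", function(x) standardGeneric("ci"))
#' @rdname accessors
#' @export
setGeneric("orSD", function(x) standardGeneric("orSD"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("methodName", function(x) standardGeneric("methodName"))
#' @rdname accessors
#' @export
setGeneric("causalEstimate", function(x) standardGeneric("causalEstimate"))
#' @rdname accessors
#' @export
setGeneric("pGlobal", function(x) standardGeneric("pGlobal"))
#' @rdname accessors
#' @export
setGeneric("outlierSNPs", function(x) standardGeneric("outlierSNPs"))
#' @rdname accessors
#' @export
setGeneric("outlierP", function(x) standardGeneric("outlierP"))

setMethod("snps", "HarmonizedInstrument", function(x) x@snps)
setMethod("nSNP", "HarmonizedInstrument", function(x) length(x@snps))
setMethod("betaExposure", "HarmonizedInstrument", function(x) x@betaExposure)
setMethod("seExposure", "HarmonizedInstrument", function(x) x@seExposure)
setMethod("betaOutcome", "HarmonizedInstrument", function(x) x@betaOutcome)
setMethod("seOutcome", "HarmonizedInstrument", function(x) x@seOutcome)
setMethod("eaf", "HarmonizedInstrument", function(x) x@eaf)
setMethod("harmonyFlag", "HarmonizedInstrument", function(x) x@flag)
setMethod("exclusions", "HarmonizedInstrument", function(x) x@exclusions)
setMethod("nSNP", "CausalEstimate", function(x) x@nSNP)
setMethod("theta", "CausalEstimate", function(x) x@theta)
setMethod("se", "CausalEstimate", function(x) x@se)
setMethod("ci", "CausalEstimate", function(x) c(x@ciLow, x@ciHigh))
setMethod("orSD", "CausalEstimate", function(x) exp(x@theta))
setMethod("pValue", "CausalEstimate", function(x) x@pValue)
setMethod("methodName", "CausalEstimate", function(x) x@method)
setMethod("causalEstimate", "LikelihoodFit", function(x) x@estimate)
setMethod("theta", "LikelihoodFit", function(x) x@estimate@theta)
setMethod("se", "LikelihoodFit", function(x) x@estimate@se)
setMethod("ci", "LikelihoodFit", function(x) ci(x@estimate))
setMethod("orSD", "LikelihoodFit", function(x) exp(x@estimate@theta))
setMethod("theta", "EggerResult", function(x) x@slope)
setMethod("se", "EggerResult", function(x) x@slopeSE)
setMethod("nSNP", "EggerResult", function(x) x@nSNP)
setMethod("pGlobal", "PressoResult", function(x) x@pGlobal)
setMethod("outlierSNPs", "PressoResult", function(x) x@outlierSNPs)
setMethod("outlierP", "PressoResult", function(x) x@outlierP)

#' Subset a harmonized instrument by SNP
#'
#' @param x a \linkS4class{HarmonizedInstrument}.
#' @param i logical/integer index or rsid character vector.
#' @param j,...,drop ignored.
#' @return The subset instrument (exclusion log carried over unchanged).
#' @export
setMethod("[", "HarmonizedInstrument", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    i <- match(i, x@snps)
    if (anyNA(i)) stop("unknown rsid in subset")
  }
  HarmonizedInstrument(x@snps[i], x@betaExposure[i], x@seExposure[i],
                       x@betaOutcome[i], x@seOutcome[i], x@eaf[i],
                       x@flag[i], x@exclusions)
})

setMethod("show", "HarmonizedInstrument", function(object) {
  cat(sprintf("HarmonizedInstrument with %d SNPs (%d excluded)\n",
              length(object@snps), nrow(object@exclusions)))
  if (length(object@snps)) {
    tab <- table(object@flag)
    cat("  flags:", paste(sprintf("%s=%d", names(tab), tab),
                          collapse = ", "), "\n")
    k <- min(5L, length(object@snps))
    df <- data.frame(rsid = object@snps, beta.exposure = object@betaExposure,
                     beta.outcome = object@betaOutcome)[seq_len(k), ]
    print(df, row.names = FALSE)
    if (length(object@snps) > k) cat("  ...\n")
  }
})

setMethod("show", "CausalEstimate", function(object) {
  cat(sprintf("CausalEstimate [%s], %d SNPs\n", object@method, object@nSNP))
  cat(sprintf("  OR per SD: %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              exp(object@theta), exp(object@ciLow), exp(object@ciHigh),
              object@pValue))
  if (!is.na(object@qStat))
    cat(sprintf("  SNP heterogeneity: Q = %.2f, I2 = %.1f%%, p = %.3g\n",
                object@qStat, 100 * object@i2, object@pHet))
})

setMethod("show", "LikelihoodFit", function(object) {
  cat("LikelihoodFit\n")
  show(object@estimate)
})

setMethod("show", "EggerResult", function(object) {
  kind <- if (length(object@lambdaGrid)) "SIMEX" else "naive"
  cat(sprintf("EggerResult (%s), %d SNPs\n", kind, object@nSNP))
  cat(sprintf("  slope: %.4f (SE %.4f, p = %.3g)\n",
              object@slope, object@slopeSE, object@slopeP))
  cat(sprintf("  intercept: %.5f (SE %.5f, p = %.3g)\n",
              object@intercept, object@interceptSE, object@interceptP))
})

setMethod("show", "PressoResult", function(object) {
  cat(sprintf("PressoResult: RSS = %.3f, global p = %.4g (%d simulations)\n",
              object@rssObserved, object@pGlobal, object@nSim))
  if (length(object@outlierSNPs))
    cat("  outliers:", paste(object@outlierSNPs, collapse = ", "), "\n")
  else cat("  no outliers flagged\n")
  if (is(object@corrected, "CausalEstimate")) {
    cat("  corrected estimate:\n")
    show(object@corrected)
  }
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0(
    "SimulationConfig: %d SNPs, theta = %.4f (OR %.2f/SD), R2 = %.3f\n",
    "  exposure n = %d; outcome %d cases / %d controls\n",
    "  pleiotropy: %.0f%% invalid, direct ~ N(%.3g, %.3g^2), ",
    "InSIDE corr %.2f; seed %d\n"),
    object@nSNP, object@thetaTrue, exp(object@thetaTrue), object@targetR2,
    object@nExposure, object@nCases, object@nControls,
    100 * object@fractionInvalid, object@meanDirect, object@sdDirect,
    object@insideCorr, object@seed))
})

setMethod("show", "LDMatrix", function(object) {
  cat(sprintf("LDMatrix for %d SNPs\n", length(object@snps)))
})
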