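#' @import methods
NULL

.HARMONY_FLAGS <- c("as_is", "allele_flipped", "palindromic_kept_by_freq",
                    "substituted_by_proxy")

#' HarmonizedInstrument: an allele-aligned two-sample MR instrument
#'
#' Holds, for each retained SNP, the exposure association (log-SD of the
#' trait per effect allele) and the outcome association (log-odds per
#' effect allele) expressed on a common effect allele, together with a
#' per-SNP harmonization provenance flag and the exclusion log for SNPs
#' that could not be aligned.
#'
#' @slot snps character vector of rsids (unique).
#' @slot betaExposure,seExposure numeric, SNP-exposure effect and SE.
#' @slot betaOutcome,seOutcome numeric, SNP-outcome effect and SE.
#' @slot eaf numeric, effect allele frequency (may be NA).
#' @slot flag character, one of \code{as_is}, \code{allele_flipped},
#'   \code{palindromic_kept_by_freq}, \code{substituted_by_proxy}.
#' @slot exclusions data.frame with columns \code{rsid}, \code{reason}.
#' @exportClass HarmonizedInstrument
setClass("HarmonizedInstrument",
  representation(
    snps         = "character",
    betaExposure = "numeric",
    seExposure   = "numeric",
    betaOutcome  = "numeric",
    seOutcome    = "numeric",
    eaf          = "numeric",
    flag         = "character",
    exclusions   = "data.frame"))

setValidity("HarmonizedInstrument", function(object) {
  n <- length(object@snps)
  lens <- c(length(object@betaExposure), length(object@seExposure),
            length(object@betaOutcome), length(object@seOutcome),
            length(object@eaf), length(object@flag))
  if (any(lens != n))
    return("all per-SNP slots must have the same length as 'snps'")
  if (anyDuplicated(object@snps))
    return("duplicate rsids in instrument")
  if (n > 0 && (any(!is.finite(object@seExposure)) ||
                any(object@seExposure <= 0)))
    return("seExposure must be finite and > 0")
  if (n > 0 && (any(!is.finite(object@seOutcome)) ||
                any(object@seOutcome <= 0)))
    return("seOutcome must be finite and > 0")
  if (n > 0 && !all(object@flag %in% .HARMONY_FLAGS))
    return(sprintf("flags must be one of: %s",
                   paste(.HARMONY_FLAGS, collapse = ", ")))
  if (!all(c("rsid", "reason") %in% names(object@exclusions)))
    return("exclusions must have columns 'rsid' and 'reason'")
  if (any(object@snps %in% object@exclusions$rsid))
    return("a SNP cannot be both retained and excluded")
  ok <- is.na(object@eaf) | (object@eaf > 0 & object@eaf < 1)
  if (!all(ok)) return("eaf must be in (0,1) or NA")
  TRUE
})

#' Construct a HarmonizedInstrument
#'
#' @param snps rsids.
#' @param betaExposure,seExposure SNP-exposure effects and SEs.
#' @param betaOutcome,seOutcome SNP-outcome effects and SEs.
#' @param eaf effect allele frequencies (NA allowed).
#' @param flag per-SNP harmonization provenance flag.
#' @param exclusions data.frame(rsid, reason) of excluded SNPs.
#' @return A \linkS4class{HarmonizedInstrument}.
#' @examples
#' HarmonizedInstrument(c("rs1", "rs2"),
#'   betaExposure = c(0.1, 0.08), seExposure = c(0.01, 0.01),
#'   betaOutcome = c(0.05, 0.03), seOutcome = c(0.02, 0.02))
#' @export
HarmonizedInstrument <- function(snps, betaExposure, seExposure,
                                 betaOutcome, seOutcome,
                                 eaf = rep(NA_real_, length(snps)),
                                 flag = rep("as_is", length(snps)),
                                 exclusions = data.frame(
                                   rsid = character(), reason = character(),
                                   stringsAsFactors = FALSE)) {
  new("HarmonizedInstrument", snps = as.character(snps),
      betaExposure = as.numeric(betaExposure),
      seExposure = as.numeric(seExposure),
      betaOutcome = as.numeric(betaOutcome),
      seOutcome = as.numeric(seOutcome),
      eaf = as.numeric(eaf), flag = as.character(flag),
      exclusions = exclusions)
}

#' CausalEstimate: one method's causal effect estimate
#'
#' The causal effect theta is on the log-odds-per-SD scale; \code{orSD()}
#' returns exp(theta), the odds ratio per SD increment of the exposure.
#'
#' @slot method estimator label.
#' @slot theta,se point estimate and standard error (log-odds per SD).
#' @slot ciLow,ciHigh confidence limits on the log-odds scale.
#' @slot pValue two-sided p-value for theta = 0.
#' @slot nSNP number of SNPs used.
#' @slot qStat,i2,pHet Cochran Q across per-SNP ratios, I-squared, and the
#'   chi-square heterogeneity p-value (NA when not computed).
#' @exportClass CausalEstimate
setClass("CausalEstimate",
  representation(
    method = "character", theta = "numeric", se = "numeric",
    ciLow = "numeric", ciHigh = "numeric", pValue = "numeric",
    nSNP = "integer", qStat = "numeric", i2 = "numeric", pHet = "numeric"))

setValidity("CausalEstimate", function(object) {
  if (length(object@theta) != 1L || !is.finite(object@theta))
    return("theta must be a finite scalar")
  if (!is.na(object@se) && object@se <= 0)
    return("se must be positive")
  if (!is.na(object@ciLow) && !is.na(object@ciHigh) &&
      (object@ciLow > object@theta + 1e-12 ||
       object@ciHigh < object@theta - 1e-12))
    return("ciLow <= theta <= ciHigh violated")
  if (!is.na(object@qStat) && object@qStat < 0)
    return("qStat must be >= 0")
  if (!is.na(object@i2) && (object@i2 < 0 || object@i2 >= 1))
    return("i2 must lie in [0, 1)")
  TRUE
})

.causalEstimate <- function(method, theta, se, ciLow = NA_real_,
                            ciHigh = NA_real_, pValue = NA_real_,
                            nSNP = NA_integer_, qStat = NA_real_,
                            i2 = NA_real_, pHet = NA_real_) {
  if (is.na(ciLow) && !is.na(se)) ciLow <- theta - 1.959964 * se
  if (is.na(ciHigh) && !is.na(se)) ciHigh <- theta + 1.959964 * se
  if (is.na(pValue) && !is.na(se))
    pValue <- 2 * stats::pnorm(-abs(theta) / se)
  new("CausalEstimate", method = method, theta = theta, se = se,
      ciLow = ciLow, ciHigh = ciHigh, pValue = pValue,
      nSNP = as.integer(nSNP), qStat = qStat, i2 = i2, pHet = pHet)
}

#' LikelihoodFit: likelihood-based estimate with profile curve
#'
#' @slot estimate the \linkS4class{CausalEstimate}.
#' @slot xi per-SNP nuisance means (true SNP-exposure effects) at the MLE.
#' @slot profile data.frame(theta, logLik) profile log-likelihood curve.
#' @exportClass LikelihoodFit
setClass("LikelihoodFit",
  representation(estimate = "CausalEstimate", xi = "numeric",
                 profile = "data.frame"))

#' EggerResult: MR-Egger regression fit (naive or SIMEX-corrected)
#'
#' @slot slope,slopeSE,slopeP causal slope, SE and two-sided p (t, n-2 df).
#' @slot intercept,interceptSE,interceptP average directional pleiotropy per
#'   SNP with SE and the directional-pleiotropy test p-value.
#' @slot nSNP number of SNPs.
#' @slot lambdaGrid SIMEX lambda grid (empty for a naive fit).
#' @slot simexTrace per-lambda averaged coefficients and variance components.
#' @slot naive for SIMEX fits, the naive coefficients (named list).
#' @exportClass EggerResult
setClass("EggerResult",
  representation(
    slope = "numeric", slopeSE = "numeric", slopeP = "numeric",
    intercept = "numeric", interceptSE = "numeric", interceptP = "numeric",
    nSNP = "integer", lambdaGrid = "numeric", simexTrace = "data.frame",
    naive = "list"))

#' PressoResult: MR-PRESSO global, outlier and corrected results
#'
#' @slot rssObserved observed weighted residual sum of squares.
#' @slot nSim number of null simulations.
#' @slot pGlobal Monte-Carlo global pleiotropy p-value,
#'   (1 + #\{RSS_sim >= RSS_obs\}) / (nSim + 1).
#' @slot outlierP named per-SNP Bonferroni-adjusted outlier p-values.
#' @slot outlierSNPs rsids flagged as outliers at the chosen alpha.
#' @slot corrected likelihood re-estimate after outlier removal (or NULL).
#' @slot seed RNG seed used for the null simulation.
#' @slot exceedCount per-SNP counts of simulated residual contributions
#'   at least as large as the observed contribution.
#' @slot obsResiduals observed per-SNP residual contributions.
#' @exportClass PressoResult
setClass("PressoResult",
  representation(
    rssObserved = "numeric", nSim = "integer", pGlobal = "numeric",
    outlierP = "numeric", outlierSNPs = "character", corrected = "ANY",
    seed = "integer", exceedCount = "numeric", obsResiduals = "numeric"))

setValidity("PressoResult", function(object) {
  if (object@pGlobal <= 0 || object@pGlobal > 1)
    return("pGlobal must lie in (0, 1]")
  if (object@rssObserved < 0) return("rssObserved must be >= 0")
  TRUE
})

#' LDMatrix: pairwise linkage-disequilibrium R-squared values
#'
#' @slot snps rsids labelling rows/columns.
#' @slot r2 symmetric matrix of pairwise R-squared in [0,1], unit diagonal.
#' @exportClass LDMatrix
setClass("LDMatrix",
  representation(snps = "character", r2 = "matrix"))

setValidity("LDMatrix", function(object) {
  m <- object@r2
  if (nrow(m) != length(object@snps) || ncol(m) != length(object@snps))
    return("r2 dimensions must match length of snps")
  if (length(object@snps) == 0) return(TRUE)
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1))
    return("r2 values must lie in [0, 1]")
  if (max(abs(m - t(m))) > 1e-8) return("r2 must be symmetric")
  if (max(abs(diag(m) - 1)) > 1e-8) return("r2 diagonal must be 1")
  TRUE
})

#' Construct an LDMatrix
#' @param snps rsids.
#' @param r2 symmetric R-squared matrix.
#' @return An \linkS4class{LDMatrix}.
#' @export
LDMatrix <- function(snps, r2) {
  dimnames(r2) <- list(snps, snps)
  new("LDMatrix", snps = as.character(snps), r2 = r2)
}

#' SimulationConfig: ground-truth settings for synthetic summary statistics
#'
#' Defaults emulate the BMI analysis scale of a large two-sample MR study:
#' a ~300k-sample exposure GWAS in SD units, a 10,784-case / 20,406-control
#' outcome GWAS on the log-odds scale, an instrument explaining 9.5% of
#' exposure variance, and a true odds ratio of 1.56 per SD.
#'
#' @slot nSNP number of instrument SNPs.
#' @slot thetaTrue true causal effect, log-odds per SD.
#' @slot nExposure exposure GWAS sample size.
#' @slot nCases,nControls outcome GWAS case/control counts.
#' @slot targetR2 exposure variance explained by the instrument.
#' @slot eafRange effect-allele frequency range (uniform draw).
#' @slot fractionInvalid fraction of SNPs with a direct (pleiotropic) effect.
#' @slot meanDirect,sdDirect direct-effect distribution, log-odds per allele.
#' @slot insideCorr Gaussian-copula correlation between instrument strength
#'   and direct effects (nonzero violates the InSIDE assumption).
#' @slot scrambleCoding whether to randomize allele/strand coding.
#' @slot seed RNG seed.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    nSNP = "integer", thetaTrue = "numeric", nExposure = "integer",
    nCases = "integer", nControls = "integer", targetR2 = "numeric",
    eafRange = "numeric", fractionInvalid = "numeric",
    meanDirect = "numeric", sdDirect = "numeric", insideCorr = "numeric",
    scrambleCoding = "logical", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  if (object@nSNP < 1) return("nSNP must be >= 1")
  if (object@targetR2 <= 0 || object@targetR2 >= 1)
    return("targetR2 must lie in (0, 1)")
  if (length(object@eafRange) != 2 || object@eafRange[1] <= 0 ||
      object@eafRange[2] >= 1 || object@eafRange[1] > object@eafRange[2])
    return("eafRange must be (low, high) within (0, 1)")
  if (object@fractionInvalid < 0 || object@fractionInvalid > 1)
    return("fractionInvalid must lie in [0, 1]")
  if (object@sdDirect < 0) return("sdDirect must be >= 0")
  if (abs(object@insideCorr) > 1) return("insideCorr must lie in [-1, 1]")
  if (object@nExposure < 2 || object@nCases < 1 || object@nControls < 1)
    return("sample sizes must be positive")
  TRUE
})

#' Construct a SimulationConfig
#'
#' @param nSNP,thetaTrue,nExposure,nCases,nControls,targetR2,eafRange
#'   see \linkS4class{SimulationConfig}.
#' @param fractionInvalid,meanDirect,sdDirect,insideCorr pleiotropy settings.
#' @param scrambleCoding randomize allele/strand coding of the emitted tables.
#' @param seed RNG seed.
#' @return A \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simConfig(nSNP = 50, seed = 7)
#' @export
simConfig <- function(nSNP = 100L, thetaTrue = log(1.56),
                      nExposure = 300000L, nCases = 10784L,
                      nControls = 20406L, targetR2 = 0.095,
                      eafRange = c(0.1, 0.9), fractionInvalid = 0,
                      meanDirect = 0, sdDirect = 0, insideCorr = 0,
                      scrambleCoding = FALSE, seed = 1L) {
  new("SimulationConfig", nSNP = as.integer(nSNP), thetaTrue = thetaTrue,
      nExposure = as.integer(nExposure), nCases = as.integer(nCases),
      nControls = as.integer(nControls), targetR2 = targetR2,
      eafRange = as.numeric(eafRange), fractionInvalid = fractionInvalid,
      meanDirect = meanDirect, sdDirect = sdDirect,
      insideCorr = insideCorr, scrambleCoding = scrambleCoding,
      seed = as.integer(seed))
}
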