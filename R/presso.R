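# Leave-one-out IVW expected outcome effects and weighted residual
# contributions, vectorized. BX, BY may be matrices (rows = datasets).
.pressoResiduals <- function(BX, BY, sy) {
  if (is.null(dim(BX))) { BX <- rbind(BX); BY <- rbind(BY) }
  W <- sweep(BX^2, 2, sy^2, "/")          # per-SNP IVW weights
  TH <- BY / BX                           # per-SNP ratios
  S1 <- rowSums(W * TH); S0 <- rowSums(W)
  THloo <- (S1 - W * TH) / (S0 - W)       # leave-one-out IVW estimates
  sweep((BY - THloo * BX)^2, 2, sy^2, "/")
}

#' MR-PRESSO global pleiotropy test
#'
#' For each SNP the expected outcome effect is the leave-one-out IVW
#' estimate times the SNP-exposure effect; the observed residual sum of
#' squares RSS = sum_j (beta_GD,j - theta_-j beta_GE,j)^2 / SE_GD,j^2 is
#' compared against a parametric null in which both summary estimates are
#' redrawn around their expectations (beta~_GD,j ~ N(theta_-j beta_GE,j,
#' SE_GD,j^2), beta~_GE,j ~ N(beta_GE,j, SE_GE,j^2)) and the RSS recomputed
#' identically. The global p-value is the add-one Monte-Carlo estimate
#' (1 + #\{RSS_sim >= RSS_obs\}) / (nSim + 1), so it is never exactly 0.
#'
#' @param inst a \linkS4class{HarmonizedInstrument} (>= 4 SNPs).
#' @param nSim null simulations (default 10000, minimum 1000).
#' @param seed RNG seed.
#' @return A \linkS4class{PressoResult} without outlier calls or a
#'   corrected estimate (see \code{\link{pressoOutliers}} and
#'   \code{\link{pressoCorrected}}, or \code{\link{mrPresso}} for the full
#'   cascade).
#' @export
pressoGlobal <- function(inst, nSim = 10000L, seed = 1L) {
  stopifnot(is(inst, "HarmonizedInstrument"))
  if (nSNP(inst) < 4)
    stop("MR-PRESSO requires at least 4 SNPs")
  stopifnot(nSim >= 1000)
  set.seed(seed)
  n <- nSNP(inst)
  bx <- inst@betaExposure; by <- inst@betaOutcome
  sx <- inst@seExposure;   sy <- inst@seOutcome
  obs <- drop(.pressoResiduals(bx, by, sy))
  rssObs <- sum(obs)
  # expected outcome effects under no pleiotropy, from the observed data
  W <- bx^2 / sy^2; TH <- by / bx
  thLoo <- (sum(W * TH) - W * TH) / (sum(W) - W)
  BX <- matrix(stats::rnorm(nSim * n, rep(bx, each = nSim),
                            rep(sx, each = nSim)), nSim, n)
  BY <- matrix(stats::rnorm(nSim * n, rep(thLoo * bx, each = nSim),
                            rep(sy, each = nSim)), nSim, n)
  sim <- .pressoResiduals(BX, BY, sy)
  pGlobal <- (1 + sum(rowSums(sim) >= rssObs)) / (nSim + 1)
  exceed <- colSums(sweep(sim, 2, obs, ">=") * 1)
  new("PressoResult", rssObserved = rssObs, nSim = as.integer(nSim),
      pGlobal = pGlobal, outlierP = stats::setNames(rep(NA_real_, n),
                                                    inst@snps),
      outlierSNPs = character(0), corrected = NULL,
      seed = as.integer(seed),
      exceedCount = stats::setNames(exceed, inst@snps),
      obsResiduals = stats::setNames(obs, inst@snps))
}

#' MR-PRESSO per-SNP outlier test
#'
#' The raw per-SNP p-value is the fraction of simulated residual
#' contributions at least as large as the observed contribution; it is
#' Bonferroni-multiplied by the number of SNPs and capped at 1. SNPs with
#' adjusted p below \code{alpha} are flagged as outliers.
#'
#' @param inst the instrument passed to \code{\link{pressoGlobal}}.
#' @param global the \linkS4class{PressoResult} from
#'   \code{\link{pressoGlobal}}.
#' @param alpha outlier significance threshold (default 0.05).
#' @return The \linkS4class{PressoResult} with \code{outlierP} and
#'   \code{outlierSNPs} filled in.
#' @export
pressoOutliers <- function(inst, global, alpha = 0.05) {
  stopifnot(is(global, "PressoResult"),
            identical(names(global@exceedCount), inst@snps))
  praw <- global@exceedCount / global@nSim
  padj <- pmin(1, praw * nSNP(inst))
  global@outlierP <- stats::setNames(padj, inst@snps)
  global@outlierSNPs <- inst@snps[padj < alpha]
  global
}

#' Re-estimate the causal effect after outlier removal
#'
#' Applies the likelihood-based estimator to the instrument with the
#' flagged outliers removed; the result carries the method tag
#' \code{presso_corrected}.
#'
#' @param inst a \linkS4class{HarmonizedInstrument}.
#' @param outliers rsids to remove (must all belong to the instrument).
#' @return A \linkS4class{CausalEstimate}.
#' @export
pressoCorrected <- function(inst, outliers) {
  stopifnot(all(outliers %in% inst@snps))
  kept <- inst[!inst@snps %in% outliers]
  if (nSNP(kept) < 2)
    stop("outlier removal leaves fewer than 2 SNPs")
  est <- mrLikelihood(kept)
  est@method <- "presso_corrected"
  est
}

#' Full MR-PRESSO cascade
#'
#' Runs the global test, the outlier test, and (when outliers are found)
#' the corrected re-estimation.
#'
#' @inheritParams pressoGlobal
#' @param alpha outlier significance threshold (default 0.05).
#' @return A complete \linkS4class{PressoResult}.
#' @examples
#' inst <- simulateInstrument(simConfig(nSNP = 20, seed = 3))$instrument
#' mrPresso(inst, nSim = 1000, seed = 4)
#' @export
mrPresso <- function(inst, nSim = 10000L, seed = 1L, alpha = 0.05) {
  res <- pressoGlobal(inst, nSim = nSim, seed = seed)
  res <- pressoOutliers(inst, res, alpha = alpha)
  if (length(res@outlierSNPs) &&
      nSNP(inst) - length(res@outlierSNPs) >= 2)
    res@corrected <- pressoCorrected(inst, res@outlierSNPs)
  res
}

#' Sensitivity-analysis summary table
#'
#' Assembles the likelihood, weighted-median, Egger(-SIMEX) and MR-PRESSO
#' results for one instrument into the tab-separated layout of a
#' sensitivity table: method, n SNP, OR, CI, p, SNP-heterogeneity p,
#' PRESSO global p.
#'
#' @param inst a \linkS4class{HarmonizedInstrument}.
#' @param nSim,nBoot,seed simulation sizes and seed for PRESSO and the
#'   weighted-median bootstrap.
#' @param path optional output file; when given the table is also written
#'   as tab-separated text.
#' @return data.frame with one row per method.
#' @export
sensitivityTable <- function(inst, nSim = 10000L, nBoot = 10000L,
                             seed = 1L, path = NULL) {
  lik <- mrLikelihood(inst)
  wm <- mrWeightedMedian(inst, nBoot = nBoot, seed = seed)
  eg <- mrEggerSimex(inst, seed = seed)
  pr <- mrPresso(inst, nSim = nSim, seed = seed)
  egEst <- .causalEstimate("egger_simex", eg@slope, eg@slopeSE,
                           nSNP = nSNP(inst))
  rows <- list(lik, wm, egEst,
               if (is(pr@corrected, "CausalEstimate")) pr@corrected)
  rows <- Filter(Negate(is.null), rows)
  df <- do.call(rbind, lapply(rows, function(e) data.frame(
    method = e@method, n_snp = e@nSNP, or = exp(e@theta),
    ci_low = exp(e@ciLow), ci_high = exp(e@ciHigh), p = e@pValue,
    p_snp_heterogeneity = e@pHet, stringsAsFactors = FALSE)))
  df$p_presso_global <- c(pr@pGlobal, rep(NA, nrow(df) - 1))
  df$p_egger_intercept <- c(eg@interceptP, rep(NA, nrow(df) - 1))
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  df
}
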