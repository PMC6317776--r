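#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the causal effect with each SNP excluded in turn, to show
#' whether any single variant drives the overall estimate. The
#' likelihood-based estimator is used per row (the Wald ratio when only
#' one SNP remains); the full-instrument estimate is appended as the
#' reference row \code{excluded = "(none)"}. A row whose estimator fails
#' is reported as NA with a warning, and the remaining rows are computed.
#'
#' @param inst a \linkS4class{HarmonizedInstrument} (>= 2 SNPs).
#' @return data.frame(excluded, theta, se, ciLow, ciHigh, orSD).
#' @export
leaveOneOut <- function(inst) {
  stopifnot(is(inst, "HarmonizedInstrument"), nSNP(inst) >= 2)
  oneRow <- function(excluded, sub) {
    est <- tryCatch({
      if (nSNP(sub) == 1) {
        r <- waldRatios(sub)
        .causalEstimate("wald", r$theta, r$se, nSNP = 1L)
      } else mrLikelihood(sub)
    }, error = function(e) {
      warning(sprintf("leave-one-out row '%s' failed: %s", excluded,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(est))
      return(data.frame(excluded = excluded, theta = NA_real_,
                        se = NA_real_, ciLow = NA_real_, ciHigh = NA_real_,
                        orSD = NA_real_, stringsAsFactors = FALSE))
    data.frame(excluded = excluded, theta = est@theta, se = est@se,
               ciLow = est@ciLow, ciHigh = est@ciHigh,
               orSD = exp(est@theta), stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nSNP(inst)), function(j)
    oneRow(inst@snps[j], inst[-j]))
  rows[[length(rows) + 1L]] <- oneRow("(none)", inst)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Funnel-plot coordinates
#'
#' Per-SNP instrument weight beta_GE / SE_GD (y-axis) against the per-SNP
#' effect estimate exp(beta_GD / beta_GE) (x-axis; plot on a logarithmic
#' axis). Asymmetry of the funnel suggests directional pleiotropy.
#'
#' @param inst a \linkS4class{HarmonizedInstrument}.
#' @return data.frame(rsid, x, y) with attribute \code{"xlog" = TRUE} as
#'   the axis hint; SNPs with beta_GE = 0 are omitted with a warning.
#' @export
funnelData <- function(inst) {
  stopifnot(is(inst, "HarmonizedInstrument"))
  bad <- inst@betaExposure == 0
  if (any(bad)) {
    warning("omitting SNP(s) with zero exposure effect: ",
            paste(inst@snps[bad], collapse = ", "))
    inst <- inst[!bad]
  }
  out <- data.frame(rsid = inst@snps,
                    x = exp(inst@betaOutcome / inst@betaExposure),
                    y = inst@betaExposure / inst@seOutcome,
                    stringsAsFactors = FALSE)
  attr(out, "xlog") <- TRUE
  out
}

#' Forest-table assembly for a set of causal estimates
#'
#' Formats estimates the way an MR forest plot tabulates them: label,
#' number of SNPs, OR per SD and CI to two decimals, p-value to two
#' significant figures, plus a preformatted text column.
#'
#' @param estimates list of \linkS4class{CausalEstimate}s (may be empty).
#' @param labels row labels (risk factor names), one per estimate.
#' @param path optional file; when given the table is written
#'   tab-separated.
#' @return data.frame(label, method, n_snp, or, ci_low, ci_high, p, text).
#' @export
forestTable <- function(estimates, labels = NULL, path = NULL) {
  if (length(estimates) == 0) {
    out <- data.frame(label = character(), method = character(),
                      n_snp = integer(), or = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      p = numeric(), text = character(),
                      stringsAsFactors = FALSE)
  } else {
    if (is.null(labels)) labels <- paste0("estimate_", seq_along(estimates))
    stopifnot(length(labels) == length(estimates))
    out <- do.call(rbind, Map(function(e, lab) {
      or <- round(exp(e@theta), 2)
      lo <- round(exp(e@ciLow), 2); hi <- round(exp(e@ciHigh), 2)
      data.frame(label = lab, method = e@method, n_snp = e@nSNP,
                 or = or, ci_low = lo, ci_high = hi,
                 p = signif(e@pValue, 2),
                 text = sprintf("%.2f (%.2f-%.2f)", or, lo, hi),
                 stringsAsFactors = FALSE)
    }, estimates, labels))
    rownames(out) <- NULL
  }
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}

#' Mediated proportion by the product-of-coefficients method
#'
#' Fraction of the total exposure effect on the outcome transmitted through
#' a mediator, on the log-odds scale: (beta_exposure-to-mediator x
#' theta_mediator) / theta_exposure. The exposure-to-mediator effect (SD of
#' mediator per SD of exposure) is an external input, typically from a
#' published association study. An optional parametric bootstrap gives a
#' percentile CI when SEs are supplied.
#'
#' @param betaExpToMed exposure-to-mediator effect (SD/SD).
#' @param thetaMed mediator-to-outcome causal effect (log-odds per SD).
#' @param thetaExp total exposure-to-outcome causal effect (log-odds per
#'   SD); must be nonzero.
#' @param seExpToMed,seMed,seExp optional SEs for the bootstrap CI.
#' @param nBoot bootstrap draws (0 = point estimate only).
#' @param seed RNG seed for the bootstrap.
#' @return The mediated proportion; with a bootstrap, attribute
#'   \code{"ci"} carries the percentile 95% interval.
#' @examples
#' mediationProportion(0.15, log(1.82), log(1.56))  # ~ 0.2
#' @export
mediationProportion <- function(betaExpToMed, thetaMed, thetaExp,
                                seExpToMed = NULL, seMed = NULL,
                                seExp = NULL, nBoot = 0L, seed = 1L) {
  if (thetaExp == 0)
    stop("mediated proportion undefined: total effect is zero")
  prop <- betaExpToMed * thetaMed / thetaExp
  if (nBoot > 0) {
    if (is.null(seExpToMed) || is.null(seMed) || is.null(seExp))
      stop("bootstrap CI needs all three standard errors")
    set.seed(seed)
    draws <- stats::rnorm(nBoot, betaExpToMed, seExpToMed) *
      stats::rnorm(nBoot, thetaMed, seMed) /
      stats::rnorm(nBoot, thetaExp, seExp)
    attr(prop, "ci") <- unname(stats::quantile(draws, c(0.025, 0.975)))
  }
  prop
}
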