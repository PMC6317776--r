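#' Per-SNP Wald ratio estimates
#'
#' For SNP j the causal effect of a one-SD exposure increment on the
#' log-odds of the outcome is estimated by the ratio beta_GD / beta_GE,
#' with the first-order standard error SE_GD / |beta_GE| and
#' inverse-variance weight beta_GE^2 / SE_GD^2. With
#' \code{secondOrder = TRUE} the SE additionally propagates the exposure
#' sampling error (delta method) and the weight is the reciprocal of that
#' variance.
#'
#' @param inst a \linkS4class{HarmonizedInstrument}.
#' @param secondOrder include the SNP-exposure error in SE and weights.
#' @return data.frame(rsid, theta, se, weight). SNPs with beta_GE = 0 are
#'   excluded with a warning (ratio undefined).
#' @examples
#' i <- HarmonizedInstrument("rs1", 0.1, 0.01, 0.05, 0.02)
#' waldRatios(i)  # theta 0.5, se 0.2, weight 25
#' @export
waldRatios <- function(inst, secondOrder = FALSE) {
  stopifnot(is(inst, "HarmonizedInstrument"))
  bad <- inst@betaExposure == 0
  if (any(bad)) {
    warning("excluding SNP(s) with zero exposure effect: ",
            paste(inst@snps[bad], collapse = ", "))
    inst <- inst[!bad]
  }
  bx <- inst@betaExposure; by <- inst@betaOutcome
  sx <- inst@seExposure;   sy <- inst@seOutcome
  theta <- by / bx
  if (secondOrder) {
    v <- sy^2 / bx^2 + by^2 * sx^2 / bx^4
    data.frame(rsid = inst@snps, theta = theta, se = sqrt(v),
               weight = 1 / v, stringsAsFactors = FALSE)
  } else {
    data.frame(rsid = inst@snps, theta = theta, se = sy / abs(bx),
               weight = bx^2 / sy^2, stringsAsFactors = FALSE)
  }
}

.asRatios <- function(x, ...) {
  if (is(x, "HarmonizedInstrument")) waldRatios(x, ...) else x
}

#' Cochran Q heterogeneity across per-SNP causal estimates
#'
#' Q = sum w_j (theta_j - thetaRef)^2, referred to chi-square with
#' nSNP - 1 df; I-squared = max(0, (Q - df)/Q).
#'
#' @param ratios output of \code{\link{waldRatios}} (or an instrument).
#' @param thetaRef reference causal estimate.
#' @return list(q, df, pHet, i2).
#' @export
snpHeterogeneity <- function(ratios, thetaRef) {
  r <- .asRatios(ratios)
  stopifnot(nrow(r) >= 2)
  q <- sum(r$weight * (r$theta - thetaRef)^2)
  df <- nrow(r) - 1L
  list(q = q, df = df, pHet = stats::pchisq(q, df, lower.tail = FALSE),
       i2 = max(0, (q - df) / q))
}

#' Inverse-variance-weighted causal estimate
#'
#' Fixed-effect weighted average of per-SNP Wald ratios; serves as the
#' closed-form cross-check of the likelihood-based estimator. With a single
#' SNP the ratio is passed through with method tag \code{wald}.
#'
#' @param x a \linkS4class{HarmonizedInstrument} or \code{\link{waldRatios}}
#'   output.
#' @return A \linkS4class{CausalEstimate}.
#' @export
mrIVW <- function(x) {
  r <- .asRatios(x)
  if (nrow(r) < 2) {
    warning("single-SNP instrument: returning the Wald ratio")
    return(.causalEstimate("wald", r$theta, r$se, nSNP = 1L))
  }
  w <- r$weight
  th <- sum(w * r$theta) / sum(w)
  s <- 1 / sqrt(sum(w))
  het <- snpHeterogeneity(r, th)
  .causalEstimate("ivw", th, s, nSNP = nrow(r), qStat = het$q,
                  i2 = het$i2, pHet = het$pHet)
}

# Profile log-likelihood of theta for the bivariate normal measurement
# model: bx_j ~ N(xi_j, sx_j^2), by_j ~ N(theta xi_j, sy_j^2), with each
# xi_j at its closed-form conditional maximizer. Vectorized over theta.
.profileLogLik <- function(theta, bx, by, sx, sy) {
  vapply(theta, function(t) {
    xi <- (bx / sx^2 + t * by / sy^2) / (1 / sx^2 + t^2 / sy^2)
    -0.5 * sum((bx - xi)^2 / sx^2 + (by - t * xi)^2 / sy^2)
  }, numeric(1))
}

#' Likelihood-based causal estimate
#'
#' Maximizes the joint normal likelihood of the observed SNP-exposure and
#' SNP-outcome estimates over the causal parameter theta and the per-SNP
#' true exposure effects xi_j, the latter profiled out in closed form:
#' xi_j(theta) = (bx_j/sx_j^2 + theta by_j/sy_j^2) /
#' (1/sx_j^2 + theta^2/sy_j^2). Unlike IVW this accounts for sampling error
#' in the SNP-exposure estimates. The confidence interval is read off the
#' profile log-likelihood at a drop of qchisq(ciLevel, 1)/2 (1.92 units at
#' 95%), and the SE is back-computed from the CI width.
#'
#' @param inst a \linkS4class{HarmonizedInstrument} (>= 2 SNPs).
#' @param ciLevel confidence level (default 0.95).
#' @param thetaBounds search interval on the log-odds-per-SD scale.
#' @param profile return a \linkS4class{LikelihoodFit} carrying the xi_j
#'   and the profile curve instead of the bare estimate.
#' @return A \linkS4class{CausalEstimate}, or a
#'   \linkS4class{LikelihoodFit} when \code{profile = TRUE}. A maximizer on
#'   the search boundary raises an error carrying the profile curve in
#'   condition data.
#' @export
mrLikelihood <- function(inst, ciLevel = 0.95, thetaBounds = c(-5, 5),
                         profile = FALSE) {
  stopifnot(is(inst, "HarmonizedInstrument"), nSNP(inst) >= 2)
  bx <- inst@betaExposure; by <- inst@betaOutcome
  sx <- inst@seExposure;   sy <- inst@seOutcome
  f <- function(t) .profileLogLik(t, bx, by, sx, sy)
  opt <- stats::optimize(f, interval = thetaBounds, maximum = TRUE,
                         tol = 1e-10)
  th <- opt$maximum; llmax <- opt$objective
  if (min(abs(th - thetaBounds)) < 1e-4) {
    grid <- seq(thetaBounds[1], thetaBounds[2], length.out = 201)
    cond <- simpleError(sprintf(
      "likelihood maximizer at the search boundary (theta = %.4f)", th))
    cond$profile <- data.frame(theta = grid, logLik = f(grid))
    stop(cond)
  }
  drop <- stats::qchisq(ciLevel, df = 1) / 2
  target <- llmax - drop
  bracket <- function(side) {
    step <- 0.05
    a <- th
    repeat {
      b <- a + side * step
      if (b < thetaBounds[1] || b > thetaBounds[2]) {
        warning("profile CI truncated at the search boundary")
        return(max(min(b, thetaBounds[2]), thetaBounds[1]))
      }
      if (f(b) < target)
        return(stats::uniroot(function(t) f(t) - target, sort(c(a, b)),
                              tol = 1e-9)$root)
      a <- b
      step <- step * 2
    }
  }
  lo <- bracket(-1); hi <- bracket(+1)
  z2 <- 2 * stats::qnorm(0.5 + ciLevel / 2)
  s <- (hi - lo) / z2
  het <- if (nSNP(inst) >= 2 && all(bx != 0))
    snpHeterogeneity(waldRatios(inst), th)
  else list(q = NA_real_, i2 = NA_real_, pHet = NA_real_)
  est <- .causalEstimate("likelihood", th, s, ciLow = lo, ciHigh = hi,
                         nSNP = nSNP(inst), qStat = het$q, i2 = het$i2,
                         pHet = het$pHet)
  if (!profile) return(est)
  grid <- seq(lo - 2 * s, hi + 2 * s, length.out = 201)
  xi <- (bx / sx^2 + th * by / sy^2) / (1 / sx^2 + th^2 / sy^2)
  new("LikelihoodFit", estimate = est, xi = xi,
      profile = data.frame(theta = grid, logLik = f(grid)))
}

# Weighted median of ratios: cumulative standardized weights
# s_j = (cumsum(w)_j - w_j/2) / sum(w), linear interpolation at 0.5.
.weightedMedianPoint <- function(theta, w) {
  o <- order(theta)
  theta <- theta[o]; w <- w[o]
  dominant <- which(w / sum(w) > 0.5)
  if (length(dominant)) return(theta[dominant])
  s <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= s[1]) return(theta[1])
  if (0.5 >= s[length(s)]) return(theta[length(theta)])
  stats::approx(s, theta, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' Consistent when SNPs carrying at least half of the weight are valid
#' instruments; less sensitive than IVW to individual pleiotropic SNPs.
#' The point estimate interpolates the inverse-variance-weighted empirical
#' quantile function of the per-SNP ratios at 0.5; the SE is the standard
#' deviation of the estimate under a parametric bootstrap that redraws
#' beta_GE,j ~ N(bx_j, sx_j^2) and beta_GD,j ~ N(by_j, sy_j^2).
#'
#' @param inst a \linkS4class{HarmonizedInstrument} (>= 3 SNPs).
#' @param nBoot bootstrap resamples (default 10000); 0 skips the bootstrap
#'   and returns the point estimate with NA SE/CI.
#' @param seed RNG seed for the bootstrap (required when nBoot > 0).
#' @return A \linkS4class{CausalEstimate}. If one SNP holds more than half
#'   of the total weight its ratio is returned, with a warning.
#' @export
mrWeightedMedian <- function(inst, nBoot = 10000L, seed = NULL) {
  stopifnot(is(inst, "HarmonizedInstrument"), nSNP(inst) >= 3)
  r <- waldRatios(inst)
  if (max(r$weight) / sum(r$weight) > 0.5)
    warning("a single SNP holds > 50% of the weight; ",
            "the weighted median equals its ratio")
  th <- .weightedMedianPoint(r$theta, r$weight)
  if (nBoot == 0L)
    return(.causalEstimate("weighted_median", th, NA_real_,
                           ciLow = NA_real_, ciHigh = NA_real_,
                           pValue = NA_real_, nSNP = nSNP(inst)))
  if (is.null(seed)) stop("a seed is required for the bootstrap SE")
  stopifnot(nBoot >= 1)
  set.seed(seed)
  n <- nSNP(inst)
  bx <- inst@betaExposure; by <- inst@betaOutcome
  sx <- inst@seExposure;   sy <- inst@seOutcome
  boot <- vapply(seq_len(nBoot), function(b) {
    bxs <- stats::rnorm(n, bx, sx)
    bys <- stats::rnorm(n, by, sy)
    ok <- bxs != 0
    .weightedMedianPoint(bys[ok] / bxs[ok], bxs[ok]^2 / sy[ok]^2)
  }, numeric(1))
  s <- stats::sd(boot)
  .causalEstimate("weighted_median", th, s, nSNP = nSNP(inst))
}
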