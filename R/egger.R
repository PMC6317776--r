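# Closed-form weighted least squares of y on x with intercept,
# weights w; residual scale floored at 1 (multiplicative overdispersion,
# the convention for MR-Egger on summary data). Returns coefficients,
# their variances and the residual scale actually used.
.wlsFit <- function(x, y, w, floorDispersion = TRUE) {
  n <- length(x)
  sw <- sum(w)
  xbar <- sum(w * x) / sw
  sxx <- sum(w * (x - xbar)^2)
  if (sxx <= 0) stop("degenerate design: no spread in SNP-exposure effects")
  slope <- sum(w * (x - xbar) * y) / sxx
  intercept <- sum(w * y) / sw - slope * xbar
  rss <- sum(w * (y - intercept - slope * x)^2)
  disp <- rss / (n - 2)
  if (floorDispersion) disp <- max(disp, 1)
  list(slope = slope, intercept = intercept,
       slopeVar = disp / sxx,
       interceptVar = disp * (1 / sw + xbar^2 / sxx),
       dispersion = disp)
}

.eggerCoefs <- function(inst) {
  bx <- inst@betaExposure; by <- inst@betaOutcome
  neg <- bx < 0                       # orient every SNP to beta_GE >= 0
  bx[neg] <- -bx[neg]; by[neg] <- -by[neg]
  .wlsFit(bx, by, 1 / inst@seOutcome^2)
}

.eggerResult <- function(fit, n, lambdaGrid = numeric(0),
                         simexTrace = data.frame(), naive = list()) {
  tp <- function(est, se) 2 * stats::pt(-abs(est / se), df = n - 2)
  sSE <- sqrt(fit$slopeVar); iSE <- sqrt(fit$interceptVar)
  new("EggerResult", slope = fit$slope, slopeSE = sSE,
      slopeP = tp(fit$slope, sSE), intercept = fit$intercept,
      interceptSE = iSE, interceptP = tp(fit$intercept, iSE),
      nSNP = as.integer(n), lambdaGrid = lambdaGrid,
      simexTrace = simexTrace, naive = naive)
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of the SNP-outcome effects on the
#' SNP-exposure effects with an unconstrained intercept, each SNP oriented
#' so that its exposure effect is non-negative and weighted by
#' 1/SE_GD^2. The slope estimates the causal effect under the InSIDE
#' assumption; the intercept estimates the average directional pleiotropy
#' per SNP, and its two-sided t test (n-2 df, residual dispersion floored
#' at 1) is the directional-pleiotropy test.
#'
#' @param inst a \linkS4class{HarmonizedInstrument} (>= 3 SNPs).
#' @return An \linkS4class{EggerResult}.
#' @export
mrEgger <- function(inst) {
  stopifnot(is(inst, "HarmonizedInstrument"), nSNP(inst) >= 3)
  .eggerResult(.eggerCoefs(inst), nSNP(inst))
}

#' SIMEX measurement-error correction of MR-Egger
#'
#' Egger regression assumes no measurement error in the SNP-exposure
#' estimates (NOME); when SE_GE is non-negligible the slope is attenuated.
#' Simulation-extrapolation adds increasing extra error -- for each lambda
#' in the grid, \code{nRep} pseudo-datasets with beta_GE,j replaced by
#' beta_GE,j + N(0, lambda SE_GE,j^2) -- averages the Egger coefficients at
#' each lambda, fits a quadratic in lambda, and extrapolates to lambda = -1
#' (no error). Coefficient variances are extrapolated the same way using
#' the difference between the mean model-based variance and the
#' between-replicate variance at each lambda; a non-positive extrapolated
#' variance falls back to the naive model variance with a warning.
#'
#' @param inst a \linkS4class{HarmonizedInstrument} (>= 3 SNPs).
#' @param lambdaGrid added-error multipliers; must contain 0 and at least
#'   3 points (default 0, 0.5, 1, 1.5, 2).
#' @param nRep pseudo-datasets per lambda (default 1000, minimum 200).
#' @param seed RNG seed.
#' @return An \linkS4class{EggerResult} holding the extrapolated
#'   coefficients; slot \code{naive} carries the uncorrected fit and slot
#'   \code{simexTrace} the per-lambda averages.
#' @export
mrEggerSimex <- function(inst, lambdaGrid = c(0, 0.5, 1, 1.5, 2),
                         nRep = 1000L, seed = 1L) {
  stopifnot(is(inst, "HarmonizedInstrument"), nSNP(inst) >= 3)
  if (!any(lambdaGrid == 0) || length(lambdaGrid) < 3)
    stop("lambdaGrid must contain 0 and at least 3 points")
  if (any(lambdaGrid < 0)) stop("lambdaGrid must be non-negative")
  stopifnot(nRep >= 200)
  set.seed(seed)
  n <- nSNP(inst)
  bx <- inst@betaExposure; by <- inst@betaOutcome
  sx <- inst@seExposure; w <- 1 / inst@seOutcome^2
  onefit <- function(bxs) {
    neg <- bxs < 0
    .wlsFit(ifelse(neg, -bxs, bxs), ifelse(neg, -by, by), w)
  }
  naive <- .eggerCoefs(inst)
  trace <- lapply(sort(lambdaGrid), function(lam) {
    if (lam == 0) {
      return(data.frame(lambda = 0, slope = naive$slope,
                        intercept = naive$intercept,
                        slopeVar = naive$slopeVar,
                        interceptVar = naive$interceptVar))
    }
    sl <- ic <- slv <- icv <- numeric(nRep)
    for (b in seq_len(nRep)) {
      fit <- onefit(bx + stats::rnorm(n, 0, sqrt(lam) * sx))
      sl[b] <- fit$slope; ic[b] <- fit$intercept
      slv[b] <- fit$slopeVar; icv[b] <- fit$interceptVar
    }
    data.frame(lambda = lam, slope = mean(sl), intercept = mean(ic),
               slopeVar = mean(slv) - stats::var(sl),
               interceptVar = mean(icv) - stats::var(ic))
  })
  trace <- do.call(rbind, trace)
  extrap <- function(y) {
    fit <- stats::lm(y ~ lambda + I(lambda^2), data = trace)
    unname(stats::predict(fit, data.frame(lambda = -1)))
  }
  slope <- extrap(trace$slope)
  intercept <- extrap(trace$intercept)
  slopeVar <- extrap(trace$slopeVar)
  interceptVar <- extrap(trace$interceptVar)
  if (!is.finite(slopeVar) || slopeVar <= 0) {
    warning("non-positive extrapolated slope variance; using naive variance")
    slopeVar <- naive$slopeVar
  }
  if (!is.finite(interceptVar) || interceptVar <= 0) {
    warning("non-positive extrapolated intercept variance; ",
            "using naive variance")
    interceptVar <- naive$interceptVar
  }
  .eggerResult(list(slope = slope, intercept = intercept,
                    slopeVar = slopeVar, interceptVar = interceptVar),
               n, lambdaGrid = sort(lambdaGrid), simexTrace = trace,
               naive = naive)
}
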