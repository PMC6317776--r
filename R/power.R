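#' A priori power of a two-sample MR analysis with a binary outcome
#'
#' Binary-outcome approximation for the power of an instrumental-variable
#' analysis: the IV estimate of the log odds ratio per SD of exposure has
#' asymptotic standard error 1 / sqrt(n k (1-k) r2), where n is the
#' outcome-study size, k the case fraction, and r2 the exposure variance
#' explained by the instrument. Two-sided power at level alpha is
#' Phi(mu - z) + Phi(-mu - z) with mu = sqrt(n r2 k (1-k)) |ln OR| and
#' z = z_\{1-alpha/2\}; at OR = 1 this equals alpha and it is symmetric in
#' OR <-> 1/OR.
#'
#' @param nTotal total outcome-study sample size (cases + controls).
#' @param caseFraction case fraction k in (0,1).
#' @param r2 exposure variance explained by the instrument, in (0,1).
#' @param orPerSD odds ratio per SD of the exposure (> 0).
#' @param alpha two-sided significance level (default 0.05).
#' @return Power in (0,1). Vectorized over \code{r2} and \code{orPerSD}.
#' @examples
#' mrPower(31190, 10784 / 31190, r2 = 0.095, orPerSD = 1.2)
#' @export
mrPower <- function(nTotal, caseFraction, r2, orPerSD, alpha = 0.05) {
  stopifnot(nTotal > 0, caseFraction > 0, caseFraction < 1,
            all(r2 > 0), all(r2 < 1), all(orPerSD > 0),
            alpha > 0, alpha < 1)
  z <- stats::qnorm(1 - alpha / 2)
  mu <- sqrt(nTotal * r2 * caseFraction * (1 - caseFraction)) *
    abs(log(orPerSD))
  stats::pnorm(mu - z) + stats::pnorm(-mu - z)
}

#' Power across a grid of instrument strengths and effect sizes
#'
#' @inheritParams mrPower
#' @param r2Grid,orGrid non-empty grids of variance-explained and odds
#'   ratio values.
#' @return data.frame(r2, or, power), one row per grid combination; power
#'   is monotone non-decreasing in r2 and in |ln OR|.
#' @export
powerCurve <- function(nTotal, caseFraction, r2Grid, orGrid,
                       alpha = 0.05) {
  stopifnot(length(r2Grid) >= 1, length(orGrid) >= 1)
  g <- expand.grid(r2 = r2Grid, or = orGrid, KEEP.OUT.ATTRS = FALSE)
  g$power <- mrPower(nTotal, caseFraction, g$r2, g$or, alpha)
  g
}

#' Monte-Carlo check of the analytic MR power
#'
#' Simulates the generative model the analytic formula approximates: a
#' standardized genetic score explaining \code{r2} of a standard-normal
#' exposure, a logistic disease model with log odds ratio ln(OR) per SD of
#' exposure, case-control sampling at the requested case fraction, and a
#' Wald test of the score coefficient in a logistic regression of disease
#' on the score. Serves as the independent oracle for \code{\link{mrPower}}.
#'
#' @inheritParams mrPower
#' @param nRep simulation replicates (default 2000).
#' @param seed RNG seed.
#' @return Empirical power (rejection rate at level alpha).
#' @export
simulatePower <- function(nTotal, caseFraction, r2, orPerSD,
                          alpha = 0.05, nRep = 2000L, seed = 1L) {
  set.seed(seed)
  nCase <- round(nTotal * caseFraction)
  nCtrl <- nTotal - nCase
  # population prevalence matching the case fraction keeps the sampling cheap
  b0 <- stats::qlogis(caseFraction)
  bTheta <- log(orPerSD)
  rej <- logical(nRep)
  for (r in seq_len(nRep)) {
    cases <- matrix(numeric(0), 0, 1); ctrls <- matrix(numeric(0), 0, 1)
    while (nrow(cases) < nCase || nrow(ctrls) < nCtrl) {
      m <- 2L * nTotal
      s <- stats::rnorm(m, 0, sqrt(r2))          # genetic score, per SD of X
      x <- s + stats::rnorm(m, 0, sqrt(1 - r2))  # exposure
      d <- stats::rbinom(m, 1, stats::plogis(b0 + bTheta * x))
      cases <- rbind(cases, cbind(s[d == 1]))
      ctrls <- rbind(ctrls, cbind(s[d == 0]))
    }
    sv <- c(cases[seq_len(nCase), 1], ctrls[seq_len(nCtrl), 1])
    y <- rep(1:0, c(nCase, nCtrl))
    fit <- stats::glm.fit(cbind(1, sv), y,
                          family = stats::binomial())
    cf <- fit$coefficients[2]
    # Wald SE from the IRLS weights at convergence
    X <- cbind(1, sv)
    XtWX <- crossprod(X * sqrt(fit$weights))
    sec <- sqrt(solve(XtWX)[2, 2])
    rej[r] <- abs(cf / sec) > stats::qnorm(1 - alpha / 2)
  }
  mean(rej)
}
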