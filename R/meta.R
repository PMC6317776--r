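#' Recover a standard error from a printed 95% confidence interval
#'
#' The single CI-to-SE convention used throughout: on the log scale,
#' se = (ln(ciHigh) - ln(ciLow)) / (2 z), z = 1.96 at 95%.
#'
#' @param ciLow,ciHigh confidence limits (odds-ratio scale when
#'   \code{logInput = FALSE}, the default).
#' @param level confidence level of the interval (default 0.95).
#' @param logInput limits already on the log-odds scale.
#' @return The standard error on the log-odds scale.
#' @examples
#' ciToSE(1.44, 1.70)   # BMI-style interval
#' @export
ciToSE <- function(ciLow, ciHigh, level = 0.95, logInput = FALSE) {
  z <- stats::qnorm(0.5 + level / 2)
  if (!logInput) { ciLow <- log(ciLow); ciHigh <- log(ciHigh) }
  (ciHigh - ciLow) / (2 * z)
}

#' Fixed-effect meta-analysis of stratum estimates
#'
#' Inverse-variance pooling of stratum-specific causal estimates (e.g. the
#' four study sources of an outcome GWAS), with the Cochran Q
#' between-stratum heterogeneity test on n - 1 degrees of freedom and the
#' I-squared share of variance attributable to stratum heterogeneity.
#'
#' @param theta stratum estimates on the log-odds scale (or a data.frame
#'   with columns \code{theta} and \code{se}).
#' @param se stratum standard errors.
#' @param labels optional stratum labels.
#' @return list(theta, se, ciLow, ciHigh, q, df, pHet, i2).
#' @export
fixedEffectMeta <- function(theta, se = NULL, labels = NULL) {
  if (is.data.frame(theta)) {
    se <- theta$se
    labels <- theta$label
    theta <- theta$theta
  }
  stopifnot(length(theta) >= 1, length(se) == length(theta), all(se > 0))
  w <- 1 / se^2
  th <- sum(w * theta) / sum(w)
  s <- 1 / sqrt(sum(w))
  q <- sum(w * (theta - th)^2)
  df <- length(theta) - 1L
  pHet <- if (df > 0) stats::pchisq(q, df, lower.tail = FALSE) else NA_real_
  list(theta = th, se = s, ciLow = th - 1.959964 * s,
       ciHigh = th + 1.959964 * s, q = q, df = df, pHet = pHet,
       i2 = if (q > 0) max(0, (q - df) / q) else 0)
}

#' Two-group heterogeneity test (1 degree of freedom)
#'
#' z = (theta_a - theta_b) / sqrt(se_a^2 + se_b^2) with a two-sided normal
#' p-value; z^2 equals the 2-stratum fixed-effect Q statistic exactly.
#' Used for e.g. male-vs-female heterogeneity of a stratified estimate.
#'
#' @param thetaA,seA,thetaB,seB the two estimates (log-odds scale) and SEs.
#' @return list(z, p).
#' @export
twoGroupHeterogeneity <- function(thetaA, seA, thetaB, seB) {
  stopifnot(seA > 0, seB > 0)
  z <- (thetaA - thetaB) / sqrt(seA^2 + seB^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Difference test between two exposures' causal estimates
#'
#' The two-group z test applied to two \linkS4class{CausalEstimate}s
#' (e.g. diastolic vs systolic blood pressure). The estimates share the
#' outcome sample, so independence is an approximation; the output carries
#' an explicit \code{independenceAssumed} flag.
#'
#' @param a,b \linkS4class{CausalEstimate}s on the log-odds scale.
#' @return list(z, p, independenceAssumed = TRUE).
#' @export
estimateDifferenceTest <- function(a, b) {
  stopifnot(is(a, "CausalEstimate"), is(b, "CausalEstimate"))
  res <- twoGroupHeterogeneity(a@theta, a@se, b@theta, b@se)
  res$independenceAssumed <- TRUE
  res
}

#' Read stratum estimates from a tab-separated file
#'
#' Expected columns: \code{label}, then either \code{theta} and \code{se},
#' or \code{or} (or \code{theta}) with \code{ci_low}/\code{ci_high} from
#' which the SE is recovered via \code{\link{ciToSE}}.
#'
#' @param path file path.
#' @param input \code{"or"} if effect columns are odds ratios (default) or
#'   \code{"log"} if already log-odds.
#' @return data.frame(label, theta, se) on the log-odds scale.
#' @export
readStrata <- function(path, input = c("or", "log")) {
  input <- match.arg(input)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  eff <- if ("or" %in% names(df)) df$or else df$theta
  theta <- if (input == "or") log(eff) else eff
  se <- if ("se" %in% names(df) && !all(is.na(df$se))) df$se
        else ciToSE(df$ci_low, df$ci_high, logInput = input == "log")
  data.frame(label = df$label, theta = theta, se = se,
             stringsAsFactors = FALSE)
}
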