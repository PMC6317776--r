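.NONPAL_PAIRS <- rbind(c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
                       c("T", "G"), c("T", "C"), c("G", "T"), c("C", "T"))
.PAL_PAIRS <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

#' Draw the per-SNP ground truth of a simulated instrument
#'
#' Effect-allele frequencies are uniform on the configured range. Per-allele
#' SNP-exposure effects gamma_j are drawn half-normal (effect alleles are
#' exposure-increasing in the truth table; coding is randomized later by
#' \code{\link{scrambleCoding}}) and rescaled so the instrument explains
#' exactly the target variance of the standardized exposure:
#' sum_j 2 eaf_j (1 - eaf_j) gamma_j^2 = targetR2. A configured fraction of
#' SNPs receives a direct (pleiotropic) outcome effect alpha_j ~
#' N(meanDirect, sdDirect^2), correlated with instrument strength through a
#' Gaussian copula when insideCorr is nonzero (an InSIDE violation).
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @return data.frame(rsid, eaf, gamma, alpha, valid).
#' @export
simulateInstrumentTruth <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  if (cfg@targetR2 / cfg@nSNP > 0.05)
    stop("targetR2 too large for nSNP: mean per-SNP variance explained ",
         "would exceed 5%")
  set.seed(cfg@seed)
  n <- cfg@nSNP
  f <- stats::runif(n, cfg@eafRange[1], cfg@eafRange[2])
  rho <- cfg@insideCorr
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  gamma <- stats::qnorm(0.5 + stats::pnorm(z1) / 2)  # half-normal via copula
  scale <- sqrt(cfg@targetR2 / sum(2 * f * (1 - f) * gamma^2))
  gamma <- gamma * scale
  nInvalid <- round(cfg@fractionInvalid * n)
  invalid <- if (nInvalid > 0) sample.int(n, nInvalid) else integer(0)
  alpha <- numeric(n)
  alpha[invalid] <- cfg@meanDirect + cfg@sdDirect * z2[invalid]
  data.frame(rsid = sprintf("rs%05d", seq_len(n)), eaf = f, gamma = gamma,
             alpha = alpha, valid = !seq_len(n) %in% invalid,
             stringsAsFactors = FALSE)
}

#' Simulate a two-sample pair of summary-statistic tables
#'
#' Sampling noise follows the standard summary-statistic approximations
#' for an additive biallelic variant: SE_GE,j = 1/sqrt(2 f_j (1-f_j)
#' n_exposure) for a standardized continuous exposure, and SE_GD,j =
#' 1/sqrt(2 f_j (1-f_j) n k (1-k)) for a log-odds outcome effect with case
#' fraction k. The true per-allele outcome effect is theta_true gamma_j +
#' alpha_j. Observed effects are normal around the truth; p-values are
#' two-sided normal; info is set to 1.
#'
#' @param truth output of \code{\link{simulateInstrumentTruth}}.
#' @param cfg the \linkS4class{SimulationConfig}.
#' @param palindromicFraction fraction of SNPs assigned palindromic (A/T or
#'   C/G) allele pairs, to exercise strand-ambiguity handling.
#' @param seed optional RNG seed; NULL continues the current stream.
#' @return list(exposure, outcome) of data.frames in
#'   \code{\link{readSumstats}} layout.
#' @export
simulateSumstatsPair <- function(truth, cfg, palindromicFraction = 0,
                                 seed = NULL) {
  stopifnot(is(cfg, "SimulationConfig"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(truth)
  f <- truth$eaf
  nTot <- cfg@nCases + cfg@nControls
  k <- cfg@nCases / nTot
  sx <- 1 / sqrt(2 * f * (1 - f) * cfg@nExposure)
  sy <- 1 / sqrt(2 * f * (1 - f) * nTot * k * (1 - k))
  muY <- cfg@thetaTrue * truth$gamma + truth$alpha
  bx <- stats::rnorm(n, truth$gamma, sx)
  by <- stats::rnorm(n, muY, sy)
  nPal <- round(palindromicFraction * n)
  isPal <- seq_len(n) %in% sample.int(n, nPal)
  pairs <- .NONPAL_PAIRS[sample.int(nrow(.NONPAL_PAIRS), n, TRUE), ,
                         drop = FALSE]
  if (nPal > 0)
    pairs[isPal, ] <- .PAL_PAIRS[sample.int(nrow(.PAL_PAIRS), nPal, TRUE), ,
                                 drop = FALSE]
  mk <- function(beta, sexx, nn) data.frame(
    rsid = truth$rsid, chrom = "1", pos = seq_len(n) * 1000L,
    effect_allele = pairs[, 1], other_allele = pairs[, 2], eaf = f,
    beta = beta, se = sexx,
    pval = pmax(2 * stats::pnorm(-abs(beta) / sexx), 1e-300),
    info = 1, n = nn, stringsAsFactors = FALSE)
  list(exposure = mk(bx, sx, cfg@nExposure), outcome = mk(by, sy, nTot))
}

#' Randomize allele and strand coding of a summary-statistic table
#'
#' Per SNP, independently swaps the effect/other alleles (negating beta and
#' reflecting eaf) and/or complements the strand, emulating the arbitrary
#' coding conventions of real GWAS releases. The original orientation is
#' retained in audit columns \code{.orig_effect_allele} /
#' \code{.orig_other_allele} (kept from the first scramble if applied
#' repeatedly), so tests can verify that harmonization inverts the
#' scrambling exactly.
#'
#' @param records a summary-statistic data.frame.
#' @param seed optional RNG seed; NULL continues the current stream.
#' @param pSwap,pComplement per-SNP probabilities of an allele swap and of
#'   a strand complement (defaults 0.5).
#' @return The re-coded table.
#' @export
scrambleCoding <- function(records, seed = NULL, pSwap = 0.5,
                           pComplement = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(records)
  if (!".orig_effect_allele" %in% names(records)) {
    records$.orig_effect_allele <- records$effect_allele
    records$.orig_other_allele <- records$other_allele
  }
  swap <- stats::runif(n) < pSwap
  comp <- stats::runif(n) < pComplement
  ea <- records$effect_allele; oa <- records$other_allele
  records$effect_allele <- ifelse(swap, oa, ea)
  records$other_allele <- ifelse(swap, ea, oa)
  records$beta <- ifelse(swap, -records$beta, records$beta)
  if ("eaf" %in% names(records))
    records$eaf <- ifelse(swap, 1 - records$eaf, records$eaf)
  records$effect_allele <- ifelse(comp, .complement[records$effect_allele],
                                  records$effect_allele)
  records$other_allele <- ifelse(comp, .complement[records$other_allele],
                                 records$other_allele)
  records
}

#' Simulate a full two-sample instrument with known ground truth
#'
#' Draws the truth table, the exposure/outcome summary statistics, applies
#' coding scrambling when configured, and harmonizes the pair. The whole
#' procedure is a deterministic function of the config (one seed).
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @param palindromicFraction fraction of palindromic allele pairs (when
#'   scrambling is enabled, defaults to 0.1; otherwise 0).
#' @return list(truth, exposure, outcome, instrument).
#' @examples
#' sim <- simulateInstrument(simConfig(nSNP = 30, seed = 11))
#' mrIVW(sim$instrument)
#' @export
simulateInstrument <- function(cfg, palindromicFraction =
                                 if (cfg@scrambleCoding) 0.1 else 0) {
  truth <- simulateInstrumentTruth(cfg)       # sets the seed
  pair <- simulateSumstatsPair(truth, cfg, palindromicFraction)
  if (cfg@scrambleCoding) {
    pair$exposure <- scrambleCoding(pair$exposure)
    pair$outcome <- scrambleCoding(pair$outcome)
  }
  inst <- harmonize(pair$exposure, pair$outcome)
  list(truth = truth, exposure = pair$exposure, outcome = pair$outcome,
       instrument = inst)
}

#' Write simulated summary statistics in the package's TSV dialect
#'
#' @param sim output of \code{\link{simulateInstrument}} (or a
#'   list(exposure, outcome, truth)).
#' @param dir output directory (created if needed).
#' @return The directory, invisibly; writes exposure.tsv, outcome.tsv and
#'   truth.tsv.
#' @export
writeSimulated <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(sim$exposure, "exposure.tsv")
  wt(sim$outcome, "outcome.tsv")
  wt(sim$truth, "truth.tsv")
  invisible(dir)
}
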