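# Orientation of an outcome allele pair relative to the exposure pair:
# "same" (use beta as reported), "swap" (flip sign, eaf -> 1-eaf),
# "palindromic" (undecidable from alleles alone), or "mismatch".
.alleleOrientation <- function(eaX, oaX, eaY, oaY) {
  if (.isPalindromic(eaX, oaX)) return("palindromic")
  if (eaY == eaX && oaY == oaX) return("same")
  if (eaY == oaX && oaY == eaX) return("swap")
  ceaY <- .complement[eaY]; coaY <- .complement[oaY]
  if (ceaY == eaX && coaY == oaX) return("same")
  if (ceaY == oaX && coaY == eaX) return("swap")
  "mismatch"
}

#' Harmonize exposure and outcome summary statistics into an instrument
#'
#' Aligns each exposure SNP's outcome association to the exposure's effect
#' allele. Direct and allele-swapped matches are resolved exactly (a swap
#' negates the outcome beta and reflects the frequency); strand complements
#' are resolved by complementing first. Palindromic variants (A/T or C/G),
#' whose strand cannot be read off the alleles, are substituted by a proxy
#' when one is supplied, oriented by comparing which side of 0.5 the effect
#' allele frequency falls on in the two datasets when the minor allele
#' frequency is at most \code{mafAmbiguousThreshold} in both, and excluded
#' otherwise. Every input SNP ends up exactly once in either the retained
#' set or the exclusion log.
#'
#' @param exposure,outcome data.frames in \code{\link{readSumstats}} layout.
#' @param mafAmbiguousThreshold palindromic variants with minor allele
#'   frequency above this in either dataset are excluded (default 0.4).
#' @param proxyTable optional data.frame(rsid, proxy): substitutes for
#'   palindromic or outcome-missing SNPs; the proxy must itself be present
#'   (and resolvable) in both datasets. The substituted record keeps the
#'   original rsid.
#' @param palindromicMode \code{"freq"} (default) orients sub-threshold
#'   palindromic variants by allele frequency; \code{"same_strand"} assumes
#'   both datasets report the same strand and aligns by allele labels alone
#'   (the MAF exclusion still applies).
#' @return A \linkS4class{HarmonizedInstrument}.
#' @examples
#' exp <- data.frame(rsid = "rs1", effect_allele = "A", other_allele = "G",
#'                   eaf = 0.3, beta = 0.1, se = 0.01)
#' out <- data.frame(rsid = "rs1", effect_allele = "G", other_allele = "A",
#'                   eaf = 0.7, beta = -0.05, se = 0.02)
#' harmonize(exp, out)   # outcome beta flipped to +0.05
#' @export
harmonize <- function(exposure, outcome, mafAmbiguousThreshold = 0.4,
                      proxyTable = NULL,
                      palindromicMode = c("freq", "same_strand")) {
  palindromicMode <- match.arg(palindromicMode)
  stopifnot(mafAmbiguousThreshold > 0, mafAmbiguousThreshold < 0.5)
  if (anyDuplicated(exposure$rsid))
    stop("duplicate rsids in exposure table")
  if (anyDuplicated(outcome$rsid)) {
    warning("duplicate rsids in outcome table; keeping first occurrence")
    outcome <- outcome[!duplicated(outcome$rsid), , drop = FALSE]
  }
  keep <- list(); excl <- list()
  for (i in seq_len(nrow(exposure))) {
    x <- exposure[i, ]
    res <- .harmonizeOne(x, outcome, mafAmbiguousThreshold, palindromicMode)
    if (is.null(res$reason)) {
      keep[[length(keep) + 1L]] <- res
      next
    }
    # try a proxy substitution before giving up
    if (!is.null(proxyTable) && x$rsid %in% proxyTable$rsid &&
        res$reason %in% c("missing_in_outcome", "palindromic_maf_gt_threshold",
                          "palindromic_missing_eaf")) {
      proxy <- proxyTable$proxy[match(x$rsid, proxyTable$rsid)]
      px <- exposure[exposure$rsid == proxy, ]
      pres <- if (nrow(px) == 1)
        .harmonizeOne(px, outcome, mafAmbiguousThreshold, palindromicMode)
      else list(reason = "proxy_not_in_exposure")
      if (is.null(pres$reason)) {
        pres$rsid <- x$rsid           # record kept under the original id
        pres$flag <- "substituted_by_proxy"
        keep[[length(keep) + 1L]] <- pres
        next
      }
    }
    excl[[length(excl) + 1L]] <- data.frame(
      rsid = x$rsid, reason = res$reason, stringsAsFactors = FALSE)
  }
  kdf <- if (length(keep)) do.call(rbind, lapply(keep, as.data.frame))
         else data.frame(rsid = character(), beta_exposure = numeric(),
                         se_exposure = numeric(), beta_outcome = numeric(),
                         se_outcome = numeric(), eaf = numeric(),
                         flag = character(), stringsAsFactors = FALSE)
  edf <- if (length(excl)) do.call(rbind, excl)
         else data.frame(rsid = character(), reason = character(),
                         stringsAsFactors = FALSE)
  if (anyDuplicated(kdf$rsid))
    stop("proxy substitution produced a duplicate rsid in the instrument")
  HarmonizedInstrument(kdf$rsid, kdf$beta_exposure, kdf$se_exposure,
                       kdf$beta_outcome, kdf$se_outcome, kdf$eaf,
                       kdf$flag, edf)
}

.harmonizeOne <- function(x, outcome, mafThr, mode) {
  j <- match(x$rsid, outcome$rsid)
  if (is.na(j)) return(list(reason = "missing_in_outcome"))
  y <- outcome[j, ]
  ori <- .alleleOrientation(x$effect_allele, x$other_allele,
                            y$effect_allele, y$other_allele)
  rec <- list(rsid = x$rsid, beta_exposure = x$beta, se_exposure = x$se,
              beta_outcome = y$beta, se_outcome = y$se, eaf = x$eaf,
              flag = "as_is")
  if (ori == "mismatch") return(list(reason = "allele_mismatch"))
  if (ori == "swap") {
    rec$beta_outcome <- -y$beta
    rec$flag <- "allele_flipped"
    return(rec)
  }
  if (ori == "same") return(rec)
  # palindromic: allele labels must still agree under a same-strand reading
  labels_ok <- (y$effect_allele == x$effect_allele &&
                y$other_allele == x$other_allele) ||
               (y$effect_allele == x$other_allele &&
                y$other_allele == x$effect_allele)
  if (!labels_ok) return(list(reason = "allele_mismatch"))
  if (is.na(x$eaf) || is.na(y$eaf))
    return(list(reason = "palindromic_missing_eaf"))
  maf <- function(f) pmin(f, 1 - f)
  if (maf(x$eaf) > mafThr || maf(y$eaf) > mafThr)
    return(list(reason = "palindromic_maf_gt_threshold"))
  if (mode == "same_strand") {
    if (y$effect_allele == x$effect_allele) return(rec)
    rec$beta_outcome <- -y$beta
    rec$flag <- "allele_flipped"
    return(rec)
  }
  # frequency orientation: the outcome's effect allele is taken to be the
  # exposure's effect allele iff its frequency falls on the same side of 0.5
  if ((x$eaf < 0.5) != (y$eaf < 0.5)) rec$beta_outcome <- -y$beta
  rec$flag <- "palindromic_kept_by_freq"
  rec
}

#' Write / read a harmonized instrument as tab-separated text
#'
#' Fixed column order: rsid, beta_exposure, se_exposure, beta_outcome,
#' se_outcome, eaf, flag. \code{writeExclusions} writes the exclusion log
#' as (rsid, reason).
#'
#' @param inst a \linkS4class{HarmonizedInstrument}.
#' @param path output (input) file path.
#' @return \code{readInstrument} returns the instrument (with an empty
#'   exclusion log); the writers return the path invisibly.
#' @export
writeInstrument <- function(inst, path) {
  df <- data.frame(rsid = inst@snps, beta_exposure = inst@betaExposure,
                   se_exposure = inst@seExposure,
                   beta_outcome = inst@betaOutcome,
                   se_outcome = inst@seOutcome, eaf = inst@eaf,
                   flag = inst@flag, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeInstrument
#' @export
readInstrument <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  HarmonizedInstrument(df$rsid, df$beta_exposure, df$se_exposure,
                       df$beta_outcome, df$se_outcome, df$eaf, df$flag)
}

#' @rdname writeInstrument
#' @export
writeExclusions <- function(inst, path) {
  utils::write.table(inst@exclusions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
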