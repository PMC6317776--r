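.STD_FIELDS <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                 "eaf", "beta", "se", "pval", "info", "n")
.MANDATORY  <- c("rsid", "effect_allele", "other_allele", "beta", "se")

.complement <- c(A = "T", C = "G", G = "C", T = "A")

.isPalindromic <- function(a1, a2) .complement[a1] == a2

.num <- function(x) suppressWarnings(as.numeric(x))

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab-separated table of per-SNP association statistics and
#' validates each row. Alleles are uppercased on ingest. Rows violating the
#' field invariants (non-ACGT alleles, identical alleles, non-positive SE,
#' unparseable numerics, eaf outside (0,1), p outside (0,1]) are dropped
#' from the returned table and collected, with row numbers and reasons, in
#' the \code{"validation"} attribute.
#'
#' @param path path to a tab-separated file with a header line.
#' @param columnMap named character vector mapping standard field names
#'   (\code{rsid, chrom, pos, effect_allele, other_allele, eaf, beta, se,
#'   pval, info, n}) to the file's column names. Unmapped optional fields
#'   are filled with NA.
#' @param sep field separator, default tab.
#' @return data.frame with the standard columns; attribute
#'   \code{"validation"} holds a data.frame(row, rsid, reason) of rejected
#'   rows.
#' @examples
#' f <- system.file("extdata", "example_exposure.tsv", package = "summaryMR")
#' head(readSumstats(f))
#' @export
readSumstats <- function(path, columnMap = NULL, sep = "\t") {
  if (!file.exists(path)) stop("summary-statistics file not found: ", path)
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  map <- stats::setNames(.STD_FIELDS, .STD_FIELDS)
  if (!is.null(columnMap)) map[names(columnMap)] <- columnMap
  missing_mand <- .MANDATORY[!map[.MANDATORY] %in% names(raw)]
  if (length(missing_mand))
    stop("mandatory column(s) not found in file: ",
         paste(sprintf("%s (mapped to '%s')", missing_mand,
                       map[missing_mand]), collapse = ", "))
  out <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
    rsid = raw[[map["rsid"]]],
    chrom = if (map["chrom"] %in% names(raw))
      as.character(raw[[map["chrom"]]]) else NA_character_,
    pos = if (map["pos"] %in% names(raw))
      as.integer(.num(raw[[map["pos"]]])) else NA_integer_,
    effect_allele = toupper(raw[[map["effect_allele"]]]),
    other_allele = toupper(raw[[map["other_allele"]]]),
    eaf = if (map["eaf"] %in% names(raw)) .num(raw[[map["eaf"]]]) else NA_real_,
    beta = .num(raw[[map["beta"]]]),
    se = .num(raw[[map["se"]]]),
    pval = if (map["pval"] %in% names(raw))
      .num(raw[[map["pval"]]]) else NA_real_,
    info = if (map["info"] %in% names(raw))
      .num(raw[[map["info"]]]) else NA_real_,
    n = if (map["n"] %in% names(raw))
      as.integer(.num(raw[[map["n"]]])) else NA_integer_)
  .validateSumstats(out)
}

# Row-level invariant checks shared by readSumstats and the harmonizer.
.validateSumstats <- function(out) {
  reasons <- character(nrow(out))
  flag <- function(bad, why) {
    bad <- which(bad & reasons == "")
    reasons[bad] <<- why
  }
  flag(!out$effect_allele %in% names(.complement), "invalid_effect_allele")
  flag(!out$other_allele %in% names(.complement), "invalid_other_allele")
  flag(out$effect_allele == out$other_allele, "identical_alleles")
  flag(!is.finite(out$beta), "unparseable_beta")
  flag(!is.finite(out$se) | out$se <= 0, "invalid_se")
  flag(!is.na(out$eaf) & (out$eaf <= 0 | out$eaf >= 1), "eaf_out_of_range")
  flag(!is.na(out$pval) & (out$pval <= 0 | out$pval > 1), "pval_out_of_range")
  flag(!is.na(out$info) & (out$info < 0 | out$info > 1), "info_out_of_range")
  bad <- reasons != ""
  report <- data.frame(row = which(bad), rsid = out$rsid[bad],
                       reason = reasons[bad], stringsAsFactors = FALSE)
  if (nrow(report))
    warning(sprintf("%d row(s) failed validation (see attr 'validation')",
                    nrow(report)), call. = FALSE)
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "validation") <- report
  out
}

#' Filter candidate instrument SNPs on significance and imputation quality
#'
#' Retains SNPs with exposure p-value strictly below \code{pThreshold} and
#' imputation info score at least \code{infoThreshold}. A missing info score
#' passes (the info filter targets imputed outcome variants). Both
#' comparisons are strict in the direction of exclusion: a p-value exactly
#' at the genome-wide threshold is excluded, an info score just below the
#' cutoff is excluded.
#'
#' @param records data.frame from \code{\link{readSumstats}}.
#' @param pThreshold genome-wide significance threshold (default 5e-8).
#' @param infoThreshold minimum imputation info score (default 0.7).
#' @return The retained rows; attribute \code{"exclusions"} holds a
#'   data.frame(rsid, reason) for dropped SNPs. An empty survivor set is
#'   returned as a zero-row data.frame (with a message), not an error.
#' @export
filterInstrument <- function(records, pThreshold = 5e-8,
                             infoThreshold = 0.7) {
  stopifnot(pThreshold > 0, pThreshold <= 1,
            infoThreshold > 0, infoThreshold <= 1)
  p_ok <- !is.na(records$pval) & records$pval < pThreshold
  info_ok <- is.na(records$info) | records$info >= infoThreshold
  reason <- ifelse(!p_ok, "pval_above_threshold",
                   ifelse(!info_ok, "info_below_threshold", ""))
  keep <- p_ok & info_ok
  excl <- data.frame(rsid = records$rsid[!keep], reason = reason[!keep],
                     stringsAsFactors = FALSE)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  if (nrow(out) == 0)
    message("no SNPs survive the instrument filters")
  out
}

#' Read a pairwise LD matrix
#'
#' Accepts either a square matrix layout (header row and first column hold
#' rsids) or a long triplet layout with columns \code{rsid_a, rsid_b, r2}.
#' Unlisted pairs in the long layout are taken as R-squared 0.
#'
#' @param path file path.
#' @param format \code{"auto"} (detect from the header), \code{"square"} or
#'   \code{"long"}.
#' @return An \linkS4class{LDMatrix}.
#' @export
readLDMatrix <- function(path, format = c("auto", "square", "long")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("LD file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (format == "auto")
    format <- if (all(c("rsid_a", "rsid_b", "r2") %in% header))
      "long" else "square"
  if (format == "long") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    ids <- sort(unique(c(tab$rsid_a, tab$rsid_b)))
    m <- diag(1, length(ids))
    dimnames(m) <- list(ids, ids)
    i <- match(tab$rsid_a, ids); j <- match(tab$rsid_b, ids)
    m[cbind(i, j)] <- tab$r2
    m[cbind(j, i)] <- tab$r2
    diag(m) <- 1
    LDMatrix(ids, m)
  } else {
    tab <- utils::read.delim(path, row.names = 1, check.names = FALSE)
    m <- as.matrix(tab)
    m[] <- as.numeric(m)
    m <- (m + t(m)) / 2   # tolerate asymmetric rounding in the file
    LDMatrix(rownames(tab), m)
  }
}

#' Greedy LD pruning of an instrument
#'
#' Repeatedly keeps the remaining SNP with the smallest exposure p-value and
#' removes every SNP in LD with it at R-squared >= \code{r2Threshold}. Ties
#' in p-value are broken by rsid lexicographic order, making the result
#' invariant to input row order.
#'
#' @param records data.frame of candidate SNPs (needs \code{rsid},
#'   \code{pval}).
#' @param ld an \linkS4class{LDMatrix} covering every record.
#' @param r2Threshold LD exclusion threshold (default 0.1).
#' @return The retained rows, in input order; attribute \code{"exclusions"}
#'   holds data.frame(rsid, reason = "ld_pruned").
#' @export
pruneLD <- function(records, ld, r2Threshold = 0.1) {
  stopifnot(is(ld, "LDMatrix"))
  missing_ld <- setdiff(records$rsid, ld@snps)
  if (length(missing_ld))
    stop("SNP(s) absent from LD matrix: ",
         paste(missing_ld, collapse = ", "))
  if (any(is.na(records$pval)))
    stop("LD pruning requires a p-value for every SNP")
  ord <- order(records$pval, records$rsid)
  remaining <- records$rsid[ord]
  r2 <- ld@r2
  keep <- character(0)
  while (length(remaining)) {
    top <- remaining[1]
    keep <- c(keep, top)
    linked <- remaining[r2[top, remaining] >= r2Threshold]  # includes top
    remaining <- setdiff(remaining, linked)
  }
  out <- records[records$rsid %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  dropped <- setdiff(records$rsid, keep)
  attr(out, "exclusions") <- data.frame(
    rsid = dropped, reason = rep("ld_pruned", length(dropped)),
    stringsAsFactors = FALSE)
  out
}
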