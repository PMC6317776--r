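test_that("a well-formed table parses to identity and round-trips", {
  df <- rbind(sumstatsRow("rs1", "a", "g", 0.10, 0.01, 0.30, 1e-9, 0.95),
              sumstatsRow("rs2", "T", "C", -0.05, 0.02, 0.70, 1e-8, 0.99),
              sumstatsRow("rs3", "c", "t", 0.02, 0.01, 0.50, 0.03, NA))
  got <- readSumstats(writeTSV(df))
  expect_equal(nrow(got), 3)
  expect_equal(got$effect_allele, c("A", "T", "C"))  # uppercased
  expect_equal(got$beta, df$beta)
  expect_equal(got$se, df$se)
  expect_equal(nrow(attr(got, "validation")), 0)
  # write/read oracle: a second round trip preserves every field
  again <- readSumstats(writeTSV(got[, setdiff(names(got), character(0))]))
  expect_equal(again, got, ignore_attr = TRUE)
})

test_that("invalid rows are reported with row numbers, not silently dropped", {
  df <- rbind(sumstatsRow("rs1", "A", "G", 0.1, 0.01),
              sumstatsRow("rs2", "A", "G", 0.1, 0),        # se = 0
              sumstatsRow("rs3", "A", "A", 0.1, 0.01),     # identical alleles
              sumstatsRow("rs4", "A", "G", 0.1, 0.01))
  df$beta <- as.character(df$beta); df$beta[4] <- "not_a_number"
  expect_warning(got <- readSumstats(writeTSV(df)), "failed validation")
  expect_equal(got$rsid, "rs1")
  rep <- attr(got, "validation")
  expect_equal(rep$row, c(2L, 3L, 4L))
  expect_setequal(rep$reason,
                  c("invalid_se", "identical_alleles", "unparseable_beta"))
})

test_that("a missing mandatory column is a configuration error", {
  df <- sumstatsRow("rs1", "A", "G", 0.1, 0.01)
  df$se <- NULL
  expect_error(readSumstats(writeTSV(df)), "mandatory column")
})

test_that("columnMap renames nonstandard headers", {
  df <- data.frame(SNP = "rs1", A1 = "A", A2 = "G", b = 0.1, stderr = 0.01)
  got <- readSumstats(writeTSV(df),
                      columnMap = c(rsid = "SNP", effect_allele = "A1",
                                    other_allele = "A2", beta = "b",
                                    se = "stderr"))
  expect_equal(got$rsid, "rs1")
  expect_equal(got$beta, 0.1)
  expect_true(is.na(got$pval))
})

test_that("instrument filters are strict at their boundaries", {
  df <- rbind(sumstatsRow("rs1", "A", "G", 0.1, 0.01, pval = 5e-8),
              sumstatsRow("rs2", "A", "G", 0.1, 0.01, pval = 4.9e-8),
              sumstatsRow("rs3", "A", "G", 0.1, 0.01, pval = 1e-9,
                          info = 0.69),
              sumstatsRow("rs4", "A", "G", 0.1, 0.01, pval = 1e-9,
                          info = 0.70),
              sumstatsRow("rs5", "A", "G", 0.1, 0.01, pval = 1e-9))
  got <- filterInstrument(df)
  expect_setequal(got$rsid, c("rs2", "rs4", "rs5"))   # rs5: missing info passes
  excl <- attr(got, "exclusions")
  expect_equal(excl$reason[excl$rsid == "rs1"], "pval_above_threshold")
  expect_equal(excl$reason[excl$rsid == "rs3"], "info_below_threshold")
})

test_that("all-pass filtering is the identity; empty survivor set is signalled", {
  df <- rbind(sumstatsRow("rs1", "A", "G", 0.1, 0.01, pval = 1e-10),
              sumstatsRow("rs2", "A", "G", 0.1, 0.01, pval = 1e-12))
  got <- filterInstrument(df)
  expect_equal(got$rsid, df$rsid)
  expect_message(empty <- filterInstrument(df, pThreshold = 1e-20),
                 "no SNPs survive")
  expect_s3_class(empty, "data.frame")
  expect_equal(nrow(empty), 0)
})

test_that("LD pruning keeps the most significant SNP of a linked pair", {
  df <- rbind(sumstatsRow("rsA", "A", "G", 0.1, 0.01, pval = 1e-10),
              sumstatsRow("rsB", "A", "G", 0.1, 0.01, pval = 1e-9))
  ld <- LDMatrix(c("rsA", "rsB"), matrix(c(1, 0.2, 0.2, 1), 2))
  got <- pruneLD(df, ld, 0.1)
  expect_equal(got$rsid, "rsA")
  # independent SNPs are all kept
  ld0 <- LDMatrix(c("rsA", "rsB"), diag(2))
  expect_equal(pruneLD(df, ld0, 0.1)$rsid, c("rsA", "rsB"))
  # missing rsid is a hard error naming the SNP
  expect_error(pruneLD(df, LDMatrix("rsA", diag(1)), 0.1), "rsB")
})

test_that("greedy pruning matches a brute-force oracle and ignores row order", {
  set.seed(41)
  n <- 10
  df <- do.call(rbind, lapply(seq_len(n), function(i)
    sumstatsRow(sprintf("rs%02d", i), "A", "G", 0.1, 0.01,
                pval = 10^-runif(1, 8, 15))))
  # chain: neighbours linked at r2 = 0.15
  m <- diag(1, n)
  for (i in seq_len(n - 1)) m[i, i + 1] <- m[i + 1, i] <- 0.15
  ld <- LDMatrix(df$rsid, m)
  got <- pruneLD(df, ld, 0.1)
  # oracle: scan SNPs in p order, keep those unlinked to anything kept so far
  dimnames(m) <- list(df$rsid, df$rsid)
  oracle <- character(0)
  for (id in df$rsid[order(df$pval, df$rsid)])
    if (length(oracle) == 0 || all(m[id, oracle] < 0.1))
      oracle <- c(oracle, id)
  expect_setequal(got$rsid, oracle)
  # pairwise R2 among survivors all below threshold
  sub <- m[got$rsid, got$rsid]
  expect_true(all(sub[upper.tri(sub)] < 0.1))
  # invariance to input order
  perm <- df[sample(n), , drop = FALSE]
  expect_setequal(pruneLD(perm, ld, 0.1)$rsid, got$rsid)
})

test_that("square and long LD layouts read to the same matrix", {
  sq <- readLDMatrix(system.file("extdata", "example_ld.tsv",
                                 package = "summaryMR"))
  lg <- readLDMatrix(system.file("extdata", "example_ld_long.tsv",
                                 package = "summaryMR"))
  expect_setequal(sq@snps, lg@snps)
  expect_equal(sq@r2[lg@snps, lg@snps], lg@r2, tolerance = 1e-12)
  # the fixture is 4 blocks of 5 at r2 = 0.15: pruning at 0.1 keeps 1/block
  exp <- readSumstats(system.file("extdata", "example_exposure.tsv",
                                  package = "summaryMR"))
  pruned <- pruneLD(exp, sq, 0.1)
  expect_equal(nrow(pruned), 4)
})
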