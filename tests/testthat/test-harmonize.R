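expOne <- sumstatsRow("rs1", "A", "G", 0.10, 0.01, eaf = 0.30)

test_that("allele orientation cases resolve as expected", {
  cases <- list(
    # outcome (ea, oa, beta) -> expected (beta_outcome, flag)
    list("A", "G", -0.05, -0.05, "as_is"),            # same orientation
    list("G", "A", -0.05, +0.05, "allele_flipped"),   # swapped orientation
    list("T", "C", -0.05, -0.05, "as_is"),            # strand complement
    list("C", "T", -0.05, +0.05, "allele_flipped"))   # complement + swap
  for (cs in cases) {
    out <- sumstatsRow("rs1", cs[[1]], cs[[2]], cs[[3]], 0.02, eaf = 0.30)
    inst <- harmonize(expOne, out)
    expect_equal(nSNP(inst), 1)
    expect_equal(betaOutcome(inst), cs[[4]])
    expect_equal(harmonyFlag(inst), cs[[5]])
  }
  # irreconcilable allele pair
  out <- sumstatsRow("rs1", "A", "C", 0.05, 0.02, eaf = 0.30)
  inst <- harmonize(expOne, out)
  expect_equal(nSNP(inst), 0)
  expect_equal(exclusions(inst)$reason, "allele_mismatch")
})

test_that("palindromic SNPs follow the MAF rule and frequency orientation", {
  pal <- function(eafX, eafY, ea = "A", oa = "T", beta = 0.05) {
    e <- sumstatsRow("rs1", ea, oa, 0.10, 0.01, eaf = eafX)
    o <- sumstatsRow("rs1", ea, oa, beta, 0.02, eaf = eafY)
    harmonize(e, o)
  }
  # MAF above the ambiguity threshold in either dataset: excluded
  i <- pal(0.45, 0.45)
  expect_equal(nSNP(i), 0)
  expect_equal(exclusions(i)$reason, "palindromic_maf_gt_threshold")
  expect_equal(nSNP(pal(0.10, 0.45)), 0)
  # frequencies on the same side of 0.5: kept as reported
  i <- pal(0.10, 0.11, ea = "C", oa = "G")
  expect_equal(betaOutcome(i), 0.05)
  expect_equal(harmonyFlag(i), "palindromic_kept_by_freq")
  # frequencies on opposite sides: outcome beta flipped
  i <- pal(0.10, 0.89)
  expect_equal(betaOutcome(i), -0.05)
  # missing eaf: cannot apply the rule
  i <- pal(NA, 0.10)
  expect_equal(exclusions(i)$reason, "palindromic_missing_eaf")
  # same-strand mode aligns by labels instead of frequency
  e <- sumstatsRow("rs1", "A", "T", 0.10, 0.01, eaf = 0.10)
  o <- sumstatsRow("rs1", "T", "A", 0.05, 0.02, eaf = 0.15)
  i <- harmonize(e, o, palindromicMode = "same_strand")
  expect_equal(betaOutcome(i), -0.05)
  expect_equal(harmonyFlag(i), "allele_flipped")
})

test_that("proxy substitution rescues palindromic and missing SNPs", {
  e <- rbind(sumstatsRow("rs1", "A", "T", 0.10, 0.01, eaf = 0.45),
             sumstatsRow("rsP", "A", "G", 0.09, 0.01, eaf = 0.30),
             sumstatsRow("rs2", "C", "T", 0.07, 0.01, eaf = 0.20),
             sumstatsRow("rsQ", "T", "C", 0.06, 0.01, eaf = 0.25))
  o <- rbind(sumstatsRow("rs1", "A", "T", 0.02, 0.02, eaf = 0.45),
             sumstatsRow("rsP", "G", "A", -0.04, 0.02, eaf = 0.70),
             sumstatsRow("rsQ", "T", "C", 0.03, 0.02, eaf = 0.25))
  proxies <- data.frame(rsid = c("rs1", "rs2"), proxy = c("rsP", "rsQ"),
                        stringsAsFactors = FALSE)
  inst <- harmonize(e, o, proxyTable = proxies)
  # rs1 (palindromic, MAF > 0.4) takes rsP's statistics under its own id
  expect_true("rs1" %in% snps(inst))
  k <- match("rs1", snps(inst))
  expect_equal(harmonyFlag(inst)[k], "substituted_by_proxy")
  expect_equal(betaExposure(inst)[k], 0.09)
  expect_equal(betaOutcome(inst)[k], 0.04)   # rsP was allele-swapped
  # rs2 (absent from outcome) takes rsQ's statistics
  k2 <- match("rs2", snps(inst))
  expect_equal(harmonyFlag(inst)[k2], "substituted_by_proxy")
  expect_equal(betaOutcome(inst)[k2], 0.03)
  # without proxies both are excluded with their own reasons
  noP <- harmonize(e[c(1, 3), ], o)
  expect_setequal(exclusions(noP)$reason,
                  c("palindromic_maf_gt_threshold", "missing_in_outcome"))
})

test_that("conservation: every input SNP is retained or logged, exactly once", {
  sim <- simulateInstrument(simConfig(nSNP = 60, seed = 5,
                                      scrambleCoding = TRUE),
                            palindromicFraction = 0.3)
  inst <- sim$instrument
  expect_equal(nSNP(inst) + nrow(exclusions(inst)), 60)
  expect_false(any(duplicated(c(snps(inst), exclusions(inst)$rsid))))
})

test_that("harmonizing an already-harmonized pair changes nothing", {
  sim <- simulateInstrument(simConfig(nSNP = 40, seed = 6,
                                      scrambleCoding = TRUE))
  inst <- sim$instrument
  tabs <- instrumentToTables(inst, sim$exposure)
  again <- harmonize(tabs$exposure, tabs$outcome)
  keep <- match(snps(inst), snps(again))
  expect_equal(betaOutcome(again)[keep], betaOutcome(inst))
  expect_equal(betaExposure(again)[keep], betaExposure(inst))
})

test_that("flipping every outcome record's coding leaves the result unchanged", {
  sim <- simulateInstrument(simConfig(nSNP = 30, seed = 7,
                                      scrambleCoding = TRUE),
                            palindromicFraction = 0.2)
  out2 <- sim$outcome
  ea <- out2$effect_allele
  out2$effect_allele <- out2$other_allele
  out2$other_allele <- ea
  out2$beta <- -out2$beta
  out2$eaf <- 1 - out2$eaf
  inst2 <- harmonize(sim$exposure, out2)
  expect_equal(snps(inst2), snps(sim$instrument))
  expect_equal(betaOutcome(inst2), betaOutcome(sim$instrument))
})

test_that("frequency orientation recovers the true strand at MAF 0.1", {
  # noisy allele-frequency estimates from two finite samples; the known
  # truth is beta_outcome = +1 on the exposure's effect allele
  set.seed(99)
  n <- 500
  nSamp <- 30000
  fTrue <- 0.1
  fx <- rbinom(n, 2 * nSamp, fTrue) / (2 * nSamp)
  fy <- rbinom(n, 2 * nSamp, fTrue) / (2 * nSamp)
  correct <- logical(n)
  for (i in seq_len(n)) {
    e <- sumstatsRow("rs1", "A", "T", 0.1, 0.01, eaf = fx[i])
    swap <- i %% 2 == 0    # outcome arbitrarily re-coded for half the SNPs
    o <- if (swap)
      sumstatsRow("rs1", "T", "A", -1, 0.02, eaf = 1 - fy[i])
    else
      sumstatsRow("rs1", "A", "T", 1, 0.02, eaf = fy[i])
    inst <- harmonize(e, o)
    correct[i] <- nSNP(inst) == 1 && betaOutcome(inst) == 1
  }
  expect_gte(mean(correct), 0.99)
})
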