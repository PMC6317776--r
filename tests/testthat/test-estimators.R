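test_that("Wald ratios follow the first-order formulas", {
  i <- makeInstrument(bx = c(0.1, 1), by = c(0.05, 0),
                      sx = c(0.01, 0.01), sy = c(0.02, 0.02))
  r <- waldRatios(i)
  expect_equal(r$theta, c(0.5, 0))
  expect_equal(r$se, c(0.2, 0.02))
  expect_equal(r$weight, c(25, 2500))
  # zero exposure effect: excluded with warning
  iz <- makeInstrument(bx = c(0.1, 0), by = c(0.05, 0.01))
  expect_warning(rz <- waldRatios(iz), "zero exposure")
  expect_equal(nrow(rz), 1)
})

test_that("first-order ratio SE matches the Monte-Carlo sd when SE_GE = 0", {
  set.seed(1)
  bx <- 0.1; by <- 0.05; sy <- 0.02
  draws <- rnorm(1e6, by, sy) / bx
  expect_equal(sd(draws), sy / abs(bx), tolerance = 0.02)
})

test_that("IVW is the precision-weighted mean and degenerates correctly", {
  i <- makeInstrument(bx = c(0.1, 0.1), by = c(0.05, 0.01))
  est <- mrIVW(i)   # equal weights: mean of ratios 0.5 and 0.1
  expect_equal(theta(est), 0.3)
  # identical ratios: estimate equals the ratio, Q = 0
  i2 <- makeInstrument(bx = c(0.1, 0.2), by = c(0.04, 0.08),
                       sy = c(0.02, 0.04))
  est2 <- mrIVW(i2)
  expect_equal(theta(est2), 0.4)
  expect_equal(est2@qStat, 0, tolerance = 1e-12)
  # single SNP: Wald passthrough, flagged
  expect_warning(w <- mrIVW(makeInstrument(0.1, 0.05)), "single-SNP")
  expect_equal(methodName(w), "wald")
  expect_equal(theta(w), 0.5)
})

test_that("IVW is unbiased for valid simulated instruments", {
  reps <- 200
  ths <- vapply(seq_len(reps), function(r) {
    sim <- simulateInstrument(simConfig(nSNP = 50, thetaTrue = log(1.5),
                                        targetR2 = 0.05, seed = 1000 + r))
    theta(mrIVW(sim$instrument))
  }, numeric(1))
  mcse <- sd(ths) / sqrt(reps)
  expect_lt(abs(mean(ths) - log(1.5)), 3 * mcse)
})

test_that("likelihood estimator reduces to IVW as exposure error vanishes", {
  set.seed(2)
  n <- 20
  i <- makeInstrument(bx = runif(n, 0.05, 0.2),
                      by = rnorm(n, 0.08, 0.02),
                      sx = rep(1e-8, n), sy = rep(0.02, n))
  expect_equal(theta(mrLikelihood(i)), theta(mrIVW(i)), tolerance = 1e-6)
})

test_that("likelihood maximizer matches a dense grid search", {
  sim <- simulateInstrument(simConfig(nSNP = 40, seed = 31))
  inst <- sim$instrument
  fit <- mrLikelihood(inst, profile = TRUE)
  grid <- seq(-2, 2, length.out = 2000)
  bx <- betaExposure(inst); by <- betaOutcome(inst)
  sx <- seExposure(inst); sy <- seOutcome(inst)
  ll <- vapply(grid, function(t) {
    xi <- (bx / sx^2 + t * by / sy^2) / (1 / sx^2 + t^2 / sy^2)
    sum(dnorm(bx, xi, sx, log = TRUE) + dnorm(by, t * xi, sy, log = TRUE))
  }, numeric(1))
  step <- diff(grid)[1]
  expect_lt(abs(theta(fit) - grid[which.max(ll)]), step)
  # the profiled xi at the MLE equals its closed-form conditional maximizer
  th <- theta(fit)
  xiHat <- (bx / sx^2 + th * by / sy^2) / (1 / sx^2 + th^2 / sy^2)
  expect_equal(fit@xi, xiHat)
})

test_that("likelihood agrees with IVW within 1% for strong instruments", {
  set.seed(3)
  n <- 30
  bx <- runif(n, 0.5, 1)
  i <- makeInstrument(bx = bx, by = 0.3 * bx + rnorm(n, 0, 0.02),
                      sx = 0.005 * bx, sy = rep(0.02, n))
  expect_lt(max(seExposure(i) / abs(betaExposure(i))), 0.01)
  expect_equal(theta(mrLikelihood(i)), theta(mrIVW(i)), tolerance = 0.01)
})

test_that("weighted median interpolates the weighted quantile function", {
  i <- makeInstrument(bx = c(0.1, 0.1, 0.1), by = c(0.01, 0.05, 0.09))
  est <- mrWeightedMedian(i, nBoot = 0)   # equal weights: middle ratio
  expect_equal(theta(est), 0.5)
  # brute-force percentile oracle on a 10-SNP instrument
  set.seed(4)
  n <- 10
  bx <- runif(n, 0.05, 0.2)
  i10 <- makeInstrument(bx = bx, by = bx * 0.4 + rnorm(n, 0, 0.02),
                        sy = runif(n, 0.01, 0.03))
  r <- waldRatios(i10)
  o <- order(r$theta)
  th <- r$theta[o]; w <- r$weight[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  j <- max(which(s < 0.5))
  oracle <- th[j] + (th[j + 1] - th[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
  expect_equal(theta(mrWeightedMedian(i10, nBoot = 0)), oracle)
  # a SNP holding > 50% of the weight dominates
  idom <- makeInstrument(bx = c(1, 0.1, 0.1), by = c(0.7, 0.01, 0.02))
  expect_warning(dom <- mrWeightedMedian(idom, nBoot = 0), "50%")
  expect_equal(theta(dom), 0.7)
})

test_that("weighted median bootstrap SE is reproducible and sane", {
  sim <- simulateInstrument(simConfig(nSNP = 30, seed = 8))
  a <- mrWeightedMedian(sim$instrument, nBoot = 1000, seed = 5)
  b <- mrWeightedMedian(sim$instrument, nBoot = 1000, seed = 5)
  expect_identical(theta(a), theta(b))
  expect_identical(se(a), se(b))
  expect_gt(se(a), 0)
  expect_error(mrWeightedMedian(sim$instrument, nBoot = 1000), "seed")
})

test_that("SNP heterogeneity statistics follow the Q definitions", {
  # identical ratios
  i <- makeInstrument(bx = c(0.1, 0.2), by = c(0.04, 0.08),
                      sy = c(0.02, 0.04))
  h <- snpHeterogeneity(i, 0.4)
  expect_equal(h$q, 0, tolerance = 1e-12)
  expect_equal(h$i2, 0)
  expect_equal(h$pHet, 1)
  # hand arithmetic: w = 1, ratios 0 and 2, reference 1 -> Q = 2, df = 1
  r <- data.frame(theta = c(0, 2), weight = c(1, 1))
  h2 <- snpHeterogeneity(r, 1)
  expect_equal(h2$q, 2)
  expect_equal(h2$df, 1)
  expect_equal(h2$pHet, pchisq(2, 1, lower.tail = FALSE))
})

test_that("Q p-values are uniform under valid instruments", {
  set.seed(6)
  reps <- 1000
  n <- 10
  ps <- vapply(seq_len(reps), function(r) {
    gamma <- runif(n, 0.05, 0.2)
    i <- makeInstrument(bx = rnorm(n, gamma, 0.001),
                        by = rnorm(n, 0.4 * gamma, 0.02),
                        sx = rep(0.001, n), sy = rep(0.02, n))
    est <- mrIVW(i)
    est@pHet
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("estimators are scale-equivariant and flip-antisymmetric", {
  sim <- simulateInstrument(simConfig(nSNP = 25, seed = 9))
  inst <- sim$instrument
  c0 <- 2.5
  scaled <- HarmonizedInstrument(snps(inst), c0 * betaExposure(inst),
                                 c0 * seExposure(inst), betaOutcome(inst),
                                 seOutcome(inst), eaf(inst))
  flipped <- HarmonizedInstrument(snps(inst), betaExposure(inst),
                                  seExposure(inst), -betaOutcome(inst),
                                  seOutcome(inst), eaf(inst))
  for (f in list(function(x) theta(mrIVW(x)),
                 function(x) theta(mrLikelihood(x)),
                 function(x) theta(mrWeightedMedian(x, nBoot = 0)),
                 function(x) mrEgger(x)@slope)) {
    expect_equal(f(scaled), f(inst) / c0, tolerance = 1e-6)
    expect_equal(f(flipped), -f(inst), tolerance = 1e-9)
  }
  # I2 in [0,1) and Q invariant to SNP order
  perm <- inst[sample(nSNP(inst))]
  expect_equal(mrIVW(perm)@qStat, mrIVW(inst)@qStat)
  expect_true(mrIVW(inst)@i2 >= 0 && mrIVW(inst)@i2 < 1)
})
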