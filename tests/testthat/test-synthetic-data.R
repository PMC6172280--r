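test_that("genotype simulation is reproducible and respects MAF bounds", {
  cfg <- simConfig(p = 30, seed = 51)
  g1 <- simulateGenotypes(cfg, n = 200)
  g2 <- simulateGenotypes(cfg, n = 200)
  expect_identical(dosages(g1), dosages(g2))
  expect_true(all(dosages(g1) %in% 0:2))
  expect_true(all(snpInfo(g1)$maf <= 0.5))
})

test_that("rhoLd = 0 gives near-independent SNPs", {
  cfg <- simConfig(p = 10, rhoLd = 0, seed = 52)
  g <- simulateGenotypes(cfg, n = 2000)
  V <- ldMatrix(computeLD(g, ridge = 0))
  expect_lt(mean(abs(V[upper.tri(V)])), 4 / sqrt(2000))
})

test_that("strong AR(1) targets yield strong, attenuated dosage LD", {
  ## thresholding the latent Gaussians attenuates the dosage correlation
  ## below the latent 0.9; at matched MAFs the phi correlation lands
  ## around 0.7 (measured), and must stay clearly below the latent target
  cfg <- simConfig(p = 2, rhoLd = 0.9, kCausalSnps = 1,
                   mafRange = c(0.3, 0.35), seed = 53)
  g <- simulateGenotypes(cfg, n = 2000)
  r <- cor(dosages(g))[1, 2]
  expect_gt(r, 0.6)
  expect_lt(r, 0.9)
})

test_that("expression simulation hits the target variance ratio exactly", {
  cfg <- simConfig(p = 20, seed = 54)
  g <- simulateGenotypes(cfg, n = 300)
  Z <- scale(dosages(g))
  for (h2 in c(0.25, 0.7)) {
    ex <- simulateExpression(g, h2, 4, seed = 55)
    ratio <- var(as.numeric(Z %*% ex$trueW)) / var(ex$y)
    expect_equal(ratio, h2, tolerance = 1e-12)
  }
  ## boundary cases
  ex1 <- simulateExpression(g, 1, 4, seed = 56)
  expect_equal(var(as.numeric(Z %*% ex1$trueW)) / var(ex1$y), 1,
               tolerance = 1e-12)
  ex0 <- simulateExpression(g, 0, 4, seed = 57)
  expect_true(all(ex0$trueW == 0))
  expect_error(simulateExpression(g, 0.5, 21), "causal")
})

test_that("null GWAS summary statistics are centered", {
  cfg <- simConfig(p = 50, seed = 58)
  g <- simulateGenotypes(cfg, n = 489)
  zAll <- unlist(lapply(1:40, function(i)
    records(simulateGwasSumstats(g, numeric(50), 0, 1e5,
                                 seed = 600 + i))$z))
  expect_lt(abs(mean(zAll)), 4 / sqrt(length(zAll)))
  expect_lt(abs(var(zAll) - 1), 0.1)
})

test_that("the causal SNP's expected Z grows as sqrt(n)", {
  cfg <- simConfig(p = 12, seed = 59)
  g <- simulateGenotypes(cfg, n = 489)
  V <- cor(dosages(g))
  w <- numeric(12); w[6] <- 1
  alpha <- 0.02
  for (n in c(1e4, 4e4)) {
    zMean <- rowMeans(sapply(1:60, function(i)
      records(simulateGwasSumstats(g, w, alpha, n, seed = 700 + i))$z))
    wt <- w / sqrt(as.numeric(t(w) %*% V %*% w))
    expected <- sqrt(n) * alpha * as.numeric(V %*% wt)
    expect_equal(unname(zMean[6]), expected[6],
                 tolerance = 4 / sqrt(60) / abs(expected[6]))
  }
})

test_that("individual- and summary-level modes agree in distribution", {
  cfg <- simConfig(p = 15, kCausalSnps = 2, seed = 60)
  g <- simulateGenotypes(cfg, n = 489)
  ex <- simulateExpression(g, 0.4, 2, seed = 61)
  V <- ldMatrix(computeLD(g, ridge = 0))
  alpha <- 0.05
  nG <- 3000
  zTwas <- function(ssMode, i) {
    ss <- simulateGwasSumstats(g, ex$trueW, alpha, nG, seed = 800 + i,
                               mode = ssMode, cfg = cfg)
    twasZscore(ex$trueW, records(ss)$z, V)$z_twas
  }
  zSum <- sapply(1:60, function(i) zTwas("summary", i))
  zInd <- sapply(1:60, function(i) zTwas("individual", i + 500))
  iqrS <- quantile(zSum, c(0.25, 0.75))
  iqrI <- quantile(zInd, c(0.25, 0.75))
  ## overlapping interquartile ranges across the two generative modes
  expect_lt(max(iqrS[1], iqrI[1]), min(iqrS[2], iqrI[2]))
})

test_that("sampled TWAS regions have the advertised moments", {
  set.seed(62)
  k <- 4
  n <- 1e5
  sigmaA2 <- 30 / n
  ## independent genes: non-causal z standard normal, causal var 1+n*s
  zs <- replicate(5000, simulateTwasRegion(diag(k), 2, n, sigmaA2))
  causalZ2 <- zs[2, ]^2
  expect_equal(mean(causalZ2), 1 + 30,
               tolerance = 3 * sd(causalZ2) / sqrt(5000) / 31)
  other <- as.numeric(zs[-2, ])
  expect_lt(abs(mean(other)), 0.05)
  expect_lt(abs(var(other) - 1), 0.07)
  ## null prior: plain MVN draws
  z0 <- replicate(2000, simulateTwasRegion(diag(k), 1, n, 0))
  expect_lt(abs(var(as.numeric(z0)) - 1), 0.1)
})

test_that("gene correlation matrices from sparse weights are valid", {
  cfg <- simConfig(p = 40, kGenes = 5, seed = 63)
  g <- simulateGenotypes(cfg, n = 489)
  ld <- computeLD(g, ridge = 0)
  gc <- simulateGeneCorr(cfg, ld)
  expect_equal(unname(diag(gc$geneCorr)), rep(1, 5))
  expect_gte(min(eigen(gc$geneCorr, symmetric = TRUE,
                       only.values = TRUE)$values), -1e-8)
  expect_true(all(abs(gc$geneCorr) <= 1 + 1e-12))
})

test_that("calibration is exact in the degenerate designs", {
  cfg1 <- simConfig(p = 20, kGenes = 1, seed = 64)
  out1 <- calibrationExperiment(nRegions = 25, rhoLevels = 0.9,
                                cfg = cfg1)
  expect_equal(out1$coverage, 1)
  expect_equal(out1$mean_size, 1)

  cfg5 <- simConfig(p = 20, kGenes = 5, seed = 65)
  out2 <- calibrationExperiment(nRegions = 25, rhoLevels = 1.0,
                                cfg = cfg5)
  expect_equal(out2$coverage, 1)
})

test_that("simulated filesets exercise the package's own I/O", {
  cfg <- simConfig(p = 12, seed = 66)
  g <- simulateGenotypes(cfg, n = 60)
  prefix <- tempfile()
  writePlink(g, prefix)
  back <- loadGenotypes(prefix, mafMin = 0)
  expect_equal(dosages(back), dosages(g))
  ss <- simulateGwasSumstats(g, numeric(12), 0, 1e4, seed = 67)
  f <- tempfile(fileext = ".tsv")
  writeSumstats(ss, f)
  expect_equal(records(loadSumstats(f)), records(ss), tolerance = 1e-12)
})
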