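#' Build a simulation configuration
#'
#' Defaults describe the conditions the pipeline is designed for: an LD
#' reference of 489 samples, an expression panel of 500, a GWAS of 142,392
#' samples, 100 cis SNPs per locus with AR(1) latent correlation 0.7 and
#' MAF drawn from (0.05, 0.5), cis-heritability 0.4 from 3 causal eQTL
#' SNPs, a gene-trait effect sized for a GWAS non-centrality of about
#' `chi^2 = 40` at a strong risk locus, 5 gene models per region, and a
#' causal-gene prior with `n * sigma_a2 = 30`.
#'
#' @param seed integer RNG seed.
#' @param nRef,nPanel,nGwas sample sizes (LD reference, expression panel,
#'   GWAS).
#' @param p SNPs per locus.
#' @param rhoLd adjacent-SNP AR(1) correlation of the latent Gaussians.
#' @param mafRange MAF range, increasing pair in (0, 0.5].
#' @param h2Expr cis-heritability of expression.
#' @param kCausalSnps causal eQTL SNPs per gene.
#' @param alphaGene effect of standardized genetic expression on the trait.
#' @param kGenes gene models per region.
#' @param sigmaA2 prior causal-effect variance.
#' @return A [SimConfig-class].
#' @export
simConfig <- function(seed = 1, nRef = 489, nPanel = 500, nGwas = 142392,
                      p = 100, rhoLd = 0.7, mafRange = c(0.05, 0.5),
                      h2Expr = 0.4, kCausalSnps = 3,
                      alphaGene = sqrt(40 / 142392), kGenes = 5,
                      sigmaA2 = 30 / nGwas) {
  new("SimConfig", seed = seed, nRef = nRef, nPanel = nPanel,
      nGwas = nGwas, p = p, rhoLd = rhoLd, mafRange = mafRange,
      h2Expr = h2Expr, kCausalSnps = kCausalSnps, alphaGene = alphaGene,
      kGenes = kGenes, sigmaA2 = sigmaA2)
}

#' Simulate reference genotypes with local LD
#'
#' Draws two latent Gaussian pseudo-haplotypes per individual with AR(1)
#' correlation `rhoLd` along the locus and thresholds each at the normal
#' quantile of a per-SNP MAF drawn from `mafRange`; the dosage is the
#' allele count over the two haplotypes. Discretization attenuates the
#' realized adjacent-SNP correlation below `rhoLd`; the generator is
#' validated empirically rather than assumed exact. Deterministic given
#' `seed`.
#'
#' @param cfg a [SimConfig-class].
#' @param n number of samples (default `cfg@nRef`).
#' @param seed RNG seed (default `cfg@seed`).
#' @param chrom,startBp,spacingBp coordinates given to the simulated SNPs.
#' @return A [GenotypeMatrix-class] with rsID-style identifiers.
#' @export
simulateGenotypes <- function(cfg, n = cfg@nRef, seed = cfg@seed,
                              chrom = "1", startBp = 1e6,
                              spacingBp = 1e4) {
  stopifnot(is(cfg, "SimConfig"))
  .checkSeed(seed)
  p <- cfg@p
  mafs <- stats::runif(p, cfg@mafRange[1], cfg@mafRange[2])
  thr <- stats::qnorm(mafs)

  drawHap <- function() {
    L <- matrix(stats::rnorm(n * p), n, p)
    if (cfg@rhoLd > 0 && p > 1) {
      for (j in 2:p)
        L[, j] <- cfg@rhoLd * L[, j - 1] +
          sqrt(1 - cfg@rhoLd^2) * L[, j]
    }
    L
  }
  X <- (drawHap() < rep(thr, each = n)) + (drawHap() < rep(thr, each = n))
  mode(X) <- "numeric"

  ## a column monomorphic by chance cannot enter LD estimation; redraw it
  ## independently (rare at these MAFs and sample sizes)
  for (tries in 1:10) {
    const <- apply(X, 2, function(x) length(unique(x)) == 1)
    if (!any(const)) break
    for (j in which(const))
      X[, j] <- (stats::rnorm(n) < thr[j]) + (stats::rnorm(n) < thr[j])
  }

  snps <- data.frame(
    snp_id = sprintf("rs%d", 1e5 + seq_len(p)),
    chrom = chrom, pos = as.integer(startBp + (seq_len(p) - 1) * spacingBp),
    a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  freq <- colMeans(X) / 2
  snps$maf <- pmin(freq, 1 - freq)
  samples <- sprintf("sim%04d", seq_len(n))
  dimnames(X) <- list(samples, snps$snp_id)
  new("GenotypeMatrix", dosages = X, snps = snps, samples = samples)
}

#' Simulate cis-heritable expression with known weights
#'
#' Picks `kCausal` causal SNPs with standard-normal effects on the
#' standardized genotypes, then rescales the genetic component and an
#' orthogonalized noise component so the in-sample variance ratio
#' `var(Xw) / var(y)` equals `h2Expr` exactly.
#'
#' @param X a [GenotypeMatrix-class] or dosage matrix.
#' @param h2Expr target cis-heritability in `[0, 1]`.
#' @param kCausal number of causal SNPs.
#' @param seed RNG seed.
#' @return List with `y` (expression), `trueW` (causal weights on the
#'   standardized scale) and `causal` (causal SNP indices).
#' @export
simulateExpression <- function(X, h2Expr, kCausal, seed = 1) {
  if (is(X, "GenotypeMatrix")) X <- dosages(X)
  p <- ncol(X)
  n <- nrow(X)
  stopifnot(h2Expr >= 0, h2Expr <= 1, kCausal >= 1)
  if (kCausal > p) stop("more causal SNPs requested than SNPs available")
  .checkSeed(seed)
  Z <- .standardize(X)
  causal <- sort(sample.int(p, kCausal))
  w <- numeric(p)
  w[causal] <- stats::rnorm(kCausal)
  g <- as.numeric(Z %*% w)
  e <- stats::rnorm(n)

  if (h2Expr == 0) {
    y <- e / stats::sd(e)
    w[] <- 0
  } else if (h2Expr == 1) {
    s <- stats::sd(g)
    y <- g / s
    w <- w / s
  } else {
    sg <- stats::sd(g)
    g <- g * sqrt(h2Expr) / sg
    w <- w * sqrt(h2Expr) / sg
    ePerp <- as.numeric(stats::residuals(stats::lm.fit(cbind(1, g), e)))
    y <- g + ePerp * sqrt(1 - h2Expr) / stats::sd(ePerp)
  }
  list(y = y, trueW = w, causal = causal)
}

#' Simulate GWAS summary statistics for a locus
#'
#' Two generative modes for marginal SNP Z-scores when the trait acts
#' through cis-regulated expression:
#' \describe{
#'   \item{`"individual"`}{simulates `nGwas` new individuals with the same
#'     LD process, a trait `alphaGene * std(Xw) + noise`, and computes
#'     per-SNP marginal Wald statistics.}
#'   \item{`"summary"`}{draws directly from the asymptotic distribution
#'     `z ~ MVN(sqrt(nGwas) * alphaGene * V w~, V)`, where `w~` is the
#'     weight vector standardized to unit variance of predicted expression
#'     under `V` (`w~ = w / sqrt(w'Vw)`).}
#' }
#'
#' @param g a [GenotypeMatrix-class] describing the locus (provides SNP
#'   descriptors; in individual mode, also the LD-generating template via
#'   `cfg`).
#' @param trueW causal weight vector on the standardized scale.
#' @param alphaGene gene-trait effect per SD of genetic expression.
#' @param nGwas GWAS sample size.
#' @param seed RNG seed.
#' @param mode `"summary"` (default) or `"individual"`.
#' @param cfg [SimConfig-class], required for individual mode.
#' @param ld optional precomputed [LDMatrix-class] for summary mode
#'   (defaults to unregularized LD of `g`).
#' @return A [SumStats-class]; the mode is recorded in its QC log.
#' @export
simulateGwasSumstats <- function(g, trueW, alphaGene, nGwas, seed = 1,
                                 mode = c("summary", "individual"),
                                 cfg = NULL, ld = NULL) {
  mode <- match.arg(mode)
  stopifnot(is(g, "GenotypeMatrix"))
  snps <- snpInfo(g)
  p <- nrow(snps)
  stopifnot(length(trueW) == p)
  .checkSeed(seed)

  if (mode == "summary") {
    V <- if (!is.null(ld)) ldMatrix(ld) else
      stats::cor(dosages(g))
    if (any(trueW != 0) && alphaGene != 0) {
      wt <- trueW / sqrt(as.numeric(t(trueW) %*% V %*% trueW))
      mu <- sqrt(nGwas) * alphaGene * as.numeric(V %*% wt)
    } else mu <- numeric(p)
    z <- as.numeric(.rmvn(1, mu, V))
  } else {
    if (is.null(cfg)) stop("individual mode needs the SimConfig")
    Xg <- dosages(simulateGenotypes(cfg, n = nGwas, seed = NULL))
    Zg <- .standardize(Xg)
    gexp <- as.numeric(Zg %*% trueW)
    gstd <- if (stats::sd(gexp) > 0) gexp / stats::sd(gexp) else gexp
    yt <- alphaGene * gstd + stats::rnorm(nGwas)
    r <- as.numeric(crossprod(Zg, yt - mean(yt))) /
      ((nGwas - 1) * stats::sd(yt))
    z <- sqrt(nGwas - 2) * r / sqrt(pmax(1 - r^2, 1e-12))
  }

  rec <- data.frame(snp_id = snps$snp_id, chrom = snps$chrom,
                    pos = snps$pos, a1 = snps$a1, a2 = snps$a2,
                    z = z, maf = snps$maf, n = nGwas,
                    stringsAsFactors = FALSE)
  log <- data.frame(rule = paste0("simulated_", mode, "_mode"),
                    n_removed = 0L, stringsAsFactors = FALSE)
  SumStats(rec, qcLog = log)
}

#' Predicted-expression correlation from random sparse weight models
#'
#' Draws `kGenes` sparse weight vectors (each with `kCausalSnps` nonzero
#' standard-normal entries at random positions) over the given LD and
#' returns the implied predicted-expression correlation matrix
#' `D^-1 W' V W D^-1` -- the mechanism that makes TWAS Z-scores of
#' neighboring genes correlated.
#'
#' @param cfg a [SimConfig-class].
#' @param ld an [LDMatrix-class].
#' @param seed RNG seed.
#' @return List with `geneCorr` (k x k), `W` (p x k weight matrix).
#' @export
simulateGeneCorr <- function(cfg, ld, seed = cfg@seed) {
  stopifnot(is(cfg, "SimConfig"), is(ld, "LDMatrix"))
  .checkSeed(seed)
  V <- ldMatrix(ld)
  p <- nrow(V)
  k <- cfg@kGenes
  W <- matrix(0, p, k)
  for (gIdx in seq_len(k)) {
    idx <- sample.int(p, cfg@kCausalSnps)
    W[idx, gIdx] <- stats::rnorm(cfg@kCausalSnps)
  }
  VW <- V %*% W
  d <- sqrt(colSums(W * VW))
  geneCorr <- crossprod(W, VW) / tcrossprod(d)
  diag(geneCorr) <- 1
  list(geneCorr = geneCorr, W = W)
}

#' Sample correlated TWAS Z-scores for one region
#'
#' Under the single-causal-gene model: the causal effect is
#' `lambda ~ N(0, sigmaA2)` and
#' `z ~ MVN(sqrt(n) * lambda * geneCorr[, causal], geneCorr)`, so the
#' causal gene's squared Z-score has expectation `1 + n * sigmaA2` and
#' non-causal genes pick up signal only through their predicted-expression
#' correlation with the causal gene.
#'
#' @param geneCorr k x k predicted-expression correlation matrix.
#' @param causalIndex index of the causal gene.
#' @param n GWAS sample size.
#' @param sigmaA2 causal effect variance.
#' @param seed RNG seed.
#' @return Numeric vector of k TWAS Z-scores with attribute `lambda`.
#' @export
simulateTwasRegion <- function(geneCorr, causalIndex, n, sigmaA2,
                               seed = NULL) {
  k <- nrow(geneCorr)
  stopifnot(causalIndex >= 1, causalIndex <= k)
  .checkSeed(seed)
  lambda <- stats::rnorm(1, 0, sqrt(sigmaA2))
  mu <- sqrt(n) * lambda * geneCorr[, causalIndex]
  z <- as.numeric(.rmvn(1, mu, geneCorr))
  attr(z, "lambda") <- lambda
  z
}

#' Credible-set coverage calibration
#'
#' Replicates the calibration experiment behind the rho-credible sets:
#' simulates `nRegions` independent regions (each with its own reference
#' LD, random sparse weight models, a single causal gene, and TWAS
#' Z-scores drawn from the Bayes-factor model), runs Bayesian
#' prioritization with the same `n * sigmaA2`, and reports, for each level
#' of `rho`, the fraction of regions whose causal gene landed in the
#' credible set, along with the mean set size.
#'
#' @param nRegions number of simulated regions (default 1000).
#' @param rhoLevels credible-set densities to evaluate.
#' @param cfg a [SimConfig-class].
#' @param seed RNG seed (default `cfg@seed`).
#' @return data.frame with columns `rho`, `coverage`, `mean_size`,
#'   `n_regions`, `seed`.
#' @export
calibrationExperiment <- function(nRegions = 1000,
                                  rhoLevels = c(0.5, 0.9, 0.95),
                                  cfg = simConfig(), seed = cfg@seed) {
  stopifnot(is(cfg, "SimConfig"))
  .checkSeed(seed)
  hit <- matrix(FALSE, nRegions, length(rhoLevels))
  size <- matrix(NA_integer_, nRegions, length(rhoLevels))
  for (i in seq_len(nRegions)) {
    g <- simulateGenotypes(cfg, seed = NULL)
    ld <- computeLD(g, ridge = 0)
    gc <- simulateGeneCorr(cfg, ld, seed = NULL)
    causal <- sample.int(cfg@kGenes, 1)
    z <- simulateTwasRegion(gc$geneCorr, causal, cfg@nGwas, cfg@sigmaA2,
                            seed = NULL)
    post <- genePosteriors(bayesFactor(z, cfg@nGwas, cfg@sigmaA2))
    for (r in seq_along(rhoLevels)) {
      cs <- credibleSet(post, rho = rhoLevels[r],
                        labels = sprintf("g%02d", seq_len(cfg@kGenes)))
      hit[i, r] <- sprintf("g%02d", causal) %in% setMembers(cs)
      size[i, r] <- length(setMembers(cs))
    }
  }
  data.frame(rho = rhoLevels, coverage = colMeans(hit),
             mean_size = colMeans(size), n_regions = nRegions,
             seed = seed)
}
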