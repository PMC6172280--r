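#' Inverse-normal rank transform
#'
#' Maps values to normal quantiles of `rank / (n + 1)` (bounded Blom-type
#' offset; ties get average ranks). The output depends on the input only
#' through its ranks, has mean approximately zero, and is monotone in the
#' input.
#'
#' @param values numeric vector, length >= 3, not all tied.
#' @return numeric vector of the same length.
#' @examples
#' inverseNormalTransform(c(1, 2, 3))  # -0.674, 0, 0.674
#' @export
inverseNormalTransform <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 3)
  if (length(unique(values)) == 1)
    stop("all values are tied; rank transform undefined")
  r <- rank(values, ties.method = "average")
  stats::qnorm(r / (length(values) + 1))
}

## Profile REML-style log-likelihood machinery.
##
## With A = ZZ'/p (Z standardized genotypes) and spectral decomposition
## A = U diag(d) U', the model var(y) = sigma_p^2 * (h2 * A + (1-h2) * I)
## gives independent rotated components. Only the <= p nonzero eigenvalues
## need explicit eigenvectors; the orthogonal complement contributes through
## the residual sum of squares. Total variance is profiled out analytically,
## leaving a 1-D likelihood in h2.
.h2Spectrum <- function(y, Z) {
  n <- nrow(Z)
  p <- ncol(Z)
  if (p <= n) {
    K <- crossprod(Z) / p                  # p x p
    eig <- eigen(K, symmetric = TRUE)
    pos <- eig$values > 1e-10
    d <- eig$values[pos]
    ## eigenvectors of A for nonzero eigenvalues: u_i = Z v_i / sqrt(p d_i)
    U <- Z %*% eig$vectors[, pos, drop = FALSE]
    U <- sweep(U, 2, sqrt(p * d), "/")
  } else {
    A <- tcrossprod(Z) / p
    eig <- eigen(A, symmetric = TRUE)
    pos <- eig$values > 1e-10
    d <- eig$values[pos]
    U <- eig$vectors[, pos, drop = FALSE]
  }
  u2 <- as.numeric(crossprod(U, y))^2
  rss0 <- max(sum(y^2) - sum(u2), 0)
  list(d = d, u2 = u2, rss0 = rss0, n = n)
}

.h2LogLik <- function(h2, spec, nEff) {
  v <- h2 * spec$d + (1 - h2)
  nZero <- nEff - length(spec$d)
  if (nZero < 0) nZero <- 0
  quad <- sum(spec$u2 / v) +
    if (nZero > 0) spec$rss0 / (1 - h2) else 0
  if (!is.finite(quad) || quad <= 0) return(-Inf)
  sigmaP2 <- quad / nEff
  -0.5 * (nEff * log(sigmaP2) + sum(log(v)) +
            max(nZero, 0) * log(1 - h2) + nEff)
}

#' Estimate cis-SNP heritability of expression by REML
#'
#' Fits the variance-component model `var(y') = A sigma_g^2 + I sigma_e^2`,
#' where `y'` is expression residualized on fixed-effect covariates and
#' `A = ZZ'/p` is the kinship of standardized cis genotypes. The restricted
#' likelihood is profiled down to one dimension in
#' `h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)` and maximized by a coarse grid
#' followed by golden-section refinement. Significance against
#' `sigma_g^2 = 0` uses the likelihood-ratio statistic referred to the
#' boundary 50:50 mixture of a point mass at zero and chi-squared(1).
#'
#' @param y numeric expression vector (one gene).
#' @param X a [GenotypeMatrix-class] or dosage matrix of cis SNPs.
#' @param C optional covariate matrix (no intercept column needed).
#' @return An [H2Estimate-class].
#' @export
estimateCisH2 <- function(y, X, C = NULL) {
  if (is(X, "GenotypeMatrix")) X <- dosages(X)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, ncol(X) >= 1)
  q <- 1 + if (is.null(C)) 0 else qr(as.matrix(C))$rank
  if (n <= q + 2) stop("too few samples relative to covariates")

  y <- as.numeric(.residualize(y, C))
  Z <- .standardize(X)
  spec <- .h2Spectrum(y, Z)
  nEff <- n - q

  hMax <- if (nEff > length(spec$d) && spec$rss0 > 1e-12 * sum(y^2))
    1 - 1e-8 else 1
  grid <- seq(0, min(hMax, 0.999999), length.out = 51)
  ll <- vapply(grid, .h2LogLik, numeric(1), spec = spec, nEff = nEff)
  best <- which.max(ll)
  lo <- grid[max(best - 1, 1)]
  hi <- grid[min(best + 1, length(grid))]
  opt <- stats::optimize(.h2LogLik, c(lo, hi), spec = spec, nEff = nEff,
                         maximum = TRUE, tol = 1e-8)
  h2 <- opt$maximum
  llHat <- opt$objective
  if (ll[best] > llHat) { h2 <- grid[best]; llHat <- ll[best] }
  ## keep exact boundary values clean
  if (.h2LogLik(0, spec, nEff) >= llHat) { h2 <- 0; llHat <- .h2LogLik(0, spec, nEff) }

  v <- h2 * spec$d + (1 - h2)
  nZero <- max(nEff - length(spec$d), 0)
  quad <- sum(spec$u2 / v) + if (nZero > 0) spec$rss0 / (1 - h2) else 0
  sigmaP2 <- quad / nEff

  ll0 <- .h2LogLik(0, spec, nEff)
  lrt <- max(2 * (llHat - ll0), 0)
  pValue <- if (lrt <= 0) 1 else
    0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)

  new("H2Estimate", h2 = h2, sigmaG2 = h2 * sigmaP2,
      sigmaE2 = (1 - h2) * sigmaP2, pValue = pValue, logLik = llHat,
      converged = is.finite(llHat))
}

#' Keep genes with nominally significant cis-heritability
#'
#' Retains genes whose REML likelihood-ratio p-value is strictly below
#' `alpha`; genes without evidence of cis-genetic regulation are unlikely
#' to yield usable predictive models and are pruned before training.
#'
#' @param estimates named list of [H2Estimate-class] objects (names = genes).
#' @param alpha significance level (default 0.05).
#' @return Character vector of retained gene names, with attributes
#'   `n_tested` and `n_kept`.
#' @export
filterHeritable <- function(estimates, alpha = 0.05) {
  pvals <- vapply(estimates, function(e) e@pValue, numeric(1))
  keep <- as.character(names(estimates))[pvals < alpha]
  structure(keep, n_tested = length(estimates), n_kept = length(keep))
}

#' Normalized prediction accuracy
#'
#' Cross-validation R-squared as a fraction of its upper bound, the gene's
#' cis-heritability: `min(cvR2 / h2, 1)`, with negative R-squared clamped
#' to zero.
#'
#' @param cvR2 out-of-sample R-squared.
#' @param h2 cis-heritability estimate, must be positive.
#' @return A fraction in `[0, 1]`.
#' @export
normalizedAccuracy <- function(cvR2, h2) {
  if (any(h2 <= 0)) stop("h2 must be positive")
  pmin(pmax(cvR2, 0) / h2, 1)
}

## Fit one candidate estimator on (Z, y); returns the weight vector.
.fitWeights <- function(model, Z, y, h2, lambdaSeq = NULL, inner = 5) {
  p <- ncol(Z)
  switch(model,
    top1 = {
      b <- as.numeric(crossprod(Z, y)) / nrow(Z)
      j <- which.max(abs(b))
      w <- numeric(p)
      w[j] <- b[j]
      w
    },
    blup = {
      ## mixed-model ridge with lambda = p(1-h2)/h2 (GBLUP equivalence)
      h <- min(max(h2, 0.01), 0.99)
      lam <- p * (1 - h) / h
      as.numeric(solve(crossprod(Z) + diag(lam, p), crossprod(Z, y)))
    },
    lasso = ,
    enet = {
      alpha <- if (model == "lasso") 1 else 0.5
      cv <- glmnet::cv.glmnet(Z, y, alpha = alpha, nfolds = inner,
                              standardize = FALSE, intercept = TRUE,
                              nlambda = 40)
      as.numeric(stats::coef(cv, s = "lambda.min"))[-1]
    },
    stop("unknown model: ", model))
}

#' Train penalized expression weight models with CV model selection
#'
#' Fits a menu of estimators -- ridge-BLUP, LASSO, Elastic Net (mixing 0.5,
#' penalty chosen by inner fivefold CV) and `top1` (the single best marginal
#' eQTL SNP) -- on covariate-residualized expression, measures fivefold
#' out-of-sample R-squared for each, and keeps the model with the largest
#' R-squared among those whose cross-validated predictions correlate with
#' observed expression at one-sided P < 0.05. The winner is refit on all
#' samples for the final weights. Fold assignment is a deterministic
#' function of `seed`.
#'
#' @param y expression vector for one gene.
#' @param X a [GenotypeMatrix-class] or dosage matrix of cis SNPs.
#' @param C optional covariate matrix, residualized out first.
#' @param folds number of cross-validation folds (default 5).
#' @param models candidate estimators, subset of
#'   `c("blup", "lasso", "enet", "top1")`.
#' @param h2 optional precomputed [H2Estimate-class]; estimated if missing
#'   (it parameterizes the BLUP penalty and is stored on the model).
#' @param gene,panel identifiers stored on the result.
#' @param seed RNG seed for fold assignment.
#' @return A [GeneModel-class], or `NULL` when no candidate reaches
#'   significance (the gene is untrainable; no error is raised).
#' @export
trainWeights <- function(y, X, C = NULL, folds = 5,
                         models = c("blup", "lasso", "enet", "top1"),
                         h2 = NULL, gene = "gene", panel = "panel",
                         seed = 1) {
  g <- NULL
  if (is(X, "GenotypeMatrix")) { g <- X; X <- dosages(X) }
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n)
  models <- match.arg(models, several.ok = TRUE)

  yr <- as.numeric(.residualize(y, C))
  Z <- .standardize(X)
  if (is.null(h2)) h2 <- estimateCisH2(y, X, C)

  .checkSeed(seed)
  foldId <- sample(rep_len(seq_len(folds), n))

  cvTab <- data.frame(model = models, cv_r2 = NA_real_, cv_p = NA_real_,
                      stringsAsFactors = FALSE)
  preds <- matrix(NA_real_, n, length(models),
                  dimnames = list(NULL, models))
  for (m in seq_along(models)) {
    for (f in seq_len(folds)) {
      tr <- foldId != f
      Ztr <- .standardize(X[tr, , drop = FALSE])
      w <- tryCatch(.fitWeights(models[m], Ztr, yr[tr], h2@h2),
                    error = function(e) numeric(ncol(X)))
      ## apply training-fold standardization to held-out genotypes
      mu <- colMeans(X[tr, , drop = FALSE])
      sd <- apply(X[tr, , drop = FALSE], 2, stats::sd)
      sd[sd == 0] <- 1
      Zte <- sweep(sweep(X[!tr, , drop = FALSE], 2, mu, "-"), 2, sd, "/")
      preds[!tr, m] <- as.numeric(Zte %*% w)
    }
    if (stats::sd(preds[, m]) > 0) {
      ct <- stats::cor.test(preds[, m], yr, alternative = "greater")
      r <- ct$estimate
      cvTab$cv_r2[m] <- sign(r) * r^2
      cvTab$cv_p[m] <- ct$p.value
    } else {
      cvTab$cv_r2[m] <- 0
      cvTab$cv_p[m] <- 1
    }
  }

  eligible <- which(cvTab$cv_p < 0.05)
  if (!length(eligible)) return(NULL)
  bestIdx <- eligible[which.max(cvTab$cv_r2[eligible])]
  label <- models[bestIdx]

  w <- .fitWeights(label, Z, yr, h2@h2)
  if (all(w == 0)) {
    ## degenerate full-data refit (e.g. LASSO shrank everything away):
    ## fall back through the remaining eligible models by R2
    for (idx in eligible[order(-cvTab$cv_r2[eligible])]) {
      w <- .fitWeights(models[idx], Z, yr, h2@h2)
      if (any(w != 0)) { label <- models[idx]; bestIdx <- idx; break }
    }
    if (all(w == 0)) return(NULL)
  }

  snps <- if (!is.null(g)) snpInfo(g)[, c("snp_id", "a1", "a2")]
  else data.frame(snp_id = colnames(X) %||% paste0("snp", seq_len(ncol(X))),
                  a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  new("GeneModel", gene = gene, panel = panel, snps = snps, weights = w,
      modelLabel = label, cvR2 = cvTab$cv_r2[bestIdx],
      cvP = cvTab$cv_p[bestIdx], h2 = h2, cvTable = cvTab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict genetic expression from a weight model
#'
#' Standardizes genotype columns and applies the model weights; SNPs are
#' matched by id, with sign flips for swapped alleles (strand flips via
#' complement matching). SNPs absent from the genotypes contribute zero.
#'
#' @param model a [GeneModel-class].
#' @param g a [GenotypeMatrix-class].
#' @return Numeric vector of predicted expression, one value per sample.
#' @export
predictExpression <- function(model, g) {
  stopifnot(is(model, "GeneModel"), is(g, "GenotypeMatrix"))
  ref <- snpInfo(g)
  idx <- match(model@snps$snp_id, ref$snp_id)
  keep <- which(!is.na(idx))
  if (!length(keep)) stop("no model SNP found in the genotypes")
  a1 <- model@snps$a1[keep]; a2 <- model@snps$a2[keep]
  r1 <- ref$a1[idx[keep]]; r2 <- ref$a2[idx[keep]]
  sgn <- ifelse(a1 == r1 & a2 == r2, 1,
         ifelse(a1 == r2 & a2 == r1, -1,
         ifelse(.complementAllele(a1) == r1 & .complementAllele(a2) == r2, 1,
         ifelse(.complementAllele(a1) == r2 & .complementAllele(a2) == r1,
                -1, NA))))
  usable <- !is.na(sgn)
  Z <- .standardize(dosages(g)[, idx[keep][usable], drop = FALSE])
  as.numeric(Z %*% (model@weights[keep][usable] * sgn[usable]))
}
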