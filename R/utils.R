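## Internal helpers shared across modules.

## Order chromosome labels numerically where possible ("1" < "2" < "10" < "X").
.chromRank <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom))
  num <- suppressWarnings(as.numeric(x))
  num[is.na(num)] <- 1000 + as.numeric(factor(x[is.na(num)]))
  num
}

.sortRecords <- function(records) {
  records[order(.chromRank(records$chrom), records$pos), , drop = FALSE]
}

.logRule <- function(qcLog, rule, n) {
  rbind(qcLog, data.frame(rule = rule, n_removed = as.integer(n),
                          stringsAsFactors = FALSE))
}

.complementAllele <- function(a) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[a])
}

.isAmbiguousPair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

## Standardize columns to mean 0, sd 1 (population sd is irrelevant here;
## any constant rescale cancels in every downstream ratio).
.standardize <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  if (any(sd == 0)) stop("cannot standardize a constant column")
  sweep(sweep(X, 2, mu, "-"), 2, sd, "/")
}

## Residualize y (vector or matrix) on covariates incl. an intercept.
.residualize <- function(y, C = NULL) {
  y <- as.matrix(y)
  M <- cbind(rep(1, nrow(y)), C)
  as.matrix(stats::residuals(stats::lm.fit(M, y)))
}

## Draw from MVN(mu, Sigma) via Cholesky with a small jitter fallback.
.rmvn <- function(n, mu, Sigma) {
  L <- tryCatch(chol(Sigma),
                error = function(e) chol(Sigma + diag(1e-8, nrow(Sigma))))
  sweep(matrix(stats::rnorm(n * nrow(Sigma)), n) %*% L, 2, mu, "+")
}

.checkSeed <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}
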