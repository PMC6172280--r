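## Shared fixtures and independent oracles used across test files.

## Write a small sumstats TSV and return its path.
writeSumstatsFixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

## A well-formed record set used as a base for QC fixtures.
cleanRecords <- function(n = 2, chrom = "1") {
  data.frame(
    SNP = sprintf("rs%d", seq_len(n)), CHR = chrom,
    BP = 1000L * seq_len(n), A1 = "A", A2 = "G",
    Z = seq_len(n) / 2, MAF = 0.25, N = 1000,
    stringsAsFactors = FALSE)
}

## Hand-built GenotypeMatrix from a dosage matrix.
makeGenotypes <- function(X, chrom = "1", startBp = 1000L,
                          spacing = 1000L) {
  X <- matrix(as.numeric(X), nrow(X))
  p <- ncol(X)
  snps <- data.frame(
    snp_id = sprintf("rs%d", seq_len(p)), chrom = chrom,
    pos = as.integer(startBp + (seq_len(p) - 1) * spacing),
    a1 = "A", a2 = "G",
    maf = pmin(colMeans(X, na.rm = TRUE) / 2,
               1 - colMeans(X, na.rm = TRUE) / 2),
    stringsAsFactors = FALSE)
  samples <- sprintf("s%03d", seq_len(nrow(X)))
  dimnames(X) <- list(samples, snps$snp_id)
  new("GenotypeMatrix", dosages = X, snps = snps, samples = samples)
}

## Minimal GeneModel wrapper for conditional / prediction tests.
makeModel <- function(w, snpIds, gene = "g", panel = "p",
                      a1 = "A", a2 = "G") {
  h2 <- new("H2Estimate", h2 = 0.5, sigmaG2 = 0.5, sigmaE2 = 0.5,
            pValue = 0.01, logLik = 0, converged = TRUE)
  new("GeneModel", gene = gene, panel = panel,
      snps = data.frame(snp_id = snpIds, a1 = a1, a2 = a2,
                        stringsAsFactors = FALSE),
      weights = w, modelLabel = "top1", cvR2 = 0.3, cvP = 0.01,
      h2 = h2, cvTable = data.frame())
}

## All permutations of 1..n (oracle helper; n <= 7).
allPermutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- allPermutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  out
}

## Exhaustive permutation p-value oracle: fraction of all weight orders
## whose |z| reaches the observed |z| (the estimator's target quantity).
exactPermutationP <- function(w, z, V) {
  obs <- abs(sum(w * z)) / sqrt(as.numeric(t(w) %*% V %*% w))
  perms <- allPermutations(length(w))
  stat <- apply(perms, 1, function(ix) {
    wp <- w[ix]
    abs(sum(wp * z)) / sqrt(as.numeric(t(wp) %*% V %*% wp))
  })
  mean(stat >= obs - 1e-12)
}

## Brute-force one-sided hypergeometric tail by log-space enumeration.
bruteHyperP <- function(both, aOnly, bOnly, neither) {
  nA <- both + aOnly
  nB <- both + bOnly
  N <- both + aOnly + bOnly + neither
  kMax <- min(nA, nB)
  terms <- vapply(both:kMax, function(k) {
    lchoose(nA, k) + lchoose(N - nA, nB - k) - lchoose(N, nB)
  }, numeric(1))
  m <- max(terms)
  exp(m) * sum(exp(terms - m))
}
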