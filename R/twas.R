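#' Summary-based TWAS association statistic
#'
#' Association between cis-genetically predicted expression and the trait
#' from GWAS summary data alone:
#' `z = w'z_gwas / sqrt(w'Vw)`, where `w` are the expression weights,
#' `z_gwas` the SNP Wald statistics and `V` the reference LD matrix, all on
#' a shared SNP order and allele frame (see [harmonizeAlleles()]). The
#' statistic is invariant to positive rescaling of `w`; its p-value is
#' two-tailed under the standard normal.
#'
#' @param w numeric weight vector.
#' @param zGwas numeric vector of GWAS Z-scores, aligned with `w`.
#' @param V an [LDMatrix-class] or plain correlation matrix, same order.
#' @param gene label used in error messages.
#' @return A list with elements `z_twas` and `p_twas`.
#' @export
twasZscore <- function(w, zGwas, V, gene = "gene") {
  if (is(V, "LDMatrix")) V <- ldMatrix(V)
  stopifnot(length(w) == length(zGwas), nrow(V) == length(w))
  denom2 <- as.numeric(t(w) %*% V %*% w)
  if (denom2 <= 1e-8)
    stop("degenerate model for ", gene,
         ": predicted expression has (near-)zero variance in the reference")
  z <- sum(w * zGwas) / sqrt(denom2)
  list(z_twas = z, p_twas = zToP(z))
}

#' Convert between Z-scores and two-tailed p-values
#'
#' `zToP()` returns the two-tailed normal p-value of a Z-score, computed on
#' the log scale so extreme statistics do not underflow. `pToZ()` inverts
#' it, attaching the requested sign. The two are mutually inverse to
#' numerical precision.
#'
#' @param z numeric Z-score(s).
#' @param p two-tailed p-value(s) in (0, 1).
#' @param sign sign of the returned Z (+1 or -1, default +1).
#' @return Numeric vector.
#' @examples
#' pToZ(1.25e-11, sign = -1)  # -6.77
#' zToP(0)                    # 1
#' @export
zToP <- function(z) {
  2 * stats::pnorm(abs(z), lower.tail = FALSE)
}

#' @rdname zToP
#' @export
pToZ <- function(p, sign = 1) {
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly inside (0, 1)")
  sign * stats::qnorm(p / 2, lower.tail = FALSE)
}

#' Bonferroni significance threshold
#'
#' `alpha / M` for `M` tested gene models; conservative when models are
#' correlated across tissues.
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param M number of predictive models tested.
#' @return The per-test threshold.
#' @examples
#' bonferroniThreshold(0.05, 109170)  # 4.58e-7
#' @export
bonferroniThreshold <- function(alpha = 0.05, M) {
  stopifnot(M >= 1)
  alpha / M
}

#' Adaptive permutation test for a TWAS association
#'
#' Permutes the expression weights across the model's SNP slots while
#' keeping the GWAS Z-scores (and hence local GWAS signal) fixed,
#' recomputing `|z|` each time. This conditions on the observed GWAS signal
#' and asks whether the specific SNP-weight configuration matters, guarding
#' against chance colocalization. Sampling stops early once `stopExceed`
#' permuted statistics reach `|z_twas|`; the estimate is
#' `perm_p = (1 + exceedances) / (1 + permutations)`. Deterministic given
#' `seed`.
#'
#' @inheritParams twasZscore
#' @param maxPerm maximum permutations (default 10000).
#' @param stopExceed early-stopping exceedance count (default 10; use `Inf`
#'   to disable early stopping).
#' @param seed RNG seed.
#' @param batch internal batch size for vectorized sampling.
#' @return A list with `perm_p`, `perm_n` (permutations performed) and
#'   `exceed`.
#' @export
permutationTest <- function(w, zGwas, V, maxPerm = 10000, stopExceed = 10,
                            seed = 1, batch = 256) {
  if (is(V, "LDMatrix")) V <- ldMatrix(V)
  p <- length(w)
  if (p < 2) stop("permutation test undefined for fewer than 2 SNPs")
  stopifnot(length(zGwas) == p, nrow(V) == p)
  obs <- abs(twasZscore(w, zGwas, V)$z_twas)
  .checkSeed(seed)

  exceed <- 0L
  nDone <- 0L
  while (nDone < maxPerm && exceed < stopExceed) {
    b <- min(batch, maxPerm - nDone)
    P <- matrix(0, b, p)
    for (i in seq_len(b)) P[i, ] <- w[sample.int(p)]
    num <- as.numeric(P %*% zGwas)
    den2 <- rowSums((P %*% V) * P)
    zPerm <- abs(num) / sqrt(den2)
    ## honor sequential early stopping inside the batch; ties with the
    ## observed statistic count as exceedances (small tolerance so the
    ## identity permutation is never lost to rounding)
    hits <- which(zPerm >= obs * (1 - 1e-12) - 1e-12)
    if (length(hits) && exceed + length(hits) >= stopExceed) {
      need <- stopExceed - exceed
      cutoff <- hits[need]
      exceed <- exceed + need
      nDone <- nDone + cutoff
      break
    }
    exceed <- exceed + length(hits)
    nDone <- nDone + b
  }
  list(perm_p = (1 + exceed) / (1 + nDone), perm_n = nDone,
       exceed = exceed)
}

#' Run the TWAS scan over a set of gene models
#'
#' For each trained [GeneModel-class], aligns summary statistics and the LD
#' reference to the model's SNPs, computes the TWAS Z-score and p-value,
#' annotates the strongest GWAS SNP in the gene's cis window, and
#' (optionally) the adaptive permutation p-value. Models losing more than
#' half of their absolute weight mass to harmonization are flagged.
#'
#' @param models list of [GeneModel-class] objects.
#' @param ss a harmonized [SumStats-class].
#' @param ld an [LDMatrix-class] covering the models' SNPs.
#' @param geneInfo optional data.frame (`gene`, `chrom`, `tss`) used for the
#'   best-cis-SNP annotation; cis window is `tss` +/- `window`.
#' @param window cis-window half-width in bp (default 1e6).
#' @param permute logical; run [permutationTest()] per model.
#' @param maxPerm,stopExceed,seed passed to [permutationTest()].
#' @return A [TwasResults-class].
#' @export
twasScan <- function(models, ss, ld, geneInfo = NULL, window = 1e6,
                     permute = FALSE, maxPerm = 10000, stopExceed = 10,
                     seed = 1) {
  stopifnot(is(ss, "SumStats"), is(ld, "LDMatrix"))
  r <- records(ss)
  V <- ldMatrix(ld)
  rows <- lapply(seq_along(models), function(i) {
    m <- models[[i]]
    idx <- match(m@snps$snp_id, r$snp_id)
    keep <- which(!is.na(idx) & m@snps$snp_id %in% ld@snps)
    if (length(keep) < 1)
      stop("no usable SNP for model ", m@gene, " / ", m@panel)
    lost <- 1 - sum(abs(m@weights[keep])) / sum(abs(m@weights))
    snps <- m@snps$snp_id[keep]
    w <- m@weights[keep]
    z <- r$z[idx[keep]]
    Vi <- V[snps, snps, drop = FALSE]
    tw <- twasZscore(w, z, Vi, gene = m@gene)

    bestSnp <- NA_character_; bestP <- NA_real_
    if (!is.null(geneInfo)) {
      gi <- geneInfo[geneInfo$gene == m@gene, , drop = FALSE]
      if (nrow(gi)) {
        cis <- r$chrom == as.character(gi$chrom[1]) &
          abs(r$pos - gi$tss[1]) <= window
        if (any(cis)) {
          pv <- zToP(r$z[cis])
          bi <- which.min(pv)
          bestSnp <- r$snp_id[cis][bi]
          bestP <- pv[bi]
        }
      }
    }
    permP <- NA_real_; permN <- NA_integer_
    if (permute && length(keep) >= 2) {
      pt <- permutationTest(w, z, Vi, maxPerm = maxPerm,
                            stopExceed = stopExceed, seed = seed + i)
      permP <- pt$perm_p; permN <- pt$perm_n
    }
    data.frame(gene = m@gene, panel = m@panel, z_twas = tw$z_twas,
               p_twas = tw$p_twas, n_snps_used = length(keep),
               weight_mass_lost = lost, best_gwas_snp = bestSnp,
               best_gwas_p = bestP, perm_p = permP, perm_n = permN,
               stringsAsFactors = FALSE)
  })
  new("TwasResults", table = do.call(rbind, rows))
}

#' Flag gene models whose TWAS statistic beats the local GWAS signal
#'
#' Indicator per result row: `TRUE` when the TWAS chi-squared strictly
#' exceeds that of the strongest GWAS SNP in the gene's cis window (ties
#' count as `FALSE`); `NA` when the window held no SNPs. A gene model
#' beating its best local SNP suggests expression aggregates signal across
#' multiple regulatory variants.
#'
#' @param results a [TwasResults-class] whose table carries `best_gwas_p`.
#' @return Logical vector, one entry per result row.
#' @export
flagJointGwasComparison <- function(results) {
  tab <- resultTable(results)
  if (!"best_gwas_p" %in% names(tab))
    stop("results lack the best_gwas_p annotation")
  ok <- !is.na(tab$best_gwas_p)
  out <- rep(NA, nrow(tab))
  bestChi2 <- pToZ(pmin(pmax(tab$best_gwas_p[ok], 1e-300), 1 - 1e-16))^2
  ## strict comparison; a small tolerance keeps p->z round-trip noise from
  ## promoting exact ties
  out[ok] <- tab$z_twas[ok]^2 > bestChi2 * (1 + 1e-8) + 1e-8
  out
}
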