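#' Correlations between SNPs and predicted expression at a locus
#'
#' With `W` the p x G matrix of model weights aligned to the locus SNP
#' order (zero for SNPs a model does not use) and
#' `D = diag(sqrt(w_g' V w_g))`, returns the SNP-by-gene correlation
#' `C = V W D^-1` and the gene-by-gene predicted-expression correlation
#' `V_GE = D^-1 W' V W D^-1` (unit diagonal).
#'
#' @param models list of [GeneModel-class] objects.
#' @param ld an [LDMatrix-class] giving the locus SNP order.
#' @return List with `C` (p x G), `VGE` (G x G), and `labels` (gene:panel).
#' @export
predictedExpressionCorrelations <- function(models, ld) {
  stopifnot(is(ld, "LDMatrix"))
  V <- ldMatrix(ld)
  p <- nrow(V)
  G <- length(models)
  W <- matrix(0, p, G)
  labels <- character(G)
  for (g in seq_len(G)) {
    m <- models[[g]]
    idx <- match(m@snps$snp_id, ld@snps)
    if (anyNA(idx) && all(is.na(idx)))
      stop("model ", m@gene, " shares no SNP with the LD matrix")
    W[idx[!is.na(idx)], g] <- m@weights[!is.na(idx)]
    labels[g] <- paste(m@gene, m@panel, sep = ":")
  }
  VW <- V %*% W
  d2 <- colSums(W * VW)
  if (any(d2 <= 1e-8))
    stop("degenerate gene model(s): ",
         paste(labels[d2 <= 1e-8], collapse = ", "))
  Dinv <- 1 / sqrt(d2)
  C <- sweep(VW, 2, Dinv, "*")
  VGE <- crossprod(W, VW) * tcrossprod(Dinv)
  diag(VGE) <- 1
  dimnames(C) <- list(ld@snps, labels)
  dimnames(VGE) <- list(labels, labels)
  list(C = C, VGE = VGE, labels = labels)
}

#' SNP association statistics conditional on predicted expression
#'
#' Removes the component of the GWAS signal explained by the predicted
#' expression of selected genes:
#' `z_resid = z_gwas - C V_GE^-1 z_twas`, standardized per SNP by the
#' square root of `diag(V - C V_GE^-1 C')`. Gene models that are collinear
#' in predicted expression (`|r| > pruneR` in `V_GE`) are pruned first,
#' keeping the model with the larger `|z_twas|`. SNPs whose residual
#' variance falls below `tol` are reported as fully explained with
#' conditional Z set to 0.
#'
#' @param zGwas marginal GWAS Z-scores in the locus SNP order.
#' @param corr output of [predictedExpressionCorrelations()].
#' @param zTwas TWAS Z-scores, one per gene model in `corr`.
#' @param ld the locus [LDMatrix-class].
#' @param snps optional data.frame (`snp_id`, `chrom`, `pos`) describing
#'   the locus SNPs.
#' @param pruneR collinearity threshold on `|V_GE|` (default 0.95).
#' @param tol residual-variance floor (default 1e-6).
#' @return A [ConditionalResult-class].
#' @export
conditionalZscores <- function(zGwas, corr, zTwas, ld, snps = NULL,
                               pruneR = 0.95, tol = 1e-6) {
  stopifnot(is(ld, "LDMatrix"))
  V <- ldMatrix(ld)
  C <- corr$C
  VGE <- corr$VGE
  labels <- corr$labels
  stopifnot(length(zTwas) == ncol(C), length(zGwas) == nrow(C))

  ## collinearity pruning: drop the weaker member of every |r|>pruneR pair
  keep <- seq_along(labels)
  ord <- order(-abs(zTwas))
  pruned <- integer(0)
  for (i in ord) {
    if (i %in% pruned) next
    clash <- which(abs(VGE[i, ]) > pruneR)
    clash <- setdiff(clash, c(i, pruned))
    clash <- clash[abs(zTwas[clash]) <= abs(zTwas[i])]
    pruned <- c(pruned, clash)
  }
  keep <- setdiff(keep, pruned)
  if (!length(keep)) stop("all gene models pruned as collinear")
  Ck <- C[, keep, drop = FALSE]
  Vk <- VGE[keep, keep, drop = FALSE]
  zk <- zTwas[keep]

  Vinv <- tryCatch(solve(Vk), error = function(e)
    stop("predicted-expression correlation matrix not invertible after ",
         "pruning; collinear block: ", paste(labels[keep], collapse = ", ")))
  proj <- Ck %*% Vinv
  zCond <- zGwas - as.numeric(proj %*% zk)
  residVar <- unname(diag(V)) - unname(rowSums(proj * Ck))
  residVar <- pmin(pmax(residVar, 0), 1)
  fully <- residVar < tol
  z <- numeric(length(zGwas))
  z[!fully] <- zCond[!fully] / sqrt(residVar[!fully])

  if (is.null(snps))
    snps <- data.frame(snp_id = ld@snps, chrom = NA_character_,
                       pos = NA_integer_, stringsAsFactors = FALSE)
  new("ConditionalResult", snps = snps, zMarginal = as.numeric(zGwas),
      zConditional = z, genes = labels[keep],
      pruned = labels[pruned], residVar = residVar,
      fullyExplained = fully)
}

#' Export a conditional analysis as a TSV table
#'
#' @param x a [ConditionalResult-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeConditional <- function(x, path) {
  stopifnot(is(x, "ConditionalResult"))
  tab <- data.frame(
    snp = x@snps$snp_id, chrom = x@snps$chrom, pos = x@snps$pos,
    z_marginal = x@zMarginal, p_marginal = zToP(x@zMarginal),
    z_conditional = x@zConditional,
    p_conditional = ifelse(x@fullyExplained, NA, zToP(x@zConditional)),
    fully_explained = x@fullyExplained,
    genes_conditioned = paste(x@genes, collapse = ","),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
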