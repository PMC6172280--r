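#' @import methods
NULL

## Column order used throughout for summary-statistic tables.
.SUMSTAT_COLS <- c("snp_id", "chrom", "pos", "a1", "a2", "z", "maf", "n")

.VALID_ALLELES <- c("A", "C", "G", "T")

#' GWAS summary statistics
#'
#' Container for per-SNP GWAS association records (Wald Z-scores) together
#' with a provenance log of quality-control actions. Records are kept unique
#' by rsID and sorted by (chromosome, position).
#'
#' @slot records data.frame with columns `snp_id`, `chrom`, `pos`, `a1`,
#'   `a2`, `z`, `maf`, `n`. Positions are 1-based; `a1` is the effect allele
#'   to which the sign of `z` refers; `maf` is the minor allele frequency.
#' @slot qcLog data.frame with columns `rule` and `n_removed` recording every
#'   filtering action applied so far.
#'
#' @seealso [loadSumstats()], [qcSumstats()], [harmonizeAlleles()]
#' @export
setClass("SumStats",
  representation(records = "data.frame", qcLog = "data.frame"),
  prototype(
    records = data.frame(
      snp_id = character(), chrom = character(), pos = integer(),
      a1 = character(), a2 = character(), z = numeric(),
      maf = numeric(), n = numeric(), stringsAsFactors = FALSE
    ),
    qcLog = data.frame(rule = character(), n_removed = integer(),
                       stringsAsFactors = FALSE)
  )
)

setValidity("SumStats", function(object) {
  r <- object@records
  msg <- character()
  if (!all(.SUMSTAT_COLS %in% names(r)))
    msg <- c(msg, paste("records must contain columns:",
                        paste(.SUMSTAT_COLS, collapse = ", ")))
  else {
    if (anyDuplicated(r$snp_id))
      msg <- c(msg, paste("duplicated snp_id:",
                          r$snp_id[duplicated(r$snp_id)][1L]))
    if (nrow(r) && any(r$a1 == r$a2))
      msg <- c(msg, "a1 and a2 must differ for every record")
    if (nrow(r) && (any(r$maf < 0) || any(r$maf > 0.5)))
      msg <- c(msg, "maf must lie in [0, 0.5]")
    if (nrow(r) && any(!is.finite(r$z)))
      msg <- c(msg, "all z must be finite")
    o <- order(.chromRank(r$chrom), r$pos)
    if (nrow(r) && !identical(o, seq_len(nrow(r))))
      msg <- c(msg, "records must be sorted by (chrom, pos)")
  }
  if (length(msg)) msg else TRUE
})

#' Reference genotype dosage matrix
#'
#' Dosages for `n` samples at `p` SNPs (values in `[0, 2]`; fractional after
#' mean-imputation of missing calls), with per-SNP descriptors.
#'
#' @slot dosages numeric matrix, samples in rows, SNPs in columns.
#' @slot snps data.frame with columns `snp_id`, `chrom`, `pos`, `a1`, `a2`,
#'   `maf`, one row per column of `dosages`.
#' @slot samples character vector of sample identifiers.
#' @export
setClass("GenotypeMatrix",
  representation(dosages = "matrix", snps = "data.frame",
                 samples = "character"))

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  if (nrow(object@snps) != ncol(object@dosages))
    msg <- c(msg, "snps rows must match dosage columns")
  if (length(object@samples) != nrow(object@dosages))
    msg <- c(msg, "samples must match dosage rows")
  if (length(msg)) msg else TRUE
})

#' SNP correlation (LD) matrix for a locus
#'
#' @slot V symmetric p x p SNP correlation matrix (unit diagonal), optionally
#'   ridge-regularized towards the identity.
#' @slot snps character vector giving the SNP order of `V`.
#' @slot ridge regularization weight lambda actually applied:
#'   `V = (1 - lambda) * cor(X) + lambda * I`.
#' @export
setClass("LDMatrix",
  representation(V = "matrix", snps = "character", ridge = "numeric"))

setValidity("LDMatrix", function(object) {
  msg <- character()
  V <- object@V
  if (nrow(V) != ncol(V)) msg <- c(msg, "V must be square")
  if (length(object@snps) != nrow(V))
    msg <- c(msg, "snps must match dimension of V")
  if (nrow(V) && max(abs(V - t(V))) > 1e-8)
    msg <- c(msg, "V must be symmetric")
  if (length(msg)) msg else TRUE
})

#' Cis-SNP heritability estimate for one gene
#'
#' Result of restricted maximum-likelihood estimation of the variance
#' components in `var(y) = A * sigma_g^2 + I * sigma_e^2`, with
#' `h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)`.
#'
#' @slot h2 heritability estimate in `[0, 1]`.
#' @slot sigmaG2,sigmaE2 genetic and environmental variance components.
#' @slot pValue likelihood-ratio p-value against `sigma_g^2 = 0`, using the
#'   50:50 mixture of a point mass at zero and chi-squared with 1 df.
#' @slot logLik profile log-likelihood at the estimate.
#' @slot converged logical; `FALSE` signals a boundary/degenerate fit.
#' @export
setClass("H2Estimate",
  representation(h2 = "numeric", sigmaG2 = "numeric", sigmaE2 = "numeric",
                 pValue = "numeric", logLik = "numeric",
                 converged = "logical"))

#' Trained expression weight model for one gene in one panel
#'
#' @slot gene,panel identifiers.
#' @slot snps data.frame (`snp_id`, `a1`, `a2`) for the model SNPs; weights
#'   refer to the dosage of `a1` on the standardized-genotype scale.
#' @slot weights numeric weight vector, same length as rows of `snps`.
#' @slot modelLabel which estimator won model selection
#'   (`"blup"`, `"lasso"`, `"enet"` or `"top1"`).
#' @slot cvR2 fivefold out-of-sample R-squared of the winning model.
#' @slot cvP one-sided p-value for `cvR2` (correlation test between
#'   cross-validated predictions and observed expression).
#' @slot h2 the gene's [H2Estimate-class].
#' @slot cvTable data.frame of per-candidate-model cross-validation results.
#' @export
setClass("GeneModel",
  representation(gene = "character", panel = "character",
                 snps = "data.frame", weights = "numeric",
                 modelLabel = "character", cvR2 = "numeric", cvP = "numeric",
                 h2 = "H2Estimate", cvTable = "data.frame"))

setValidity("GeneModel", function(object) {
  msg <- character()
  if (length(object@weights) != nrow(object@snps))
    msg <- c(msg, "weights must match snps")
  if (length(object@weights) && all(object@weights == 0))
    msg <- c(msg, "model must have at least one nonzero weight")
  if (any(!is.finite(object@weights)))
    msg <- c(msg, "weights must be finite")
  if (length(object@cvR2) && object@cvR2 > 1)
    msg <- c(msg, "cvR2 cannot exceed 1")
  if (length(msg)) msg else TRUE
})

#' Reference expression panel
#'
#' Expression of `G` genes in `n` genotyped samples, plus measured
#' covariates (sex, age, genotype PCs, platform, expression factors).
#'
#' @slot samples character sample ids, aligned with genotype rows.
#' @slot genes data.frame (`gene`, `chrom`, `tss`, `strand`).
#' @slot expr numeric n x G matrix of (normalized) expression.
#' @slot covariates numeric n x c matrix (may have zero columns).
#' @export
setClass("ExpressionPanel",
  representation(samples = "character", genes = "data.frame",
                 expr = "matrix", covariates = "matrix"))

setValidity("ExpressionPanel", function(object) {
  msg <- character()
  if (nrow(object@expr) != length(object@samples))
    msg <- c(msg, "expr rows must match samples")
  if (ncol(object@expr) != nrow(object@genes))
    msg <- c(msg, "expr columns must match genes")
  if (nrow(object@covariates) &&
      nrow(object@covariates) != length(object@samples))
    msg <- c(msg, "covariate rows must match samples")
  if (length(object@expr) && any(!is.finite(object@expr)))
    msg <- c(msg, "expression values must be finite")
  if (length(msg)) msg else TRUE
})

#' Gene-trait association results
#'
#' One row per gene x panel model: the TWAS Z-score, its two-tailed normal
#' p-value, the number of model SNPs actually used after harmonization, the
#' strongest GWAS SNP in the cis window, and (optionally) the adaptive
#' permutation p-value.
#'
#' @slot table data.frame with columns `gene`, `panel`, `z_twas`, `p_twas`,
#'   `n_snps_used`, `best_gwas_snp`, `best_gwas_p`, `perm_p`, `perm_n`.
#' @export
setClass("TwasResults", representation(table = "data.frame"))

setValidity("TwasResults", function(object) {
  need <- c("gene", "panel", "z_twas", "p_twas")
  if (!all(need %in% names(object@table)))
    return(paste("table must contain:", paste(need, collapse = ", ")))
  TRUE
})

#' SNP association statistics conditional on predicted expression
#'
#' @slot snps data.frame (`snp_id`, `chrom`, `pos`) in locus order.
#' @slot zMarginal,zConditional marginal and conditional Z-scores per SNP.
#' @slot genes character: gene models conditioned on (after pruning).
#' @slot pruned character: gene models removed for collinearity.
#' @slot residVar diagonal of the residual variance matrix
#'   `V - C V_GE^-1 C'`, one value per SNP.
#' @slot fullyExplained logical per SNP: residual variance below tolerance,
#'   conditional Z reported as 0.
#' @export
setClass("ConditionalResult",
  representation(snps = "data.frame", zMarginal = "numeric",
                 zConditional = "numeric", genes = "character",
                 pruned = "character", residVar = "numeric",
                 fullyExplained = "logical"))

setValidity("ConditionalResult", function(object) {
  p <- nrow(object@snps)
  if (length(object@zMarginal) != p || length(object@zConditional) != p ||
      length(object@residVar) != p || length(object@fullyExplained) != p)
    return("per-SNP slots must share the number of SNPs")
  if (p && any(object@residVar > 1 + 1e-6))
    return("residual variance diagonal cannot exceed 1")
  TRUE
})

#' Non-overlapping regions of associated gene models
#'
#' Result of greedy 1 Mb partitioning of transcriptome-wide significant
#' gene models, with optional novelty flags from [flagNovelRegions()].
#'
#' @slot regions data.frame (`region_id`, `chrom`, `start`, `end`,
#'   `n_models`, `n_genes`, and `is_novel` once flagged).
#' @slot genes data.frame of member gene models with a `region_id` column.
#' @export
setClass("RegionSet",
  representation(regions = "data.frame", genes = "data.frame"))

setValidity("RegionSet", function(object) {
  g <- object@genes
  r <- object@regions
  if (nrow(g)) {
    idx <- match(g$region_id, r$region_id)
    if (anyNA(idx)) return("every gene must map to a region")
    ok <- g$tss >= r$start[idx] & g$tss <= r$end[idx]
    if (!all(ok)) return("member gene TSS must lie inside its region")
  }
  TRUE
})

#' Credible set of putative causal genes for one region
#'
#' Per-model log Bayes factors and causal posteriors under the
#' single-causal-gene model, and the greedy rho-credible set.
#'
#' @slot regionId region identifier.
#' @slot table data.frame (`gene`, `panel`, `z_twas`, `log_bf`, `posterior`,
#'   `in_set`), ordered by descending posterior.
#' @slot rho target posterior density of the set.
#' @slot achievedDensity posterior mass actually captured (>= rho).
#' @slot members gene-model labels in the set, by descending posterior.
#' @export
setClass("CredibleSet",
  representation(regionId = "character", table = "data.frame",
                 rho = "numeric", achievedDensity = "numeric",
                 members = "character"))

setValidity("CredibleSet", function(object) {
  tab <- object@table
  if (abs(sum(tab$posterior) - 1) > 1e-9)
    return("posteriors must sum to 1 over the region")
  if (object@achievedDensity < object@rho - 1e-12)
    return("achieved density must reach rho")
  if (is.unsorted(rev(tab$posterior)))
    return("table must be ordered by descending posterior")
  TRUE
})

#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. Defaults describe the study
#' conditions the pipeline targets: an LD reference of 489 samples, an
#' expression training panel of 500, a GWAS of 142,392, 100 cis SNPs per
#' locus with AR(1) adjacent-SNP correlation 0.7, cis-heritability 0.4 from
#' 3 causal eQTL SNPs, 5 gene models per region and a causal-gene prior
#' variance with `n * sigma_a2 = 30`.
#'
#' @slot seed integer RNG seed recorded with every simulated object.
#' @slot nRef LD reference panel size.
#' @slot nPanel expression training sample size.
#' @slot nGwas GWAS sample size.
#' @slot p SNPs per simulated locus.
#' @slot rhoLd adjacent-SNP latent correlation (AR(1)).
#' @slot mafRange range minor allele frequencies are drawn from.
#' @slot h2Expr cis-heritability of simulated expression.
#' @slot kCausalSnps causal eQTL SNPs per gene.
#' @slot alphaGene effect of standardized genetic expression on the trait
#'   (per-SD units); the GWAS non-centrality is `sqrt(nGwas) * alphaGene`.
#' @slot kGenes gene models per simulated region.
#' @slot sigmaA2 prior effect-size variance of a causal gene.
#' @export
setClass("SimConfig",
  representation(seed = "numeric", nRef = "numeric", nPanel = "numeric",
                 nGwas = "numeric", p = "numeric", rhoLd = "numeric",
                 mafRange = "numeric", h2Expr = "numeric",
                 kCausalSnps = "numeric", alphaGene = "numeric",
                 kGenes = "numeric", sigmaA2 = "numeric"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@rhoLd < 0 || object@rhoLd >= 1)
    msg <- c(msg, "rhoLd must lie in [0, 1)")
  if (object@h2Expr < 0 || object@h2Expr > 1)
    msg <- c(msg, "h2Expr must lie in [0, 1]")
  if (length(object@mafRange) != 2 || object@mafRange[1] <= 0 ||
      object@mafRange[2] > 0.5 || diff(object@mafRange) < 0)
    msg <- c(msg, "mafRange must be an increasing pair in (0, 0.5]")
  if (object@kCausalSnps > object@p)
    msg <- c(msg, "kCausalSnps cannot exceed p")
  if (object@sigmaA2 < 0) msg <- c(msg, "sigmaA2 must be non-negative")
  if (length(msg)) msg else TRUE
})
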