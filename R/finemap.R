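#' Partition significant gene models into non-overlapping regions
#'
#' Greedy 1 Mb partitioning: gene models are sorted by (chromosome, TSS);
#' a region is seeded as the window of width `windowBp` centered on the
#' first unassigned gene's TSS, absorbing every gene whose TSS falls inside
#' it, and the scan repeats from the next unassigned gene. Regions are
#' non-overlapping by construction.
#'
#' @param genes data.frame of significant gene models with columns `gene`,
#'   `chrom`, `tss` (and any extra columns, e.g. `panel`, `z_twas`, carried
#'   through).
#' @param windowBp region width in base pairs (default 1e6).
#' @return A [RegionSet-class].
#' @export
partitionRegions <- function(genes, windowBp = 1e6) {
  stopifnot(all(c("gene", "chrom", "tss") %in% names(genes)))
  genes <- genes[order(.chromRank(genes$chrom), genes$tss), , drop = FALSE]
  rownames(genes) <- NULL
  half <- windowBp / 2
  genes$region_id <- NA_character_
  regions <- list()
  i <- 1L
  while (i <= nrow(genes)) {
    chrom <- genes$chrom[i]
    center <- genes$tss[i]
    rid <- sprintf("region_%s_%d", chrom, length(regions) + 1L)
    member <- which(genes$chrom == chrom & is.na(genes$region_id) &
                      genes$tss >= center - half &
                      genes$tss <= center + half)
    genes$region_id[member] <- rid
    regions[[rid]] <- data.frame(
      region_id = rid, chrom = chrom,
      start = center - half, end = center + half,
      n_models = length(member),
      n_genes = length(unique(genes$gene[member])),
      stringsAsFactors = FALSE)
    i <- which(is.na(genes$region_id))[1]
    if (is.na(i)) break
  }
  new("RegionSet", regions = do.call(rbind, c(regions,
                                              make.row.names = FALSE)),
      genes = genes)
}

#' Flag novel risk regions
#'
#' A region is novel when no genome-wide significant GWAS SNP
#' (`p < gwasAlpha`) lies within `flankBp` of any member gene's TSS: the
#' TWAS association points at a locus the GWAS itself has not yet reached.
#' Regions whose flanks contain no SNPs at all are flagged novel with a
#' warning. With several `flankBp` values the flag is re-evaluated at each
#' (robustness mode); the first value defines `is_novel` and the rest are
#' added as `is_novel_<flank>` columns.
#'
#' @param rs a [RegionSet-class].
#' @param ss a [SumStats-class] (harmonized or raw).
#' @param gwasAlpha genome-wide significance level (default 5e-8).
#' @param flankBp flank half-width(s) around member TSSs (default 1e6,
#'   i.e. 2 Mb windows).
#' @return The [RegionSet-class] with novelty columns on its region table.
#' @export
flagNovelRegions <- function(rs, ss, gwasAlpha = 5e-8, flankBp = 1e6) {
  stopifnot(is(rs, "RegionSet"), is(ss, "SumStats"))
  r <- records(ss)
  pv <- zToP(r$z)
  regions <- rs@regions
  genes <- rs@genes
  for (k in seq_along(flankBp)) {
    fb <- flankBp[k]
    novel <- logical(nrow(regions))
    for (i in seq_len(nrow(regions))) {
      member <- genes[genes$region_id == regions$region_id[i], ,
                      drop = FALSE]
      inFlank <- rep(FALSE, nrow(r))
      for (j in seq_len(nrow(member))) {
        inFlank <- inFlank | (r$chrom == member$chrom[j] &
                                abs(r$pos - member$tss[j]) <= fb)
      }
      if (!any(inFlank)) {
        warning("region ", regions$region_id[i],
                ": no GWAS SNP within ", fb, " bp of any member TSS")
        novel[i] <- TRUE
      } else {
        novel[i] <- min(pv[inFlank]) >= gwasAlpha
      }
    }
    col <- if (k == 1) "is_novel" else sprintf("is_novel_%g", fb)
    regions[[col]] <- novel
  }
  new("RegionSet", regions = regions, genes = genes)
}

#' Log Bayes factor that a gene is the causal gene at its region
#'
#' Under a normal prior with variance `sigma_a2` on the effect of
#' (standardized) genetic expression on the trait, the marginal
#' distribution of a causal gene's TWAS Z-score is `N(0, 1 + n sigma_a2)`
#' against `N(0, 1)` for a null gene, giving
#' `log BF = -log(1 + n sigma_a2)/2 + (z^2/2) * n sigma_a2/(1 + n sigma_a2)`.
#' Computed entirely in log space, so it is stable for arbitrarily large
#' `|z|`.
#'
#' @param zTwas TWAS Z-score(s).
#' @param n GWAS sample size.
#' @param sigmaA2 prior effect-size variance (per-SD expression units).
#' @return Log Bayes factor(s).
#' @export
bayesFactor <- function(zTwas, n, sigmaA2) {
  stopifnot(n >= 1, sigmaA2 >= 0)
  s <- n * sigmaA2
  -0.5 * log1p(s) + (zTwas^2 / 2) * (s / (1 + s))
}

#' Empirical-Bayes choice of the causal-effect prior
#'
#' Sets `n * sigma_a2 = max(0, mean(z^2) - 1)` over the supplied
#' (typically transcriptome-wide significant) TWAS Z-scores: the excess of
#' the mean chi-squared over its null expectation.
#'
#' @param zTwas TWAS Z-scores of significant gene models.
#' @param n GWAS sample size.
#' @return `sigma_a2` such that `n * sigma_a2` equals the excess variance.
#' @export
empiricalBayesSigmaA2 <- function(zTwas, n) {
  max(0, mean(zTwas^2) - 1) / n
}

#' Posterior probability that each gene in a region is causal
#'
#' Softmax over log Bayes factors under the single-causal-gene assumption:
#' `Pr(gene i causal) = BF_i / sum_k BF_k`. Invariant to adding a constant
#' to all log Bayes factors.
#'
#' @param logBfs numeric vector of per-gene log Bayes factors.
#' @return Posterior probabilities summing to 1.
#' @export
genePosteriors <- function(logBfs) {
  stopifnot(length(logBfs) >= 1)
  x <- logBfs - max(logBfs)
  exp(x) / sum(exp(x))
}

#' Greedy rho-credible gene set
#'
#' Orders genes by descending posterior (ties broken by label) and adds
#' genes until the cumulative posterior reaches `rho`.
#'
#' @param posteriors per-gene posterior probabilities for one region.
#' @param rho target density (default 0.90).
#' @param labels gene-model labels; defaults to names or indices.
#' @param table optional data.frame (one row per model, aligned with
#'   `posteriors`) carried onto the result, e.g. `gene`, `panel`, `z_twas`,
#'   `log_bf` columns.
#' @param regionId region identifier stored on the result.
#' @return A [CredibleSet-class].
#' @export
credibleSet <- function(posteriors, rho = 0.90, labels = NULL,
                        table = NULL, regionId = "region") {
  stopifnot(rho > 0, rho <= 1,
            abs(sum(posteriors) - 1) < 1e-6)
  posteriors <- posteriors / sum(posteriors)
  k <- length(posteriors)
  if (is.null(labels))
    labels <- names(posteriors) %||% as.character(seq_len(k))
  ord <- order(-posteriors, labels)
  cum <- cumsum(posteriors[ord])
  nIn <- which(cum >= rho - 1e-12)[1]
  if (rho == 1) nIn <- sum(posteriors[ord] > 0)
  inSet <- seq_len(k) %in% ord[seq_len(nIn)]

  if (is.null(table))
    table <- data.frame(gene = labels, panel = NA_character_,
                        stringsAsFactors = FALSE)
  table$posterior <- posteriors
  table$in_set <- inSet
  table <- table[ord, , drop = FALSE]
  rownames(table) <- NULL
  new("CredibleSet", regionId = regionId, table = table, rho = rho,
      achievedDensity = sum(posteriors[inSet]),
      members = labels[ord[seq_len(nIn)]])
}

#' Bayesian prioritization of all regions
#'
#' Computes per-model log Bayes factors from the TWAS Z-scores, posteriors
#' within each region, and the greedy rho-credible set per region.
#'
#' @param rs a [RegionSet-class] whose gene table carries `z_twas` (and
#'   optionally `panel`).
#' @param n GWAS sample size.
#' @param sigmaA2 prior effect variance; default gives `n*sigmaA2 = 30`.
#' @param rho credible-set density (default 0.90).
#' @return Named list of [CredibleSet-class] objects, one per region.
#' @export
fineMapRegions <- function(rs, n, sigmaA2 = 30 / n, rho = 0.90) {
  stopifnot(is(rs, "RegionSet"), "z_twas" %in% names(rs@genes))
  genes <- rs@genes
  out <- list()
  for (rid in rs@regions$region_id) {
    sub <- genes[genes$region_id == rid, , drop = FALSE]
    lbf <- bayesFactor(sub$z_twas, n, sigmaA2)
    post <- genePosteriors(lbf)
    panel <- if ("panel" %in% names(sub)) sub$panel else NA_character_
    labels <- paste(sub$gene, panel, sep = ":")
    tab <- data.frame(gene = sub$gene, panel = panel,
                      z_twas = sub$z_twas, log_bf = lbf,
                      stringsAsFactors = FALSE)
    out[[rid]] <- credibleSet(post, rho = rho, labels = labels,
                              table = tab, regionId = rid)
  }
  out
}

#' Summarize credible sets across regions
#'
#' Reports per-set sizes in unique genes (the same gene entering through
#' several panels counts once), their mean and median, and the number of
#' unique genes across all sets.
#'
#' @param sets list of [CredibleSet-class] objects.
#' @return List with `n_regions`, `set_sizes`, `mean_size`, `median_size`,
#'   `n_unique_genes`, and `genes` (sorted unique gene ids in any set).
#' @export
summarizeCredibleSets <- function(sets) {
  if (!length(sets)) stop("no credible sets supplied")
  perSet <- lapply(sets, function(s) {
    tab <- geneTable(s)
    unique(tab$gene[tab$in_set])
  })
  sizes <- vapply(perSet, length, integer(1))
  genes <- sort(unique(unlist(perSet)))
  list(n_regions = length(sets), set_sizes = unname(sizes),
       mean_size = mean(sizes), median_size = stats::median(sizes),
       n_unique_genes = length(genes), genes = genes)
}

#' Write per-region fine-mapping tables
#'
#' One TSV row per gene model (`gene`, `panel`, `z_twas`, `log_bf`,
#' `posterior`, `in_credible_set`, `rho`, `region_id`), plus an optional
#' region manifest.
#'
#' @param sets list of [CredibleSet-class] objects.
#' @param path output TSV for the per-model table.
#' @param rs optional [RegionSet-class]; when given, its region table is
#'   written to `manifestPath`.
#' @param manifestPath path for the region manifest TSV.
#' @return `path`, invisibly.
#' @export
writeCredibleSets <- function(sets, path, rs = NULL, manifestPath = NULL) {
  rows <- lapply(names(sets), function(rid) {
    s <- sets[[rid]]
    tab <- geneTable(s)
    data.frame(region_id = rid, tab,
               in_credible_set = tab$in_set, rho = s@rho,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$in_set <- NULL
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(rs) && !is.null(manifestPath))
    utils::write.table(regionTable(rs), manifestPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}
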