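#' Per-panel mean chi-squared summary
#'
#' For each expression panel: the mean TWAS chi-squared over its gene
#' models, a robust SD of the chi-squared values
#' (`1.4826 * median(|chi2 - median(chi2)|)`, the normal-consistent MAD),
#' and the count of models passing `alpha`. Optionally restricted to
#' significant models only.
#'
#' @param results a [TwasResults-class].
#' @param alpha significance threshold on `p_twas` used for
#'   `n_significant` (default the transcriptome-wide 4.58e-7 scale is up to
#'   the caller; default here 0.05).
#' @param significantOnly restrict the mean/MAD to significant models.
#' @return data.frame with one row per panel: `panel`, `n_models`,
#'   `mean_chi2`, `mad_sd`, `n_significant`.
#' @export
panelMeanChi2 <- function(results, alpha = 0.05, significantOnly = FALSE) {
  tab <- resultTable(results)
  out <- lapply(split(tab, tab$panel), function(d) {
    sig <- d$p_twas < alpha
    dd <- if (significantOnly) d[sig, , drop = FALSE] else d
    if (!nrow(dd)) {
      warning("panel ", d$panel[1], " has no qualifying models; skipped")
      return(NULL)
    }
    chi2 <- dd$z_twas^2
    data.frame(panel = d$panel[1], n_models = nrow(dd),
               mean_chi2 = mean(chi2),
               mad_sd = 1.4826 * stats::median(abs(chi2 -
                                                     stats::median(chi2))),
               n_significant = sum(sig), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Cross-tissue similarity of predicted expression
#'
#' Given per-panel prediction matrices on a shared cohort (samples x
#' genes; e.g. each panel's models predicted into the same reference
#' genotypes), computes the squared Pearson correlation of predictions for
#' every shared gene and panel pair, then averages per gene and per panel
#' pair. Zero-variance predictions are skipped and logged.
#'
#' @param predictions named list of numeric matrices with common rownames
#'   (samples) and gene-identified colnames.
#' @return List with `pairs` (data.frame `panel_a`, `panel_b`, `gene`,
#'   `r2`), `per_gene` and `per_panel_pair` aggregations, and `skipped`.
#' @export
crossTissueR2 <- function(predictions) {
  stopifnot(is.list(predictions), length(predictions) >= 2)
  panels <- names(predictions)
  rows <- list()
  skipped <- character()
  for (i in seq_along(panels)[-length(panels)]) {
    for (j in seq((i + 1), length(panels))) {
      shared <- intersect(colnames(predictions[[i]]),
                          colnames(predictions[[j]]))
      for (gene in shared) {
        a <- predictions[[i]][, gene]
        b <- predictions[[j]][, gene]
        if (stats::sd(a) == 0 || stats::sd(b) == 0) {
          skipped <- c(skipped,
                       sprintf("%s/%s:%s", panels[i], panels[j], gene))
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          panel_a = panels[i], panel_b = panels[j], gene = gene,
          r2 = stats::cor(a, b)^2, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) stop("no shared genes with non-degenerate predictions")
  pairs <- do.call(rbind, rows)
  perGene <- stats::aggregate(r2 ~ gene, pairs, mean)
  perPair <- stats::aggregate(r2 ~ panel_a + panel_b, pairs, mean)
  list(pairs = pairs, per_gene = perGene, per_panel_pair = perPair,
       skipped = skipped)
}

#' One-sided exact overlap enrichment test
#'
#' Builds the 2x2 table of two gene flags over a common universe and
#' computes the one-sided hypergeometric tail probability of observing at
#' least the seen overlap (enrichment direction). Accepts either two
#' logical/character sets plus a universe size, or the four counts
#' directly.
#'
#' @param setA,setB character vectors of gene ids (or logical vectors over
#'   the universe).
#' @param universe total number of genes considered.
#' @param counts optional length-4 numeric `(both, aOnly, bOnly, neither)`
#'   overriding `setA`/`setB`.
#' @return List with `table` (2x2 matrix) and `p` (one-sided exact).
#' @examples
#' overlapEnrichment(counts = c(56, 46, 161, 16126))$p  # < 2.2e-16
#' @export
overlapEnrichment <- function(setA = NULL, setB = NULL, universe = NULL,
                              counts = NULL) {
  if (is.null(counts)) {
    if (is.logical(setA)) setA <- which(setA)
    if (is.logical(setB)) setB <- which(setB)
    both <- length(intersect(setA, setB))
    aOnly <- length(setdiff(setA, setB))
    bOnly <- length(setdiff(setB, setA))
    if (is.null(universe)) stop("universe size required")
    if (universe < both + aOnly + bOnly)
      stop("universe smaller than the union of the two sets")
    neither <- universe - both - aOnly - bOnly
    counts <- c(both, aOnly, bOnly, neither)
  }
  stopifnot(length(counts) == 4, all(counts >= 0),
            all(counts == round(counts)))
  tab <- matrix(counts, 2, 2, byrow = TRUE,
                dimnames = list(c("in_a", "not_a"), c("in_b", "not_b")))
  nA <- counts[1] + counts[2]
  nB <- counts[1] + counts[3]
  N <- sum(counts)
  ## P(overlap >= observed) under the hypergeometric null
  p <- stats::phyper(counts[1] - 1, nA, N - nA, nB, lower.tail = FALSE)
  list(table = tab, p = p)
}

#' Manhattan-style plot of TWAS results
#'
#' One point per gene model at its TSS, `-log10(p_twas)` on the vertical
#' axis, with the transcriptome-wide significance line.
#'
#' @param results a [TwasResults-class].
#' @param geneInfo data.frame (`gene`, `chrom`, `tss`).
#' @param threshold significance threshold drawn as a horizontal line.
#' @return Invisibly, the plotted data.frame.
#' @export
plotManhattan <- function(results, geneInfo, threshold = 4.58e-7) {
  tab <- merge(resultTable(results), geneInfo, by = "gene")
  tab <- tab[order(.chromRank(tab$chrom), tab$tss), ]
  tab$x <- seq_len(nrow(tab))
  cols <- (.chromRank(tab$chrom) %% 2) + 1
  graphics::plot(tab$x, -log10(tab$p_twas), pch = 19, cex = 0.6,
                 col = c("grey30", "steelblue")[cols],
                 xlab = "gene models (genome order)",
                 ylab = expression(-log[10](italic(P)[TWAS])))
  graphics::abline(h = -log10(threshold), lty = 2, col = "red")
  invisible(tab)
}

#' Locus plot of marginal versus conditional SNP associations
#'
#' @param cond a [ConditionalResult-class] with SNP positions.
#' @param gwasAlpha genome-wide significance line (default 5e-8).
#' @return Invisibly, the plotted data.frame.
#' @export
plotConditionalLocus <- function(cond, gwasAlpha = 5e-8) {
  pos <- cond@snps$pos
  if (all(is.na(pos))) pos <- seq_along(cond@zMarginal)
  pm <- -log10(zToP(cond@zMarginal))
  pc <- -log10(pmax(zToP(cond@zConditional), 1e-300))
  graphics::plot(pos, pm, pch = 19, cex = 0.6, col = "grey50",
                 xlab = "position (bp)",
                 ylab = expression(-log[10](italic(P))),
                 ylim = c(0, max(pm, pc)))
  graphics::points(pos, pc, pch = 19, cex = 0.6, col = "forestgreen")
  graphics::abline(h = -log10(gwasAlpha), lty = 2, col = "grey30")
  graphics::legend("topright", legend = c("marginal", "conditional"),
                   col = c("grey50", "forestgreen"), pch = 19, bty = "n")
  invisible(data.frame(pos = pos, z_marginal = cond@zMarginal,
                       z_conditional = cond@zConditional))
}

#' Per-panel mean chi-squared bar plot with MAD whiskers
#'
#' @param summary output of [panelMeanChi2()].
#' @return Invisibly, the bar midpoints.
#' @export
plotPanelChi2 <- function(summary) {
  mids <- graphics::barplot(summary$mean_chi2, names.arg = summary$panel,
                            las = 2, ylab = "mean TWAS chi-squared",
                            ylim = c(0, max(summary$mean_chi2 +
                                              summary$mad_sd) * 1.1))
  graphics::arrows(mids, pmax(summary$mean_chi2 - summary$mad_sd, 0),
                   mids, summary$mean_chi2 + summary$mad_sd,
                   angle = 90, code = 3, length = 0.04)
  invisible(mids)
}
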