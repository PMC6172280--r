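#' Accessors for sumtwas containers
#'
#' Small accessor generics: `records()` and `qcLog()` for
#' [SumStats-class]; `dosages()`, `snpInfo()` and `sampleIds()` for
#' [GenotypeMatrix-class]; `ldMatrix()` for [LDMatrix-class];
#' `modelWeights()`, `modelSnps()` and `h2Estimate()` for
#' [GeneModel-class]; `resultTable()` for [TwasResults-class];
#' `regionTable()` and `geneTable()` for [RegionSet-class];
#' `setMembers()` for [CredibleSet-class].
#'
#' @param x an object of the documented class.
#' @return The slot contents (a data.frame, matrix or vector).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @rdname accessors
#' @export
setMethod("records", "SumStats", function(x) x@records)

#' @rdname accessors
#' @export
setGeneric("qcLog", function(x) standardGeneric("qcLog"))
#' @rdname accessors
#' @export
setMethod("qcLog", "SumStats", function(x) x@qcLog)

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) x@dosages)

#' @rdname accessors
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))
#' @rdname accessors
#' @export
setMethod("snpInfo", "GenotypeMatrix", function(x) x@snps)
#' @rdname accessors
#' @export
setMethod("snpInfo", "LDMatrix", function(x) x@snps)

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) x@samples)

#' @rdname accessors
#' @export
setGeneric("ldMatrix", function(x) standardGeneric("ldMatrix"))
#' @rdname accessors
#' @export
setMethod("ldMatrix", "LDMatrix", function(x) x@V)

#' @rdname accessors
#' @export
setGeneric("modelWeights", function(x) standardGeneric("modelWeights"))
#' @rdname accessors
#' @export
setMethod("modelWeights", "GeneModel", function(x) {
  stats::setNames(x@weights, x@snps$snp_id)
})

#' @rdname accessors
#' @export
setGeneric("modelSnps", function(x) standardGeneric("modelSnps"))
#' @rdname accessors
#' @export
setMethod("modelSnps", "GeneModel", function(x) x@snps)

#' @rdname accessors
#' @export
setGeneric("h2Estimate", function(x) standardGeneric("h2Estimate"))
#' @rdname accessors
#' @export
setMethod("h2Estimate", "GeneModel", function(x) x@h2)

#' @rdname accessors
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))
#' @rdname accessors
#' @export
setMethod("resultTable", "TwasResults", function(x) x@table)

#' @rdname accessors
#' @export
setGeneric("regionTable", function(x) standardGeneric("regionTable"))
#' @rdname accessors
#' @export
setMethod("regionTable", "RegionSet", function(x) x@regions)

#' @rdname accessors
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))
#' @rdname accessors
#' @export
setMethod("geneTable", "RegionSet", function(x) x@genes)
#' @rdname accessors
#' @export
setMethod("geneTable", "CredibleSet", function(x) x@table)

#' @rdname accessors
#' @export
setGeneric("setMembers", function(x) standardGeneric("setMembers"))
#' @rdname accessors
#' @export
setMethod("setMembers", "CredibleSet", function(x) x@members)

setMethod("show", "SumStats", function(object) {
  cat("SumStats with", nrow(object@records), "records\n")
  if (nrow(object@records)) {
    cat("  chromosomes:",
        paste(unique(object@records$chrom), collapse = ", "), "\n")
  }
  if (nrow(object@qcLog)) {
    cat("  QC log:\n")
    for (i in seq_len(nrow(object@qcLog)))
      cat("   -", object@qcLog$rule[i], ":",
          object@qcLog$n_removed[i], "removed\n")
  }
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@dosages), "samples x",
      ncol(object@dosages), "SNPs\n")
})

setMethod("show", "LDMatrix", function(object) {
  cat("LDMatrix over", nrow(object@V), "SNPs (ridge =", object@ridge, ")\n")
})

setMethod("show", "H2Estimate", function(object) {
  cat(sprintf("H2Estimate: h2 = %.3f (sigma_g2 = %.3f, sigma_e2 = %.3f), P = %.3g%s\n",
              object@h2, object@sigmaG2, object@sigmaE2, object@pValue,
              if (object@converged) "" else " [not converged]"))
})

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel %s [%s]: %s, %d SNPs (%d nonzero), cv R2 = %.3f (P = %.3g), h2 = %.3f\n",
              object@gene, object@panel, object@modelLabel,
              length(object@weights), sum(object@weights != 0),
              object@cvR2, object@cvP, object@h2@h2))
})

setMethod("show", "TwasResults", function(object) {
  tab <- object@table
  cat("TwasResults:", nrow(tab), "gene models\n")
  if (nrow(tab))
    cat(sprintf("  |z| range %.2f .. %.2f; min P = %.3g\n",
                min(abs(tab$z_twas)), max(abs(tab$z_twas)), min(tab$p_twas)))
})

setMethod("show", "ConditionalResult", function(object) {
  cat("ConditionalResult:", nrow(object@snps), "SNPs conditioned on",
      length(object@genes), "gene model(s)\n")
  if (length(object@pruned))
    cat("  pruned for collinearity:",
        paste(object@pruned, collapse = ", "), "\n")
})

setMethod("show", "RegionSet", function(object) {
  cat("RegionSet:", nrow(object@regions), "regions,",
      nrow(object@genes), "gene models\n")
  if ("is_novel" %in% names(object@regions))
    cat("  novel regions:", sum(object@regions$is_novel), "\n")
})

setMethod("show", "CredibleSet", function(object) {
  cat(sprintf("CredibleSet %s: rho = %.2f, %d member(s), density %.3f\n",
              object@regionId, object@rho, length(object@members),
              object@achievedDensity))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0("SimConfig: seed %d | nRef %d, nPanel %d, nGwas %d | ",
                     "p %d SNPs, AR(1) rho %.2f, maf [%.2f, %.2f] | ",
                     "h2 %.2f (%d causal), alpha %.3g | %d genes/region, ",
                     "n*sigma_a2 = %.1f\n"),
              object@seed, object@nRef, object@nPanel, object@nGwas,
              object@p, object@rhoLd, object@mafRange[1], object@mafRange[2],
              object@h2Expr, object@kCausalSnps, object@alphaGene,
              object@kGenes, object@nGwas * object@sigmaA2))
})
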