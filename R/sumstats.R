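#' Construct a SumStats object from a data.frame
#'
#' Validates, sorts by (chromosome, position) and wraps per-SNP association
#' records. Mostly used internally; end users typically start from
#' [loadSumstats()] or [simulateGwasSumstats()].
#'
#' @param records data.frame with columns `snp_id`, `chrom`, `pos`, `a1`,
#'   `a2`, `z`, `maf`, `n`.
#' @param qcLog optional provenance log to carry over.
#' @return A [SumStats-class] object.
#' @export
SumStats <- function(records, qcLog = NULL) {
  records$chrom <- as.character(records$chrom)
  records$snp_id <- as.character(records$snp_id)
  records$a1 <- toupper(as.character(records$a1))
  records$a2 <- toupper(as.character(records$a2))
  records <- .sortRecords(records)[, .SUMSTAT_COLS]
  rownames(records) <- NULL
  if (is.null(qcLog))
    qcLog <- data.frame(rule = character(), n_removed = integer(),
                        stringsAsFactors = FALSE)
  new("SumStats", records = records, qcLog = qcLog)
}

.DEFAULT_COLUMN_MAP <- c(snp_id = "SNP", chrom = "CHR", pos = "BP",
                         a1 = "A1", a2 = "A2", z = "Z", maf = "MAF",
                         n = "N", beta = "BETA", se = "SE")

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a whitespace- or tab-delimited summary-statistics file with a
#' header. Column names are resolved through `columnMap`; when no Z column
#' is present but beta and SE are, `z = beta / se` is computed. Rows with
#' missing or non-finite required values are dropped and counted in the QC
#' log rather than raising an error.
#'
#' @param path path to the file.
#' @param columnMap named character vector mapping internal field names
#'   (`snp_id`, `chrom`, `pos`, `a1`, `a2`, `z`, `maf`, `n`, and optionally
#'   `beta`, `se`) to the column names in the file. Only the fields you name
#'   override the defaults (`SNP`, `CHR`, `BP`, `A1`, `A2`, `Z`, `MAF`, `N`,
#'   `BETA`, `SE`).
#' @return A [SumStats-class] object; the QC log records malformed rows.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("SNP\tCHR\tBP\tA1\tA2\tZ\tMAF\tN",
#'              "rs1\t1\t100\tA\tG\t1.5\t0.2\t1000"), f)
#' ss <- loadSumstats(f)
#' records(ss)
#' @export
loadSumstats <- function(path, columnMap = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  cmap <- .DEFAULT_COLUMN_MAP
  cmap[names(columnMap)] <- columnMap
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          showProgress = FALSE)
  required <- c("snp_id", "chrom", "pos", "a1", "a2", "maf", "n")
  missing <- required[!cmap[required] %in% names(dt)]
  if (length(missing))
    stop("required column(s) not found in ", path, ": ",
         paste(cmap[missing], collapse = ", "),
         " (adjust columnMap)")
  hasZ <- cmap["z"] %in% names(dt)
  hasBetaSe <- all(cmap[c("beta", "se")] %in% names(dt))
  if (!hasZ && !hasBetaSe)
    stop("need either a Z column or both beta and SE columns")

  out <- data.frame(
    snp_id = as.character(dt[[cmap["snp_id"]]]),
    chrom = as.character(dt[[cmap["chrom"]]]),
    pos = as.integer(dt[[cmap["pos"]]]),
    a1 = toupper(as.character(dt[[cmap["a1"]]])),
    a2 = toupper(as.character(dt[[cmap["a2"]]])),
    z = if (hasZ) as.numeric(dt[[cmap["z"]]])
        else as.numeric(dt[[cmap["beta"]]]) / as.numeric(dt[[cmap["se"]]]),
    maf = as.numeric(dt[[cmap["maf"]]]),
    n = as.numeric(dt[[cmap["n"]]]),
    stringsAsFactors = FALSE
  )
  ## an allele-frequency column may exceed 0.5; fold onto the minor allele
  out$maf <- pmin(out$maf, 1 - out$maf)

  ok <- !is.na(out$snp_id) & !is.na(out$chrom) & !is.na(out$pos) &
    out$a1 %in% .VALID_ALLELES & out$a2 %in% .VALID_ALLELES &
    out$a1 != out$a2 & is.finite(out$z) &
    is.finite(out$maf) & out$maf >= 0 & out$maf <= 0.5 & is.finite(out$n)
  log <- data.frame(rule = "malformed_row",
                    n_removed = as.integer(sum(!ok)),
                    stringsAsFactors = FALSE)
  out <- out[ok, , drop = FALSE]
  dup <- out$snp_id[duplicated(out$snp_id)]
  if (length(dup))
    stop("duplicated snp_id in ", path, ": ", dup[1])
  SumStats(out, qcLog = log)
}

#' Quality-filter GWAS summary statistics
#'
#' Applies the standard summary-statistic filters: drops SNPs with minor
#' allele frequency below `mafMin`, strand-ambiguous variants (A/T and C/G
#' pairs, whose strand cannot be resolved from allele labels), and, when
#' `rsidRequired`, identifiers not matching `rs[0-9]+`. Each rule's removal
#' count is appended to the QC log. The operation is idempotent.
#'
#' @param ss a [SumStats-class] object.
#' @param mafMin minimum minor allele frequency (default 0.01).
#' @param rsidRequired drop SNPs whose id is not an rsID (default TRUE).
#' @return The filtered [SumStats-class]; errors if nothing survives.
#' @export
qcSumstats <- function(ss, mafMin = 0.01, rsidRequired = TRUE) {
  stopifnot(is(ss, "SumStats"))
  r <- records(ss)
  log <- qcLog(ss)

  low <- r$maf < mafMin
  log <- .logRule(log, sprintf("maf_below_%g", mafMin), sum(low))
  r <- r[!low, , drop = FALSE]

  amb <- .isAmbiguousPair(r$a1, r$a2)
  log <- .logRule(log, "strand_ambiguous", sum(amb))
  r <- r[!amb, , drop = FALSE]

  if (rsidRequired) {
    bad <- !grepl("^rs[0-9]+$", r$snp_id)
    log <- .logRule(log, "non_rsid", sum(bad))
    r <- r[!bad, , drop = FALSE]
  }

  if (!nrow(r)) {
    breakdown <- paste(sprintf("%s: %d", log$rule, log$n_removed),
                       collapse = "; ")
    stop("no summary statistics survive QC (", breakdown, ")")
  }
  SumStats(r, qcLog = log)
}

#' Harmonize summary-statistic alleles against an LD reference
#'
#' Intersects records with a reference SNP table (typically a PLINK bim) on
#' rsID and puts Z-scores on the reference allele frame: where the effect
#' and other alleles are swapped relative to the reference, the sign of `z`
#' is flipped; strand flips are resolved by complementing both alleles
#' before matching (safe once strand-ambiguous pairs have been removed by
#' [qcSumstats()]). Records whose allele set cannot be reconciled are
#' dropped and logged. Output rows follow the reference order.
#'
#' @param ss a [SumStats-class] object.
#' @param bim data.frame with columns `snp_id`, `a1`, `a2` (e.g.
#'   `snpInfo(g)` from [loadGenotypes()]).
#' @return A [SumStats-class] aligned to the reference allele frame.
#' @export
harmonizeAlleles <- function(ss, bim) {
  stopifnot(is(ss, "SumStats"),
            all(c("snp_id", "a1", "a2") %in% names(bim)))
  r <- records(ss)
  idx <- match(bim$snp_id, r$snp_id)
  keepRef <- which(!is.na(idx))
  if (!length(keepRef))
    stop("no overlap between summary statistics and reference SNPs")
  r <- r[idx[keepRef], , drop = FALSE]
  refA1 <- toupper(bim$a1[keepRef])
  refA2 <- toupper(bim$a2[keepRef])

  same <- r$a1 == refA1 & r$a2 == refA2
  swap <- r$a1 == refA2 & r$a2 == refA1
  c1 <- .complementAllele(r$a1)
  c2 <- .complementAllele(r$a2)
  flipSame <- !same & !swap & c1 == refA1 & c2 == refA2
  flipSwap <- !same & !swap & c1 == refA2 & c2 == refA1

  sign <- rep(NA_real_, nrow(r))
  sign[same | flipSame] <- 1
  sign[swap | flipSwap] <- -1

  nDropped <- sum(is.na(sign)) + (nrow(records(ss)) - nrow(r))
  keep <- !is.na(sign)
  out <- r[keep, , drop = FALSE]
  out$z <- out$z * sign[keep]
  out$a1 <- refA1[keep]
  out$a2 <- refA2[keep]
  log <- .logRule(qcLog(ss), "not_in_reference_or_mismatched", nDropped)
  if (!nrow(out)) stop("no records left after allele harmonization")
  SumStats(out, qcLog = log)
}

#' Write summary statistics (and their QC log) to TSV
#'
#' Emits the same tab-delimited layout [loadSumstats()] reads
#' (`SNP CHR BP A1 A2 Z MAF N`), so outputs round-trip. When `logPath` is
#' given, the QC provenance log is written alongside as a two-column TSV.
#'
#' @param ss a [SumStats-class] object.
#' @param path output file.
#' @param logPath optional path for the QC log TSV (`rule`, `n_removed`).
#' @return `path`, invisibly.
#' @export
writeSumstats <- function(ss, path, logPath = NULL) {
  r <- records(ss)
  names(r) <- c("SNP", "CHR", "BP", "A1", "A2", "Z", "MAF", "N")
  utils::write.table(r, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(logPath))
    utils::write.table(qcLog(ss), logPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}
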