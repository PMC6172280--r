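## Minimal PLINK 1 binary fileset I/O (bed v1.00, SNP-major).
##
## bed encoding, two bits per genotype, samples packed four to a byte,
## least-significant pair first:
##   00 = homozygous A1 (dosage 2 of A1), 10 = heterozygous (1),
##   11 = homozygous A2 (0), 01 = missing.

.BED_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))

.readBim <- function(path) {
  bim <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos",
                                         "a1", "a2"),
                           colClasses = c("character", "character",
                                          "numeric", "integer",
                                          "character", "character"))
  bim
}

.readFam <- function(path) {
  utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("fid", "iid", "pat", "mat", "sex",
                                  "pheno"))
}

## Decode one SNP-major record of ceiling(n/4) bytes into n dosages of A1.
.decodeBedRecord <- function(bytes, n) {
  bits <- rawToBits(bytes)
  lo <- as.integer(bits[seq(1, 2 * n, by = 2)])
  hi <- as.integer(bits[seq(2, 2 * n, by = 2)])
  code <- lo + 2L * hi          # 0, 1 (missing), 2, 3
  dos <- c(2, NA, 1, 0)[code + 1L]
  dos
}

#' Load a region of reference genotypes from a PLINK fileset
#'
#' Reads the bed/bim/fam triple at `prefix`, keeps SNPs inside the closed
#' base-pair interval, mean-imputes missing genotypes per SNP, and applies
#' a minor-allele-frequency floor so no constant column reaches LD
#' estimation. Dosages count copies of the bim A1 allele.
#'
#' @param prefix path prefix of the fileset (without extension).
#' @param region either `NULL` (all SNPs), a string `"chr:start-end"`, or a
#'   list/vector `(chrom, start, end)`. Positions are 1-based and the
#'   interval is closed.
#' @param mafMin minor-allele-frequency floor (default 0.01), mirroring
#'   summary-statistic QC so both operate on the same SNP universe.
#' @return A [GenotypeMatrix-class].
#' @seealso [writePlink()], [computeLD()]
#' @export
loadGenotypes <- function(prefix, region = NULL, mafMin = 0.01) {
  bedPath <- paste0(prefix, ".bed")
  bimPath <- paste0(prefix, ".bim")
  famPath <- paste0(prefix, ".fam")
  if (!all(file.exists(bedPath, bimPath, famPath)))
    stop("PLINK fileset not found at prefix: ", prefix)
  bim <- .readBim(bimPath)
  fam <- .readFam(famPath)
  n <- nrow(fam)
  p <- nrow(bim)

  keep <- seq_len(p)
  if (!is.null(region)) {
    if (is.character(region) && length(region) == 1) {
      m <- regmatches(region,
                      regexec("^(.+):([0-9]+)-([0-9]+)$", region))[[1]]
      if (length(m) != 4) stop("malformed region string: ", region)
      region <- list(m[2], as.integer(m[3]), as.integer(m[4]))
    }
    chrom <- as.character(region[[1]])
    start <- as.numeric(region[[2]])
    end <- as.numeric(region[[3]])
    keep <- which(bim$chrom == sub("^chr", "", chrom) |
                    bim$chrom == chrom)
    keep <- keep[bim$pos[keep] >= start & bim$pos[keep] <= end]
    if (!length(keep))
      stop("no SNPs in region ", chrom, ":", start, "-", end)
  }

  con <- file(bedPath, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(magic, .BED_MAGIC))
    stop("not a SNP-major PLINK v1.00 bed file: ", bedPath)
  bytesPerSnp <- ceiling(n / 4)
  X <- matrix(NA_real_, n, length(keep))
  for (j in seq_along(keep)) {
    seek(con, 3 + (keep[j] - 1) * bytesPerSnp)
    X[, j] <- .decodeBedRecord(readBin(con, "raw", bytesPerSnp), n)
  }

  ## mean-impute missing calls per SNP
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- mean(X[!miss, j])
  }

  snps <- bim[keep, c("snp_id", "chrom", "pos", "a1", "a2")]
  freq <- colMeans(X) / 2
  snps$maf <- pmin(freq, 1 - freq)
  ok <- snps$maf >= mafMin
  if (!any(ok))
    stop("no SNPs pass the MAF floor of ", mafMin, " in the region")
  X <- X[, ok, drop = FALSE]
  snps <- snps[ok, , drop = FALSE]
  rownames(snps) <- NULL
  colnames(X) <- snps$snp_id
  samples <- fam$iid
  rownames(X) <- samples
  new("GenotypeMatrix", dosages = X, snps = snps, samples = samples)
}

#' Write a GenotypeMatrix as a PLINK bed/bim/fam fileset
#'
#' Dosages are rounded to `{0, 1, 2}` copies of A1 for encoding; `NA`
#' dosages become missing calls. Used by the synthetic-data module so that
#' simulated genotypes exercise the same binary I/O path as real panels.
#'
#' @param g a [GenotypeMatrix-class].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
writePlink <- function(g, prefix) {
  stopifnot(is(g, "GenotypeMatrix"))
  X <- dosages(g)
  snps <- snpInfo(g)
  n <- nrow(X)

  fam <- data.frame(fid = g@samples, iid = g@samples, pat = 0, mat = 0,
                    sex = 0, pheno = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chrom = snps$chrom, snp_id = snps$snp_id, cm = 0,
                    pos = snps$pos, a1 = snps$a1, a2 = snps$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.BED_MAGIC, con)
  codeFor <- function(d) {
    ## dosage of A1 -> 2-bit code (as two logical bits, lsb first)
    if (is.na(d)) c(TRUE, FALSE)        # 01 missing
    else if (d >= 1.5) c(FALSE, FALSE)  # 00 hom A1
    else if (d >= 0.5) c(FALSE, TRUE)   # 10 het
    else c(TRUE, TRUE)                  # 11 hom A2
  }
  padTo <- 4 * ceiling(n / 4)
  for (j in seq_len(ncol(X))) {
    bits <- logical(2 * padTo)
    for (i in seq_len(n)) {
      bits[(2 * i - 1):(2 * i)] <- codeFor(X[i, j])
    }
    ## pad slots beyond n encode hom A2 (11)? PLINK pads with zero bits.
    if (padTo > n) bits[(2 * n + 1):(2 * padTo)] <- FALSE
    writeBin(packBits(bits, "raw"), con)
  }
  invisible(prefix)
}

#' Compute a regularized LD (SNP correlation) matrix
#'
#' Pearson correlation of dosage columns, shrunk towards the identity:
#' `V = (1 - ridge) * cor(X) + ridge * I`. The ridge keeps `V` positive
#' definite so TWAS denominators and conditional-analysis inversions are
#' finite even when the locus is rank-deficient in the reference panel;
#' the weight applied is recorded on the result.
#'
#' @param g a [GenotypeMatrix-class] with at least two samples.
#' @param ridge regularization weight in `[0, 1)` (default 0.1).
#' @return An [LDMatrix-class].
#' @export
computeLD <- function(g, ridge = 0.1) {
  stopifnot(is(g, "GenotypeMatrix"), ridge >= 0, ridge < 1)
  X <- dosages(g)
  if (nrow(X) < 2) stop("need at least two samples to estimate LD")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant genotype column: ",
         paste(snpInfo(g)$snp_id[sds == 0], collapse = ", "))
  V <- stats::cor(X)
  V <- (1 - ridge) * V + ridge * diag(ncol(X))
  dimnames(V) <- list(snpInfo(g)$snp_id, snpInfo(g)$snp_id)
  new("LDMatrix", V = V, snps = snpInfo(g)$snp_id, ridge = ridge)
}
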