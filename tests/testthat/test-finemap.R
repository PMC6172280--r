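sigGenes <- function(tss, chrom = "1", gene = NULL, z = 6) {
  data.frame(gene = gene %||% sprintf("g%d", seq_along(tss)),
             chrom = chrom, tss = tss, panel = "panelA", z_twas = z,
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("greedy partitioning merges nearby genes and splits far ones", {
  rs <- partitionRegions(sigGenes(c(1.0e6, 1.4e6)))
  expect_equal(nrow(regionTable(rs)), 1)
  expect_equal(regionTable(rs)$n_models, 2)

  rs2 <- partitionRegions(sigGenes(c(1.0e6, 3.0e6)))
  expect_equal(nrow(regionTable(rs2)), 2)

  rs3 <- partitionRegions(sigGenes(5e6))
  expect_equal(nrow(regionTable(rs3)), 1)
  expect_equal(geneTable(rs3)$region_id,
               regionTable(rs3)$region_id)
  ## regions have the configured width and do not overlap
  tab <- regionTable(rs2)
  expect_true(all(tab$end - tab$start == 1e6))
})

test_that("same-gene models across panels count once in n_genes", {
  genes <- rbind(sigGenes(1.0e6, gene = "GENE1"),
                 sigGenes(1.1e6, gene = "GENE1"),
                 sigGenes(1.2e6, gene = "GENE2"))
  rs <- partitionRegions(genes)
  expect_equal(regionTable(rs)$n_models, 3)
  expect_equal(regionTable(rs)$n_genes, 2)
})

test_that("novel regions are those without a genome-wide significant SNP", {
  mkSS <- function(pos, z) {
    SumStats(data.frame(snp_id = sprintf("rs%d", seq_along(pos)),
                        chrom = "1", pos = pos, a1 = "A", a2 = "G",
                        z = z, maf = 0.2, n = 1e5))
  }
  rs <- partitionRegions(sigGenes(10e6))

  ## a genome-wide significant SNP 0.5 Mb from the TSS: not novel
  ss <- mkSS(c(9.5e6, 10.2e6), c(pToZ(1e-9), 2))
  flagged <- flagNovelRegions(rs, ss)
  expect_false(regionTable(flagged)$is_novel)

  ## best flank SNP at P = 1.49e-5: well short of 5e-8, so novel
  ss2 <- mkSS(c(9.8e6, 10.3e6), c(pToZ(1.49e-5), 1))
  expect_true(regionTable(flagNovelRegions(rs, ss2))$is_novel)

  ## no SNPs in the flank at all: novel, with a warning
  ss3 <- mkSS(90e6, 3)
  expect_warning(out <- flagNovelRegions(rs, ss3), "no GWAS SNP")
  expect_true(regionTable(out)$is_novel)

  ## robustness mode re-evaluates at wider flanks
  multi <- suppressWarnings(
    flagNovelRegions(rs, ss, flankBp = c(1e6, 2e6)))
  expect_true("is_novel_2e+06" %in% names(regionTable(multi)))
})

test_that("log Bayes factors match the closed form", {
  ## z = 0: logBF = -log(1+s)/2
  expect_equal(bayesFactor(0, 100, 0.5), -0.5 * log(51))
  ## null prior: BF = 1 regardless of z
  expect_equal(bayesFactor(c(0, 3, 40), 1000, 0), rep(0, 3))
  ## z = 5, n*sigma_a2 = 100
  expect_equal(bayesFactor(5, 100, 1),
               -0.5 * log(101) + 12.5 * (100 / 101))
  expect_equal(round(bayesFactor(5, 100, 1), 4), 10.0687)
  ## log-space stability at |z| ~ 40
  expect_true(is.finite(bayesFactor(40, 142392, 30 / 142392)))
})

test_that("posteriors are a softmax over log Bayes factors", {
  expect_equal(genePosteriors(rep(2.7, 4)), rep(0.25, 4))
  post <- genePosteriors(c(20, 0, 0))
  expect_gt(post[1], 0.999)
  expect_equal(genePosteriors(c(2, 1, 0)),
               exp(c(2, 1, 0)) / sum(exp(c(2, 1, 0))))
  ## invariant to adding a constant
  lbf <- c(3.2, -1, 0.5, 2)
  expect_equal(genePosteriors(lbf), genePosteriors(lbf + 57))
  ## numerically safe far from zero
  expect_equal(genePosteriors(lbf + 5000), genePosteriors(lbf))
})

test_that("greedy credible sets stop at the target density", {
  cs <- credibleSet(c(0.94, 0.03, 0.02, 0.01), rho = 0.9,
                    labels = c("MLPH-like", "b", "c", "d"))
  expect_equal(setMembers(cs), "MLPH-like")
  expect_equal(cs@achievedDensity, 0.94)

  cs2 <- credibleSet(c(0.5, 0.3, 0.15, 0.05), rho = 0.9,
                     labels = letters[1:4])
  expect_equal(setMembers(cs2), c("a", "b", "c"))
  expect_equal(cs2@achievedDensity, 0.95)

  ## rho = 1 takes every gene with positive posterior
  cs3 <- credibleSet(c(0.6, 0.4, 0), rho = 1, labels = letters[1:3])
  expect_setequal(setMembers(cs3), c("a", "b"))

  ## deterministic tie-break by label
  cs4 <- credibleSet(c(0.5, 0.5), rho = 0.4, labels = c("zzz", "aaa"))
  expect_equal(setMembers(cs4), "aaa")
})

test_that("set size shrinks as the lead posterior grows", {
  sizes <- vapply(c(0.3, 0.5, 0.7, 0.95), function(lead) {
    rest <- (1 - lead) * rep(1 / 4, 4)
    length(setMembers(credibleSet(c(lead, rest), rho = 0.9,
                                  labels = letters[1:5])))
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("credible-set summaries collapse panels to unique genes", {
  mkSet <- function(genes, panels, post, rid) {
    tab <- data.frame(gene = genes, panel = panels, stringsAsFactors = FALSE)
    credibleSet(post, rho = 0.9, labels = paste(genes, panels, sep = ":"),
                table = tab, regionId = rid)
  }
  s1 <- mkSet("A", "p1", 1, "r1")
  s2 <- mkSet(c("A", "B"), c("p1", "p1"), c(0.55, 0.45), "r2")
  out <- summarizeCredibleSets(list(r1 = s1, r2 = s2))
  expect_equal(out$n_unique_genes, 2)
  expect_equal(out$set_sizes, c(1, 2))
  expect_equal(out$mean_size, 1.5)
  expect_equal(out$median_size, 1.5)

  ## the same gene via two panels is one unique gene
  s3 <- mkSet(c("A", "A"), c("p1", "p2"), c(0.5, 0.5), "r3")
  out3 <- summarizeCredibleSets(list(r3 = s3))
  expect_equal(out3$set_sizes, 1)
  expect_equal(out3$n_unique_genes, 1)
  expect_error(summarizeCredibleSets(list()), "no credible sets")
})

test_that("region-level fine-mapping ties the pieces together", {
  genes <- sigGenes(c(1.0e6, 1.2e6, 5e6), z = c(7, 3, 6))
  rs <- partitionRegions(genes)
  sets <- fineMapRegions(rs, n = 142392, rho = 0.9)
  expect_length(sets, 2)
  first <- sets[[1]]
  expect_equal(sum(geneTable(first)$posterior), 1)
  ## the z = 7 gene dominates its region
  expect_equal(geneTable(first)$gene[1], "g1")
  expect_true("g1:panelA" %in% setMembers(first))
  ## writing out works and round-trips numerically
  f <- tempfile(fileext = ".tsv")
  writeCredibleSets(sets, f, rs = rs,
                    manifestPath = tempfile(fileext = ".tsv"))
  back <- read.delim(f)
  expect_equal(sum(back$posterior), 2, tolerance = 1e-12)
})
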