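# two homeologous loci with identical exon geometry on different chromosomes
homeologAnnotation <- function() {
  ex <- GenomicRanges::GRangesList(
    tA = GenomicRanges::GRanges("chrA",
      IRanges::IRanges(c(1000, 2000), c(1499, 2999)), "+"),
    tB = GenomicRanges::GRanges("chrB",
      IRanges::IRanges(c(1000, 2000), c(1499, 2999)), "+"),
    tX = GenomicRanges::GRanges("chrC",
      IRanges::IRanges(1000, 2999), "+"))
  GeneAnnotation(ex, geneIds = c(tA = "gA", tB = "gB", tX = "gX"))
}
homeologGroups <- function() data.frame(group_id = "HG001",
  gene_id = c("gA", "gB"), stringsAsFactors = FALSE)

test_that("reads hitting several members of one group are flagged", {
  ann <- homeologAnnotation()
  aln <- mkAlignments(
    list(read_id = "both", chrom = "chrA", strand = "+", starts = c(1000, 2000),
      ends = c(1499, 2999)),
    list(read_id = "both", chrom = "chrB", strand = "+", starts = c(1000, 2000),
      ends = c(1499, 2950), read_length = 1500, is_primary = FALSE),
    list(read_id = "crossgroup", chrom = "chrA", strand = "+",
      starts = c(1000, 2000), ends = c(1499, 2999)),
    list(read_id = "crossgroup", chrom = "chrC", strand = "+", starts = 1000,
      ends = 2999, is_primary = FALSE),
    list(read_id = "single", chrom = "chrA", strand = "+", starts = 1000,
      ends = 1499))
  flags <- flagHomeologHits(aln, ann, homeologGroups())
  got <- setNames(flags$multi_homeolog, flags$read_id)
  expect_true(got[["both"]])
  # gX is not a group member: hitting gA + gX is generic multi-mapping
  expect_false(got[["crossgroup"]])
  expect_false(got[["single"]])
})

test_that("best-match resolution minimizes unaligned read bases", {
  ann <- homeologAnnotation()
  # read of 2000 bases: d = 10 at the true locus vs 100 at the sister
  aln <- mkAlignments(
    list(read_id = "r", chrom = "chrA", strand = "+", starts = c(1000, 2000),
      ends = c(1499, 2489), read_length = 2000, aln_length = 1990,
      identity = 0.99),
    list(read_id = "r", chrom = "chrB", strand = "+", starts = c(1000, 2000),
      ends = c(1499, 2399), read_length = 2000, aln_length = 1900,
      identity = 0.97, is_primary = FALSE))
  res <- resolveBestMatch(aln, ann)
  expect_equal(res$status, "resolved")
  expect_equal(res$gene_id, "gA")
  expect_equal(res$best_d, 10L)

  # equal d at both loci: ambiguous, never guessed
  tie <- mkAlignments(
    list(read_id = "t", chrom = "chrA", strand = "+", starts = c(1000, 2000),
      ends = c(1499, 2489), read_length = 2000, aln_length = 1990),
    list(read_id = "t", chrom = "chrB", strand = "+", starts = c(1000, 2000),
      ends = c(1499, 2489), read_length = 2000, aln_length = 1990,
      is_primary = FALSE))
  expect_equal(resolveBestMatch(tie, ann)$status, "ambiguous")

  # all hits below the identity threshold: filtered out entirely
  low <- mkAlignments(
    list(read_id = "l", chrom = "chrA", strand = "+", starts = 1000,
      ends = 10999, read_length = 10000, aln_length = 10000, identity = 0.89),
    list(read_id = "l", chrom = "chrB", strand = "+", starts = 1000,
      ends = 10999, read_length = 10000, aln_length = 10000, identity = 0.88,
      is_primary = FALSE))
  expect_equal(resolveBestMatch(low, ann)$status, "filtered")
})

test_that("resolution is invariant to the order of a read's records", {
  ann <- homeologAnnotation()
  recs <- list(
    list(read_id = "r", chrom = "chrA", strand = "+", starts = c(1000, 2000),
      ends = c(1499, 2489), read_length = 2000, aln_length = 1990),
    list(read_id = "r", chrom = "chrB", strand = "+", starts = c(1000, 2000),
      ends = c(1499, 2399), read_length = 2000, aln_length = 1900,
      is_primary = FALSE))
  r1 <- resolveBestMatch(do.call(mkAlignments, recs), ann)
  r2 <- resolveBestMatch(do.call(mkAlignments, rev(recs)), ann)
  expect_equal(r1, r2)
})

test_that("simulated homeolog reads resolve to their true locus", {
  cfg <- simConfig(n_genes = 12, n_homeolog_triplets = 6, p_homeolog_multi = 1,
    n_reads_per_protocol = 300, seed = 17)
  sim <- simulateExperiment(cfg)
  lib <- sim$libraries$template_switch
  flags <- flagHomeologHits(lib$alignments, sim$annotation, sim$homeologs)
  multi <- flags$read_id[flags$multi_homeolog]
  expect_gt(length(multi), 100)
  sel <- alignmentInfo(lib$alignments)$read_id %in% multi
  res <- resolveBestMatch(lib$alignments[sel], sim$annotation)
  # the true locus always has strictly minimal d in this simulation
  expect_true(all(res$status == "resolved"))
  tr <- lib$truth[match(res$read_id, lib$truth$read_id), ]
  expect_equal(res$gene_id, tr$gene_id)
  # resolution can only shrink the ambiguous set relative to no resolution
  expect_lte(sum(res$status == "ambiguous") / nrow(res), 1)
})
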