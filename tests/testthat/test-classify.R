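test_that("identity filter boundary is inclusive at the threshold", {
  aln <- mkAlignments(
    list(read_id = "a", chrom = "chr1", strand = "+", starts = 1000, ends = 1999,
      identity = 0.90),
    list(read_id = "b", chrom = "chr1", strand = "+", starts = 1000, ends = 10999,
      aln_length = 10000, read_length = 10000, identity = 0.8999),
    list(read_id = "c", chrom = "chr1", strand = "+", starts = 1000, ends = 1999,
      identity = 1))
  fl <- filterIdentity(aln)
  expect_setequal(alignmentInfo(fl$kept)$read_id, c("a", "c"))
  expect_equal(alignmentInfo(fl$rejected)$read_id, "b")
  # empty input passes through
  fe <- filterIdentity(aln[integer(0)])
  expect_equal(length(fe$kept), 0L)
  expect_equal(length(fe$rejected), 0L)
})

test_that("multiplicity partition composes with the identity filter", {
  aln <- mkAlignments(
    list(read_id = "multi", chrom = "chr1", strand = "+", starts = 1000,
      ends = 1999, identity = 0.95),
    list(read_id = "multi", chrom = "chr2", strand = "+", starts = 1000,
      ends = 1999, identity = 0.92),
    list(read_id = "rescued", chrom = "chr1", strand = "+", starts = 1000,
      ends = 1999, identity = 0.95),
    list(read_id = "rescued", chrom = "chr2", strand = "+", starts = 1000,
      ends = 1999, identity = 0.85),
    list(read_id = "lowid", chrom = "chr1", strand = "+", starts = 1000,
      ends = 1999, identity = 0.80))
  fl <- filterIdentity(aln)
  part <- partitionMultiplicity(fl$kept, fl$rejected,
    manifest = c("multi", "rescued", "lowid", "ghost"))
  got <- setNames(part$uniqueness, part$read_id)
  expect_equal(got[["multi"]], "multi")
  # the second hit fell to the identity filter, so the read is unique
  expect_equal(got[["rescued"]], "unique")
  expect_equal(got[["lowid"]], "filtered")
  expect_equal(got[["ghost"]], "unaligned")
  # totality: every manifest read in exactly one class
  expect_setequal(part$read_id, c("multi", "rescued", "lowid", "ghost"))
  expect_equal(nrow(part), 4L)
})

test_that("target assignment maximizes exonic overlap under strand agreement", {
  ann <- toyAnnotation()
  aln <- mkAlignments(
    # fully inside gPlus
    list(read_id = "in", chrom = "chr1", strand = "+", starts = c(1000, 2000),
      ends = c(1499, 2499)),
    # overlaps gPlus by 400 exonic bases and gNeighbour by 100
    list(read_id = "split", chrom = "chr1", strand = "+", starts = 2100,
      ends = 2599),
    # antisense over gPlus only: no same-strand candidate
    list(read_id = "anti", chrom = "chr1", strand = "-", starts = 1000,
      ends = 1499))
  tg <- assignTargets(aln, ann)
  expect_equal(tg$gene_id[tg$read_id == "in"], "gPlus")
  expect_equal(tg$gene_id[tg$read_id == "split"], "gPlus")
  expect_false(tg$tie_flag[tg$read_id == "split"])
  expect_true(is.na(tg$gene_id[tg$read_id == "anti"]))
  # exact tie in exonic overlap: lexicographically smaller gene wins, flagged
  tie <- mkAlignments(list(read_id = "tie", chrom = "chr1", strand = "+",
    starts = 2400, ends = 2499))  # 100 bp in both gPlus and gNeighbour
  tg2 <- assignTargets(tie, ann)
  expect_equal(tg2$gene_id, "gNeighbour")
  expect_true(tg2$tie_flag)
})

test_that("offsets and the full-length flag follow the spliced-target rule", {
  ann <- toyAnnotation()  # tPlus: tss 1000, tes 2499, spliced 1000
  aln <- mkAlignments(
    # starts at the TSS, exactly target length: offset 0, FL (boundary 'equal')
    list(read_id = "fl", chrom = "chr1", strand = "+", starts = c(1000, 2000),
      ends = c(1499, 2499)),
    # 150 bp 5'-truncated: positive offset, one base short of FL is not FL
    list(read_id = "trunc", chrom = "chr1", strand = "+", starts = c(1150, 2000),
      ends = c(1499, 2499)),
    # minus-strand gene, rightmost aligned base 40 bp beyond the TSS: upstream
    list(read_id = "mup", chrom = "chr1", strand = "-", starts = c(4000, 4700),
      ends = c(4499, 5040)))
  asg <- classifyReads(aln, ann)
  a <- asg[match(c("fl", "trunc", "mup"), asg$read_id), ]
  expect_equal(a$five_prime_offset, c(0L, 150L, -40L))
  expect_equal(a$is_full_length, c(TRUE, FALSE, TRUE))
  expect_equal(a$target_spliced_length[1:2], c(1000L, 1000L))
  # FL boundary: exactly one base short fails
  short <- mkAlignments(list(read_id = "short", chrom = "chr1", strand = "+",
    starts = c(1001, 2000), ends = c(1499, 2499)))
  expect_false(classifyReads(short, ann)$is_full_length)
})

test_that("size fractions use half-open low-inclusive boundaries", {
  expect_equal(assignSizeFraction(c(800, 1000, 1999, 2000, 2999, 3000, 4500,
    6000, 6001)),
    c("sub1k", "1-2kb", "1-2kb", "2-3kb", "2-3kb", "3-6kb", "3-6kb", "3-6kb",
      "over6k"))
  expect_error(assignSizeFraction(0), "positive")
})

test_that("mirroring the genome and flipping strands leaves offsets and FL unchanged", {
  sim <- simulateExperiment(simConfig(n_genes = 10, n_reads_per_protocol = 150,
    n_homeolog_triplets = 0, seed = 13))
  aln <- sim$libraries$template_switch$alignments
  asg <- classifyReads(aln, sim$annotation)

  M <- 10000000L
  flip <- function(s) ifelse(s == "+", "-", "+")
  ex <- exonRanges(sim$annotation)
  mirEx <- S4Vectors::endoapply(ex, function(gr)
    GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
      IRanges::IRanges(M - GenomicRanges::end(gr), M - GenomicRanges::start(gr)),
      flip(as.character(GenomicRanges::strand(gr)))))
  an0 <- geneInfo(sim$annotation)
  mirAnn <- GeneAnnotation(mirEx,
    geneIds = setNames(an0$gene_id, an0$transcript_id))
  info <- alignmentInfo(aln)
  bl <- alignmentBlocks(aln)
  mirBlocks <- IRanges::IRangesList(lapply(seq_along(bl), function(i) {
    r <- bl[[i]]
    IRanges::IRanges(rev(M - IRanges::end(r)), rev(M - IRanges::start(r)))
  }))
  mirInfo <- info
  mirInfo$strand <- flip(info$strand)
  mirAln <- AlignmentSet(mirInfo, mirBlocks)
  masg <- classifyReads(mirAln, mirAnn)
  m <- match(asg$read_id, masg$read_id)
  expect_equal(asg$gene_id, masg$gene_id[m])
  expect_equal(asg$five_prime_offset, masg$five_prime_offset[m])
  expect_equal(asg$three_prime_offset, masg$three_prime_offset[m])
  expect_equal(asg$is_full_length, masg$is_full_length[m])
})

test_that("extending a read's 5' alignment upstream never loses the FL flag", {
  ann <- toyAnnotation()
  for (ext in c(0L, 10L, 200L, 600L)) {
    aln <- mkAlignments(list(read_id = "r", chrom = "chr1", strand = "+",
      starts = c(1000L - ext, 2000L), ends = c(1499L, 2499L)))
    expect_true(classifyReads(aln, ann)$is_full_length, info = ext)
  }
})

test_that("without 3' jitter FL is exactly the zero-5'-loss truth flag", {
  cfg <- simConfig(n_genes = 12, n_reads_per_protocol = 400,
    three_prime_jitter_sd = 0, n_homeolog_triplets = 2, seed = 21)
  sim <- simulateExperiment(cfg)
  for (p in names(sim$libraries)) {
    lib <- sim$libraries[[p]]
    asg <- classifyReads(lib$alignments, sim$annotation,
      manifest = lib$truth$read_id)
    u <- asg[asg$uniqueness == "unique" & !is.na(asg$gene_id), ]
    tr <- lib$truth[match(u$read_id, lib$truth$read_id), ]
    expect_equal(u$is_full_length, tr$bases_lost_5p == 0L)
    # every manifest read appears in exactly one uniqueness class
    expect_equal(sort(asg$read_id), sort(lib$truth$read_id))
  }
})
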