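# Hand-enumerated toy instances used to validate the isoform classifier.
# Kept in the package (unexported) so the test suite and the acceptance
# script check the same frozen battery.

# annotation: four loci on chrT
#   txA (+): 4 exons, introns (1201,1500) (1701,2000) (2201,2500)
#   txB (+): 2 exons, intron (10401,10800)
#   txC (-): 2 exons, intron (20301,20700)
#   txM (+): mono-exon (30001,32000)
.isoformTruthAnnotation <- function() {
  ex <- GenomicRanges::GRangesList(
    txA = GenomicRanges::GRanges("chrT",
      IRanges::IRanges(c(1001, 1501, 2001, 2501), c(1200, 1700, 2200, 2700)), "+"),
    txB = GenomicRanges::GRanges("chrT",
      IRanges::IRanges(c(10001, 10801), c(10400, 11200)), "+"),
    txC = GenomicRanges::GRanges("chrT",
      IRanges::IRanges(c(20001, 20701), c(20300, 21000)), "-"),
    txM = GenomicRanges::GRanges("chrT",
      IRanges::IRanges(30001, 32000), "+"))
  GeneAnnotation(ex, geneIds = c(txA = "gA", txB = "gB", txC = "gC", txM = "gM"))
}

# one row per case: expected class under fuzz = 0
.isoformTruthCases <- function() {
  mk <- function(id, chrom, strand, starts, ends, class, contained = FALSE) {
    list(id = id, chrom = chrom, strand = strand,
      starts = as.integer(starts), ends = as.integer(ends),
      class = class, contained = contained)
  }
  cases <- list(
    # chain identity
    mk("c01", "chrT", "+", c(1001, 1501, 2001, 2501), c(1200, 1700, 2200, 2700), "known"),
    mk("c02", "chrT", "+", c(1100, 1501, 2001, 2501), c(1200, 1700, 2200, 2700), "known"),
    mk("c03", "chrT", "+", c(10001, 10801), c(10400, 11200), "known"),
    mk("c04", "chrT", "-", c(20001, 20701), c(20300, 21000), "known"),
    # blocks extend past annotated ends but the chain matches
    mk("c05", "chrT", "+", c(9800, 10801), c(10400, 11100), "known"),
    mk("c06", "chrT", "+", c(950, 1501, 2001, 2501), c(1200, 1700, 2200, 2750), "known"),
    # contiguous sub-chains: 5'/3'-truncated views of txA
    mk("c07", "chrT", "+", c(1600, 2001, 2501), c(1700, 2200, 2700), "novel_isoform", TRUE),
    mk("c08", "chrT", "+", c(1001, 1501, 2001), c(1200, 1700, 2100), "novel_isoform", TRUE),
    mk("c09", "chrT", "+", c(1550, 2001), c(1700, 2200), "novel_isoform", TRUE),
    # exon skipping / partly shared chains
    mk("c10", "chrT", "+", c(1001, 2001, 2501), c(1200, 2200, 2700), "novel_isoform"),
    mk("c11", "chrT", "+", c(1001, 1511, 2001, 2501), c(1210, 1700, 2200, 2700), "novel_isoform"),
    mk("c12", "chrT", "+", c(1001, 1501, 2201), c(1200, 1700, 2700), "novel_isoform"),
    mk("c13", "chrT", "+", c(2001, 2501, 2801), c(2200, 2600, 2900), "novel_isoform"),
    mk("c14", "chrT", "+", c(1001, 1501), c(1200, 2200), "novel_isoform", TRUE),
    mk("c15", "chrT", "+", c(10001, 10801, 11401), c(10400, 11209, 11500), "novel_isoform"),
    # every junction shifted: overlap without any shared junction
    mk("c16", "chrT", "+", c(1001, 1511, 2011, 2511), c(1210, 1710, 2210, 2700), "other"),
    mk("c17", "chrT", "-", c(20001, 20706), c(20295, 21000), "other"),
    mk("c18", "chrT", "+", c(1001, 1204), c(1200, 1500) + c(0, 200), "other"),
    # mono-exon reads
    mk("c19", "chrT", "+", 1050, 1150, "mono_exon_contained"),
    mk("c20", "chrT", "+", 1001, 1200, "mono_exon_contained"),
    mk("c21", "chrT", "+", 30100, 31000, "mono_exon_contained"),
    mk("c22", "chrT", "-", 20100, 20200, "mono_exon_contained"),
    mk("c23", "chrT", "+", 10900, 11100, "mono_exon_contained"),
    mk("c24", "chrT", "+", 1100, 1300, "other"),
    mk("c25", "chrT", "+", 29900, 30500, "other"),
    mk("c26", "chrT", "+", 1001, 2700, "other"),
    mk("c27", "chrT", "+", 1001, 1700, "other"),
    # no same-strand exonic overlap at all
    mk("c28", "chrT", "+", 5000, 5500, "novel_locus"),
    mk("c29", "chrT", "+", c(5000, 5300), c(5100, 5400), "novel_locus"),
    mk("c30", "chrT", "-", c(1001, 1501, 2001, 2501), c(1200, 1700, 2200, 2700), "novel_locus"),
    mk("c31", "chrU", "+", c(1001, 1501, 2001, 2501), c(1200, 1700, 2200, 2700), "novel_locus"),
    mk("c32", "chrT", "-", c(40001, 40301), c(40100, 40400), "novel_locus"))
  info <- do.call(rbind, lapply(cases, function(cs) {
    rl <- sum(cs$ends - cs$starts + 1L)
    data.frame(read_id = cs$id, read_length = rl, chrom = cs$chrom,
      strand = cs$strand, qstart = 1L, qend = rl, matches = rl,
      aln_length = rl, is_primary = TRUE, stringsAsFactors = FALSE)
  }))
  blocks <- IRanges::IRangesList(lapply(cases, function(cs)
    IRanges::IRanges(cs$starts, cs$ends)))
  expected <- data.frame(
    read_id = vapply(cases, `[[`, character(1), "id"),
    class = vapply(cases, `[[`, character(1), "class"),
    contained = vapply(cases, `[[`, logical(1), "contained"),
    stringsAsFactors = FALSE)
  list(annotation = .isoformTruthAnnotation(),
    alignments = AlignmentSet(info, blocks), expected = expected)
}
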