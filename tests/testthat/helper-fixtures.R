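# in-code fixtures and independent oracles shared across the suite

# two-gene toy annotation: gPlus (+, 2 exons) and gMinus (-, 2 exons), plus a
# small same-strand neighbour overlapping gPlus for tie/overlap tests
toyAnnotation <- function() {
  ex <- GenomicRanges::GRangesList(
    tPlus = GenomicRanges::GRanges("chr1",
      IRanges::IRanges(c(1000, 2000), c(1499, 2499)), "+"),
    tMinus = GenomicRanges::GRanges("chr1",
      IRanges::IRanges(c(4000, 4700), c(4499, 5000)), "-"),
    tNeighbour = GenomicRanges::GRanges("chr1",
      IRanges::IRanges(2400, 2899), "+"))
  GeneAnnotation(ex,
    geneIds = c(tPlus = "gPlus", tMinus = "gMinus", tNeighbour = "gNeighbour"))
}

# build an AlignmentSet from a list of records given as
# list(read_id, chrom, strand, starts, ends, identity = 1, read_length = NULL,
#      aln_length = NULL, is_primary = TRUE)
mkAlignments <- function(...) {
  recs <- list(...)
  info <- do.call(rbind, lapply(recs, function(r) {
    w <- sum(r$ends - r$starts + 1L)
    alen <- if (is.null(r$aln_length)) w else r$aln_length
    rlen <- if (is.null(r$read_length)) w else r$read_length
    idty <- if (is.null(r$identity)) 1 else r$identity
    data.frame(read_id = r$read_id, read_length = as.integer(rlen),
      chrom = r$chrom, strand = r$strand, qstart = 1L,
      qend = as.integer(alen), matches = as.integer(round(idty * alen)),
      aln_length = as.integer(alen),
      identity = as.integer(round(idty * alen)) / alen,
      is_primary = if (is.null(r$is_primary)) TRUE else r$is_primary,
      stringsAsFactors = FALSE)
  }))
  blocks <- IRanges::IRangesList(lapply(recs, function(r)
    IRanges::IRanges(as.integer(r$starts), as.integer(r$ends))))
  AlignmentSet(info, blocks)
}

# independent Mann-Whitney oracle: brute-force enumeration over all
# C(n+m, n) assignments of the pooled values, U by explicit pair counting
mwOracle <- function(a, b) {
  pool <- c(a, b)
  n <- length(a); m <- length(b)
  uStat <- function(x, y)
    sum(outer(x, y, "<")) + 0.5 * sum(outer(x, y, "=="))
  uObs <- min(uStat(a, b), uStat(b, a))
  sets <- utils::combn(n + m, n)
  stats <- apply(sets, 2L, function(idx) {
    ua <- uStat(pool[idx], pool[-idx])
    min(ua, n * m - ua)
  })
  list(U = uObs, p = mean(stats <= uObs + 1e-9))
}

# independent clustering oracle: connected components of the pairwise
# both-tolerances graph, by breadth-first search over an adjacency matrix
componentsOracle <- function(e5, e3, tol5, tol3) {
  n <- length(e5)
  adj <- outer(e5, e5, function(x, y) abs(x - y) <= tol5) &
    outer(e3, e3, function(x, y) abs(x - y) <= tol3)
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# cluster membership partition (set of read-id sets) for comparing clusterings
clusterPartition <- function(clusters) {
  sort(vapply(strsplit(clusters$members, ","), function(m)
    paste(sort(m), collapse = ","), character(1)))
}

# a minimal ReadAssignment-like table for clusterEnds from end coordinates
mkAssignments <- function(e5, e3, gene = "g1", strand = "+",
                          read_length = NULL) {
  n <- length(e5)
  if (is.null(read_length)) read_length <- abs(e3 - e5) + 1L
  data.frame(
    read_id = sprintf("r%03d", seq_len(n)), uniqueness = "unique",
    gene_id = gene, transcript_id = paste0(gene, ".1"),
    five_prime_offset = 0L, three_prime_offset = 0L,
    read_length = as.integer(read_length),
    target_spliced_length = as.integer(read_length), is_full_length = TRUE,
    size_fraction = "1-2kb", tie_flag = FALSE, chrom = "chr1",
    strand = strand,
    read_left = pmin(abs(e5), abs(e3)), read_right = pmax(abs(e5), abs(e3)),
    e5 = as.integer(e5), e3 = as.integer(e3), stringsAsFactors = FALSE)
}
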