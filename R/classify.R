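#' Assign gel size fractions from read length
#'
#' Bins follow the fractionation scheme of size-selected cDNA libraries:
#' `[1000, 2000)` -> `1-2kb`, `[2000, 3000)` -> `2-3kb`, `[3000, 6000]` ->
#' `3-6kb`; shorter reads fall in `sub1k`, longer in `over6k`. Boundaries are
#' half-open low-inclusive except the upper edge of `3-6kb`.
#'
#' @param readLength Positive integer vector of read lengths (bp).
#' @return Character vector of fraction labels.
#' @examples
#' assignSizeFraction(c(800, 1999, 2000, 4500, 6001))
#' @export
assignSizeFraction <- function(readLength) {
  if (any(is.na(readLength)) || any(readLength <= 0))
    stop("read lengths must be positive")
  out <- character(length(readLength))
  out[readLength < 1000] <- "sub1k"
  out[readLength >= 1000 & readLength < 2000] <- "1-2kb"
  out[readLength >= 2000 & readLength < 3000] <- "2-3kb"
  out[readLength >= 3000 & readLength <= 6000] <- "3-6kb"
  out[readLength > 6000] <- "over6k"
  out
}

#' Ordered size-fraction labels
#' @return Character vector of the five labels in increasing length order.
#' @export
sizeFractionLevels <- function() c("sub1k", "1-2kb", "2-3kb", "3-6kb", "over6k")

#' Filter alignment records by nucleotide identity
#'
#' Keeps records whose identity (residue matches / alignment length) is at or
#' above the threshold; the boundary is inclusive, so identity exactly 0.90
#' passes the default filter.
#'
#' @param alignments An [AlignmentSet-class].
#' @param threshold Minimum identity, default 0.90.
#' @return list with `kept` and `rejected` [AlignmentSet-class] objects.
#' @export
filterIdentity <- function(alignments, threshold = 0.90) {
  stopifnot(is(alignments, "AlignmentSet"), threshold >= 0, threshold <= 1)
  ok <- alignmentInfo(alignments)$identity >= threshold
  list(kept = alignments[ok], rejected = alignments[!ok])
}

#' Partition reads by mapping multiplicity
#'
#' After identity filtering, a read with exactly one surviving record is
#' `unique`; with two or more it is `multi` (excluded from full-length and
#' offset analysis); a read whose records were all removed by the filter is
#' `filtered`; a manifest read with no alignment at all is `unaligned`.
#'
#' @param kept [AlignmentSet-class] of records that passed the identity
#'   filter.
#' @param rejected Optional [AlignmentSet-class] of filtered-out records
#'   (distinguishes `filtered` from `unaligned`).
#' @param manifest Optional character vector of all read ids in the library;
#'   defaults to the reads seen in `kept` and `rejected`.
#' @return data.frame `read_id` / `uniqueness`, one row per manifest read.
#' @export
partitionMultiplicity <- function(kept, rejected = NULL, manifest = NULL) {
  stopifnot(is(kept, "AlignmentSet"))
  kept_ids <- alignmentInfo(kept)$read_id
  rej_ids <- if (!is.null(rejected)) unique(alignmentInfo(rejected)$read_id)
             else character()
  if (is.null(manifest)) manifest <- unique(c(kept_ids, rej_ids))
  tab <- table(kept_ids)
  uniq <- sort(unique(manifest))
  n <- as.integer(tab[uniq]); n[is.na(n)] <- 0L
  cls <- ifelse(n == 1L, "unique",
    ifelse(n >= 2L, "multi",
      ifelse(uniq %in% rej_ids, "filtered", "unaligned")))
  data.frame(read_id = uniq, uniqueness = cls, stringsAsFactors = FALSE)
}

# all (record, transcript) pairs with exonic overlap >= 1 base, same
# chromosome and strand; `ov` is the summed overlap in bases
.overlapPairs <- function(alignments, annotation) {
  info <- alignmentInfo(alignments)
  bl <- alignmentBlocks(alignments)
  empty <- data.table::data.table(record = integer(), tx = integer(),
    ov = integer())
  if (!nrow(info)) return(empty)
  nper <- S4Vectors::elementNROWS(bl)
  readGR <- GenomicRanges::GRanges(rep(info$chrom, nper),
    unlist(bl, use.names = FALSE), rep(info$strand, nper))
  readGR$record <- rep(seq_len(nrow(info)), nper)
  ex <- exonRanges(annotation)
  exFlat <- unlist(ex, use.names = FALSE)
  exFlat$tx <- rep(seq_along(ex), S4Vectors::elementNROWS(ex))
  hits <- GenomicRanges::findOverlaps(readGR, exFlat, ignore.strand = FALSE)
  if (!length(hits)) return(empty)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(readGR)[S4Vectors::queryHits(hits)],
    IRanges::ranges(exFlat)[S4Vectors::subjectHits(hits)]))
  dt <- data.table::data.table(
    record = readGR$record[S4Vectors::queryHits(hits)],
    tx = exFlat$tx[S4Vectors::subjectHits(hits)],
    ov = ov)
  dt[, list(ov = sum(ov)), by = c("record", "tx")]
}

# per-record target gene: same chromosome + strand, maximal exonic overlap
# (bases of read blocks intersecting exon blocks). Returns one row per record
# index with a candidate; ties across genes broken lexicographically.
.recordTargets <- function(alignments, annotation) {
  per_tx <- .overlapPairs(alignments, annotation)
  if (!nrow(per_tx))
    return(data.frame(record = integer(), gene_id = character(),
      transcript_id = character(), overlap_bases = integer(),
      tie_flag = logical()))
  an <- geneInfo(annotation)
  per_tx[, `:=`(gene_id = an$gene_id[per_tx$tx],
    transcript_id = an$transcript_id[per_tx$tx])]
  # per record: gene-level best = max over its transcripts; winner = max gene
  per_gene <- per_tx[, list(ov = max(ov),
    transcript_id = transcript_id[which.max(ov)]), by = c("record", "gene_id")]
  data.table::setorderv(per_gene, c("record", "ov", "gene_id"),
    order = c(1L, -1L, 1L))
  best <- per_gene[, list(gene_id = gene_id[1L],
    transcript_id = transcript_id[1L], overlap_bases = as.integer(ov[1L]),
    tie_flag = sum(ov == ov[1L]) > 1L), by = "record"]
  as.data.frame(best)
}

#' Assign each alignment record to a target gene
#'
#' Candidate targets are same-chromosome, same-strand gene models whose exons
#' overlap the record's aligned blocks; the gene maximizing the exonic overlap
#' in bases wins. Ties on overlap go to the lexicographically smaller gene id
#' and are flagged. Records with no candidate get `NA` ("not annotated").
#'
#' @param alignments An [AlignmentSet-class].
#' @param annotation A [GeneAnnotation-class].
#' @return data.frame with one row per record (in order): `read_id`,
#'   `gene_id`, `transcript_id`, `overlap_bases`, `tie_flag`.
#' @export
assignTargets <- function(alignments, annotation) {
  info <- alignmentInfo(alignments)
  best <- .recordTargets(alignments, annotation)
  out <- data.frame(read_id = info$read_id, gene_id = NA_character_,
    transcript_id = NA_character_, overlap_bases = 0L, tie_flag = FALSE,
    stringsAsFactors = FALSE)
  if (nrow(best)) {
    out$gene_id[best$record] <- best$gene_id
    out$transcript_id[best$record] <- best$transcript_id
    out$overlap_bases[best$record] <- best$overlap_bases
    out$tie_flag[best$record] <- best$tie_flag
  }
  out
}

#' Classify reads: offsets, full-length flag, size fraction
#'
#' The end-to-end read classification: filters records by identity,
#' partitions reads by mapping multiplicity, assigns every unique read to a
#' target gene model, and computes strand-aware signed end offsets and the
#' full-length flag.
#'
#' The 5' offset is the signed distance from the read's 5' alignment end (in
#' transcript orientation) to the annotated TSS: negative upstream of the
#' TSS, positive downstream (a truncated read). The 3' offset is the
#' analogous distance to the TES, positive downstream. A read is full length
#' when its length is at least the spliced length of its target model.
#'
#' @param alignments An [AlignmentSet-class] (all records, any identity).
#' @param annotation A [GeneAnnotation-class].
#' @param identityThreshold Inclusive minimum identity, default 0.90.
#' @param manifest Optional character vector of all read ids sequenced
#'   (identifies `unaligned` reads absent from the PAF).
#' @return data.frame with one row per manifest read: `read_id`,
#'   `uniqueness`, `gene_id`, `transcript_id`, `five_prime_offset`,
#'   `three_prime_offset`, `read_length`, `target_spliced_length`,
#'   `is_full_length`, `size_fraction`, `tie_flag`, plus the genomic
#'   bookkeeping columns `chrom`, `strand`, `read_left`, `read_right`, `e5`,
#'   `e3` (transcript-oriented end coordinates used by the end clustering).
#' @export
classifyReads <- function(alignments, annotation, identityThreshold = 0.90,
                          manifest = NULL) {
  fl <- filterIdentity(alignments, identityThreshold)
  part <- partitionMultiplicity(fl$kept, fl$rejected, manifest)
  uniq_ids <- part$read_id[part$uniqueness == "unique"]
  kinfo <- alignmentInfo(fl$kept)
  sel <- which(kinfo$read_id %in% uniq_ids)
  ua <- fl$kept[sel]
  uinfo <- alignmentInfo(ua)
  ubl <- alignmentBlocks(ua)
  tg <- assignTargets(ua, annotation)
  an <- geneInfo(annotation)
  an_idx <- match(tg$transcript_id, an$transcript_id)
  read_left <- vapply(seq_along(ubl), function(i) min(IRanges::start(ubl[[i]])), integer(1))
  read_right <- vapply(seq_along(ubl), function(i) max(IRanges::end(ubl[[i]])), integer(1))
  plus <- uinfo$strand == "+"
  tss <- an$tss[an_idx]; tes <- an$tes[an_idx]
  off5 <- ifelse(plus, read_left - tss, tss - read_right)
  off3 <- ifelse(plus, read_right - tes, tes - read_left)
  spl <- an$spliced_length[an_idx]
  res <- data.frame(
    read_id = uinfo$read_id,
    uniqueness = "unique",
    gene_id = tg$gene_id,
    transcript_id = tg$transcript_id,
    five_prime_offset = as.integer(off5),
    three_prime_offset = as.integer(off3),
    read_length = uinfo$read_length,
    target_spliced_length = as.integer(spl),
    is_full_length = !is.na(spl) & uinfo$read_length >= spl,
    size_fraction = assignSizeFraction(uinfo$read_length),
    tie_flag = tg$tie_flag,
    chrom = uinfo$chrom,
    strand = uinfo$strand,
    read_left = read_left,
    read_right = read_right,
    e5 = as.integer(ifelse(plus, read_left, -read_right)),
    e3 = as.integer(ifelse(plus, read_right, -read_left)),
    stringsAsFactors = FALSE)
  res$is_full_length[is.na(tg$gene_id)] <- NA
  other <- part[part$uniqueness != "unique", , drop = FALSE]
  if (nrow(other)) {
    pad <- data.frame(read_id = other$read_id, uniqueness = other$uniqueness,
      gene_id = NA_character_, transcript_id = NA_character_,
      five_prime_offset = NA_integer_, three_prime_offset = NA_integer_,
      read_length = NA_integer_, target_spliced_length = NA_integer_,
      is_full_length = NA, size_fraction = NA_character_, tie_flag = FALSE,
      chrom = NA_character_, strand = NA_character_,
      read_left = NA_integer_, read_right = NA_integer_, e5 = NA_integer_,
      e3 = NA_integer_, stringsAsFactors = FALSE)
    res <- rbind(res, pad)
  }
  res <- res[order(res$read_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Summarize full-length percentages per size fraction
#'
#' @param assignments Result of [classifyReads()].
#' @return data.frame per size fraction: `size_fraction`, `n`, `n_fl`,
#'   `fl_pct` (share of assigned unique reads that are full length), plus an
#'   `overall` row.
#' @export
summarizeFullLength <- function(assignments) {
  a <- assignments[assignments$uniqueness == "unique" & !is.na(assignments$gene_id), ]
  lev <- intersect(sizeFractionLevels(), unique(a$size_fraction))
  rows <- lapply(c(lev, "overall"), function(f) {
    x <- if (f == "overall") a else a[a$size_fraction == f, ]
    data.frame(size_fraction = f, n = nrow(x), n_fl = sum(x$is_full_length),
      fl_pct = if (nrow(x)) 100 * mean(x$is_full_length) else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
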