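# Homeolog-aware handling of multi-mapping reads. In a polyploid, a read
# from one subgenome copy often aligns to the sister copies as well; such
# reads are not random multi-mappers and can be resolved, because the true
# locus yields the longest alignment of the read.

#' Flag reads hitting multiple homeologous loci
#'
#' Maps every alignment record (primary and secondary) to its target gene and
#' reports, per read, which homeolog-group members it hits. A read hitting
#' two or more members of the same group is flagged `multi_homeolog`; a read
#' hitting members of different groups only is a generic multi-mapper, not a
#' homeolog-ambiguous one.
#'
#' @param alignments An [AlignmentSet-class].
#' @param annotation A [GeneAnnotation-class].
#' @param homeologs Long-form homeolog table (`group_id` / `gene_id`).
#' @return data.frame per read that hits at least one group member:
#'   `read_id`, `group_ids`, `gene_ids` (comma-separated), `n_group_genes`,
#'   `multi_homeolog`.
#' @export
flagHomeologHits <- function(alignments, annotation, homeologs) {
  stopifnot(is.data.frame(homeologs))
  info <- alignmentInfo(alignments)
  rt <- .recordTargets(alignments, annotation)
  if (!nrow(rt))
    return(data.frame(read_id = character(), group_ids = character(),
      gene_ids = character(), n_group_genes = integer(),
      multi_homeolog = logical(), stringsAsFactors = FALSE))
  dt <- data.table::data.table(read_id = info$read_id[rt$record],
    gene_id = rt$gene_id)
  hom <- data.table::as.data.table(homeologs)
  dt <- merge(unique(dt), hom, by = "gene_id")
  if (!nrow(dt))
    return(data.frame(read_id = character(), group_ids = character(),
      gene_ids = character(), n_group_genes = integer(),
      multi_homeolog = logical(), stringsAsFactors = FALSE))
  per_group <- dt[, list(n = length(unique(gene_id))),
    by = c("read_id", "group_id")]
  out <- dt[order(gene_id), list(
    group_ids = paste(sort(unique(group_id)), collapse = ","),
    gene_ids = paste(sort(unique(gene_id)), collapse = ","),
    n_group_genes = length(unique(gene_id))), by = "read_id"]
  flag <- per_group[, list(multi_homeolog = any(n >= 2L)), by = "read_id"]
  out <- merge(out, flag, by = "read_id")
  data.table::setorderv(out, "read_id")
  as.data.frame(out)
}

#' Resolve multi-mapping reads by best alignment match
#'
#' Two-step filter applied per read: records below the identity threshold are
#' dropped; among survivors the record minimizing `d = read length -
#' alignment length` (the bases of the read left unaligned) wins. Exactly one
#' minimizer resolves the read to that record's gene; several minimizers
#' leave it `ambiguous`; no survivor leaves it `filtered`.
#'
#' `lengthSide` chooses the alignment length entering `d`: `"read"` (default)
#' uses the PAF alignment block length; `"target"` uses the summed genomic
#' block widths.
#'
#' @param alignments An [AlignmentSet-class] holding all records of the reads
#'   to resolve.
#' @param annotation A [GeneAnnotation-class] (targets of the records).
#' @param identityThreshold Inclusive minimum identity, default 0.90.
#' @param lengthSide `"read"` or `"target"`.
#' @return data.frame per read: `read_id`, `status`
#'   (`resolved`/`ambiguous`/`filtered`), `gene_id` (for resolved reads),
#'   `best_d`, `n_candidates` (records surviving the identity filter).
#' @export
resolveBestMatch <- function(alignments, annotation, identityThreshold = 0.90,
                             lengthSide = c("read", "target")) {
  lengthSide <- match.arg(lengthSide)
  info <- alignmentInfo(alignments)
  if (!nrow(info))
    return(data.frame(read_id = character(), status = character(),
      gene_id = character(), best_d = integer(), n_candidates = integer(),
      stringsAsFactors = FALSE))
  bl <- alignmentBlocks(alignments)
  alen <- if (lengthSide == "read") info$aln_length
          else vapply(seq_along(bl), function(i) sum(IRanges::width(bl[[i]])), integer(1))
  rt <- .recordTargets(alignments, annotation)
  gene <- rep(NA_character_, nrow(info))
  if (nrow(rt)) gene[rt$record] <- rt$gene_id
  dt <- data.table::data.table(read_id = info$read_id,
    identity = info$identity, d = info$read_length - alen, gene_id = gene)
  res <- dt[, {
    surv <- identity >= identityThreshold
    if (!any(surv)) {
      list(status = "filtered", gene_id = NA_character_,
        best_d = NA_integer_, n_candidates = 0L)
    } else {
      ds <- d[surv]; gs <- gene_id[surv]
      dmin <- min(ds)
      winners <- unique(gs[ds == dmin])
      if (sum(ds == dmin) == 1L) {
        list(status = "resolved", gene_id = winners[1L],
          best_d = as.integer(dmin), n_candidates = sum(surv))
      } else {
        list(status = "ambiguous", gene_id = NA_character_,
          best_d = as.integer(dmin), n_candidates = sum(surv))
      }
    }
  }, by = "read_id"]
  data.table::setorderv(res, "read_id")
  as.data.frame(res)
}

#' Summarize homeolog resolution
#'
#' @param flags Result of [flagHomeologHits()].
#' @param resolution Result of [resolveBestMatch()] on the flagged reads.
#' @return list: `n_multi_homeolog`, `n_resolved`, `n_ambiguous`,
#'   `n_filtered`.
#' @export
summarizeHomeologResolution <- function(flags, resolution) {
  multi <- flags$read_id[flags$multi_homeolog]
  r <- resolution[resolution$read_id %in% multi, ]
  list(n_multi_homeolog = length(multi),
    n_resolved = sum(r$status == "resolved"),
    n_ambiguous = sum(r$status == "ambiguous"),
    n_filtered = sum(r$status == "filtered"))
}
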