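#' Access the per-transcript table of a GeneAnnotation
#'
#' @param x A [GeneAnnotation-class].
#' @return data.frame with one row per transcript (see
#'   [GeneAnnotation-class]).
#' @export
setGeneric("geneInfo", function(x) standardGeneric("geneInfo"))

#' @rdname geneInfo
#' @export
setMethod("geneInfo", "GeneAnnotation", function(x) x@anno)

#' Access the exon ranges of a GeneAnnotation
#'
#' @param x A [GeneAnnotation-class].
#' @return [GenomicRanges::GRangesList] named by transcript id.
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))

#' @rdname exonRanges
#' @export
setMethod("exonRanges", "GeneAnnotation", function(x) x@exons)

#' Access the per-record table of an AlignmentSet
#'
#' @param x An [AlignmentSet-class].
#' @return data.frame with one row per alignment record.
#' @export
setGeneric("alignmentInfo", function(x) standardGeneric("alignmentInfo"))

#' @rdname alignmentInfo
#' @export
setMethod("alignmentInfo", "AlignmentSet", function(x) x@info)

#' Access the aligned blocks of an AlignmentSet
#'
#' @param x An [AlignmentSet-class].
#' @return [IRanges::IRangesList] parallel to [alignmentInfo()].
#' @export
setGeneric("alignmentBlocks", function(x) standardGeneric("alignmentBlocks"))

#' @rdname alignmentBlocks
#' @export
setMethod("alignmentBlocks", "AlignmentSet", function(x) x@blocks)

#' @describeIn GeneAnnotation Number of transcript models.
#' @param x A GeneAnnotation.
#' @export
setMethod("length", "GeneAnnotation", function(x) length(x@exons))

#' @describeIn AlignmentSet Number of alignment records.
#' @param x An AlignmentSet.
#' @export
setMethod("length", "AlignmentSet", function(x) nrow(x@info))

#' @describeIn AlignmentSet Subset records by index or logical mask.
#' @param i Index vector.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "AlignmentSet", function(x, i, j, ..., drop = FALSE) {
  info <- x@info[i, , drop = FALSE]
  rownames(info) <- NULL
  new("AlignmentSet", info = info, blocks = x@blocks[i])
})

setMethod("show", "GeneAnnotation", function(object) {
  an <- object@anno
  cat(sprintf("GeneAnnotation with %d transcript model(s) (%d gene(s)) on %d sequence(s)\n",
    nrow(an), length(unique(an$gene_id)), length(unique(an$chrom))))
  if (nrow(an)) {
    cat(sprintf("  spliced length: %d-%d bp; exons per model: %d-%d\n",
      min(an$spliced_length), max(an$spliced_length),
      min(an$n_exons), max(an$n_exons)))
    utils::head(an[, c("transcript_id", "gene_id", "chrom", "strand", "tss",
      "tes", "spliced_length")], 4L) |> print()
    if (nrow(an) > 4L) cat("  ...\n")
  }
  invisible(object)
})

setMethod("show", "AlignmentSet", function(object) {
  info <- object@info
  cat(sprintf("AlignmentSet with %d record(s) from %d read(s)\n",
    nrow(info), length(unique(info$read_id))))
  if (nrow(info)) {
    cat(sprintf("  identity: %.3f-%.3f; %d secondary record(s)\n",
      min(info$identity), max(info$identity), sum(!info$is_primary)))
    utils::head(info[, c("read_id", "chrom", "strand", "read_length",
      "matches", "aln_length", "identity")], 4L) |> print()
    if (nrow(info) > 4L) cat("  ...\n")
  }
  invisible(object)
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig (library-chemistry simulator parameters)\n")
  for (nm in slotNames(object)) {
    v <- slot(object, nm)
    cat(sprintf("  %-24s %s\n", nm, paste(format(v), collapse = " - ")))
  }
  invisible(object)
})
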