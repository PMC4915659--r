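#' Read transcript models from a GFF3 annotation
#'
#' Imports gene/mRNA/exon features and builds one [GeneAnnotation-class]
#' record per mRNA (or transcript) feature. Genes with several mRNAs
#' contribute several models. mRNA features without exon children are skipped
#' with a warning.
#'
#' @param path Path to a GFF3 file (1-based inclusive coordinates; converted
#'   to the package's internal GRanges convention, which is the same).
#' @return A [GeneAnnotation-class].
#' @export
readGFF3Genes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  dataline <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[dataline], "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    bad <- which(dataline)[which(nf != 9L)[1L]]
    stop(sprintf("malformed GFF3 at line %d: expected 9 tab-separated fields, got %d",
      bad, nf[which(nf != 9L)[1L]]))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  is_tx <- type %in% c("mRNA", "transcript")
  is_ex <- type == "exon"
  if (!any(is_tx)) stop("GFF3 contains no mRNA/transcript features")
  tx <- gr[is_tx]
  tx_id <- as.character(tx$ID)
  if (anyNA(tx_id)) stop("mRNA feature(s) without an ID attribute")
  gene_of_tx <- vapply(seq_along(tx), function(i) {
    p <- tx$Parent[[i]]
    if (length(p)) as.character(p[1L]) else tx_id[i]
  }, character(1))
  ex <- gr[is_ex]
  parent <- as.character(S4Vectors::unstrsplit(ex$Parent, ","))
  # exons can name several parents; expand
  pl <- strsplit(parent, ",", fixed = TRUE)
  ex <- rep(ex, lengths(pl))
  parent <- unlist(pl, use.names = FALSE)
  keep <- parent %in% tx_id
  ex <- ex[keep]; parent <- parent[keep]
  has_ex <- tx_id %in% parent
  if (any(!has_ex)) {
    warning(sprintf("skipping %d mRNA feature(s) with no exons: %s",
      sum(!has_ex), paste(utils::head(tx_id[!has_ex], 5L), collapse = ", ")))
    tx_id <- tx_id[has_ex]; gene_of_tx <- gene_of_tx[has_ex]
  }
  if (!length(tx_id)) stop("no mRNA feature has exons")
  sp <- split(GenomicRanges::granges(ex), factor(parent, levels = tx_id))
  GeneAnnotation(methods::as(sp, "GRangesList"),
    geneIds = stats::setNames(gene_of_tx, tx_id))
}

#' Write a GeneAnnotation to GFF3
#'
#' Emits a deterministic gene/mRNA/exon hierarchy (ordered by chromosome,
#' span start, transcript id) so that identical annotations produce
#' byte-identical files.
#'
#' @param annotation A [GeneAnnotation-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGFF3Genes <- function(annotation, path) {
  an <- geneInfo(annotation)
  ex <- exonRanges(annotation)
  ord <- order(an$chrom, an$span_start, an$transcript_id)
  out <- c("##gff-version 3")
  genes_done <- character()
  for (i in ord) {
    g <- an$gene_id[i]; t <- an$transcript_id[i]
    gx <- an[an$gene_id == g, , drop = FALSE]
    if (!g %in% genes_done) {
      out <- c(out, paste(an$chrom[i], "capFL", "gene",
        min(gx$span_start), max(gx$span_end), ".", an$strand[i], ".",
        sprintf("ID=%s", g), sep = "\t"))
      genes_done <- c(genes_done, g)
    }
    out <- c(out, paste(an$chrom[i], "capFL", "mRNA",
      an$span_start[i], an$span_end[i], ".", an$strand[i], ".",
      sprintf("ID=%s;Parent=%s", t, g), sep = "\t"))
    r <- ex[[t]]
    out <- c(out, paste(an$chrom[i], "capFL", "exon",
      GenomicRanges::start(r), GenomicRanges::end(r), ".", an$strand[i], ".",
      sprintf("ID=%s.exon%d;Parent=%s", t, seq_along(r), t), sep = "\t"))
  }
  writeLines(out, path)
  invisible(path)
}
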