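#' @import methods
#' @importFrom S4Vectors isSorted
NULL

#' GeneAnnotation: annotated transcript models
#'
#' Container for a set of transcript ("gene model") annotations: one record
#' per mRNA, holding its exon blocks, strand, strand-aware transcription start
#' and end sites (TSS/TES) and spliced (mRNA) length. These models are the
#' "targets" of full-length classification: a read is full length when it is
#' at least as long as the spliced length of the model it is assigned to.
#'
#' All coordinates are 1-based closed, the native convention of
#' [GenomicRanges::GRanges]. On the plus strand the TSS is the first exon
#' start and the TES the last exon end; on the minus strand the TSS is the
#' last exon end and the TES the first exon start.
#'
#' @slot exons A [GenomicRanges::GRangesList], one element per transcript,
#'   named by transcript id, holding that transcript's exons (sorted by
#'   genomic start, non-overlapping, single chromosome and strand).
#' @slot anno A data.frame with one row per transcript: `transcript_id`,
#'   `gene_id`, `chrom`, `strand`, `tss`, `tes`, `spliced_length`, `n_exons`,
#'   `span_start`, `span_end`.
#'
#' @seealso [GeneAnnotation()] for construction, [readGFF3Genes()] to import
#'   from GFF3, [geneInfo()] and [exonRanges()] for access.
#' @export
setClass("GeneAnnotation",
  slots = c(exons = "GRangesList", anno = "data.frame"))

setValidity("GeneAnnotation", function(object) {
  ex <- object@exons
  an <- object@anno
  msgs <- character()
  if (is.null(names(ex)) || anyDuplicated(names(ex)))
    msgs <- c(msgs, "exons must be named by unique transcript ids")
  if (length(ex) != nrow(an))
    msgs <- c(msgs, "exons and anno must be parallel")
  if (length(ex)) {
    if (!identical(names(ex), an$transcript_id))
      msgs <- c(msgs, "names(exons) must equal anno$transcript_id")
    nex <- S4Vectors::elementNROWS(ex)
    if (any(nex == 0L))
      msgs <- c(msgs, "every transcript must have at least one exon")
    st <- unlist(GenomicRanges::strand(ex), use.names = FALSE)
    if (!all(as.character(S4Vectors::runValue(GenomicRanges::strand(ex))) %in% c("+", "-")))
      msgs <- c(msgs, "exon strand must be '+' or '-'")
    # sorted, non-overlapping exons within each transcript
    rg <- IRanges::ranges(ex)
    bad <- sum(vapply(seq_along(rg), function(i) {
      r <- rg[[i]]
      length(r) > 1L &&
        any(IRanges::start(r)[-1L] <= IRanges::end(r)[-length(r)])
    }, logical(1)))
    if (bad > 0L)
      msgs <- c(msgs, sprintf("%d transcript(s) have unsorted or overlapping exons", bad))
    sl <- vapply(seq_along(rg), function(i) sum(IRanges::width(rg[[i]])), numeric(1))
    if (!isTRUE(all.equal(sl, as.numeric(an$spliced_length))))
      msgs <- c(msgs, "spliced_length must equal the sum of exon widths")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GeneAnnotation from exon ranges
#'
#' @param exons A [GenomicRanges::GRangesList] of exons, one element per
#'   transcript, named by transcript id. Exons may be unsorted; they are
#'   sorted by genomic start on construction.
#' @param geneIds Character vector of gene ids, parallel to `exons` (or named
#'   by transcript id). Defaults to the transcript ids themselves.
#' @return A [GeneAnnotation-class] object.
#' @examples
#' ex <- GenomicRanges::GRangesList(
#'   t1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 301), c(200, 400)), "+"))
#' gm <- GeneAnnotation(ex, geneIds = c(t1 = "g1"))
#' geneInfo(gm)
#' @export
GeneAnnotation <- function(exons, geneIds = NULL) {
  if (!is(exons, "GRangesList"))
    exons <- GenomicRanges::GRangesList(exons)
  if (is.null(names(exons)))
    stop("exons must be named by transcript id")
  exons <- S4Vectors::endoapply(exons, function(gr) gr[order(GenomicRanges::start(gr))])
  exons <- methods::as(exons, "CompressedGRangesList")
  if (is.null(geneIds)) geneIds <- names(exons)
  if (!is.null(names(geneIds))) geneIds <- unname(geneIds[names(exons)])
  if (length(geneIds) != length(exons))
    stop("geneIds must be parallel to exons")
  anno <- .deriveAnno(exons, geneIds)
  new("GeneAnnotation", exons = exons, anno = anno)
}

.deriveAnno <- function(exons, geneIds) {
  if (!length(exons)) {
    return(data.frame(transcript_id = character(), gene_id = character(),
      chrom = character(), strand = character(), tss = integer(),
      tes = integer(), spliced_length = integer(), n_exons = integer(),
      span_start = integer(), span_end = integer()))
  }
  chrom <- vapply(seq_along(exons), function(i)
    as.character(GenomicRanges::seqnames(exons[[i]])[1L]), character(1))
  strand <- vapply(seq_along(exons), function(i)
    as.character(GenomicRanges::strand(exons[[i]])[1L]), character(1))
  rg <- IRanges::ranges(exons)
  span_start <- vapply(seq_along(rg), function(i) min(IRanges::start(rg[[i]])), integer(1))
  span_end <- vapply(seq_along(rg), function(i) max(IRanges::end(rg[[i]])), integer(1))
  spliced <- vapply(seq_along(rg), function(i) sum(IRanges::width(rg[[i]])), integer(1))
  tss <- ifelse(strand == "+", span_start, span_end)
  tes <- ifelse(strand == "+", span_end, span_start)
  data.frame(transcript_id = names(exons), gene_id = geneIds, chrom = chrom,
    strand = strand, tss = as.integer(tss), tes = as.integer(tes),
    spliced_length = spliced, n_exons = S4Vectors::elementNROWS(exons),
    span_start = span_start, span_end = span_end,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' AlignmentSet: spliced read-to-genome alignments
#'
#' One record per alignment line: a read aligned to the genome with its
#' aligned blocks (exons of the spliced alignment), residue match count,
#' alignment length and derived nucleotide identity. A read may contribute
#' several records (multi-mapping, or secondary alignments at homeologous
#' loci); records sharing `read_id` are kept as separate rows.
#'
#' @slot info data.frame, one row per record: `read_id`, `read_length`,
#'   `chrom`, `strand`, `qstart`, `qend` (1-based closed on the read),
#'   `matches`, `aln_length`, `identity` (= matches / aln_length),
#'   `is_primary`.
#' @slot blocks An [IRanges::IRangesList] parallel to `info`, each element the
#'   genomic aligned blocks (1-based closed, sorted, non-overlapping).
#' @seealso [AlignmentSet()], [readPAF()], [alignmentInfo()],
#'   [alignmentBlocks()]
#' @export
setClass("AlignmentSet",
  slots = c(info = "data.frame", blocks = "CompressedIRangesList"))

setValidity("AlignmentSet", function(object) {
  info <- object@info
  bl <- object@blocks
  msgs <- character()
  need <- c("read_id", "read_length", "chrom", "strand", "qstart", "qend",
    "matches", "aln_length", "identity", "is_primary")
  if (!all(need %in% names(info)))
    msgs <- c(msgs, paste("info must have columns:", paste(need, collapse = ", ")))
  if (nrow(info) != length(bl))
    msgs <- c(msgs, "info and blocks must be parallel")
  if (nrow(info) && all(need %in% names(info))) {
    if (!all(info$strand %in% c("+", "-")))
      msgs <- c(msgs, "strand must be '+' or '-'")
    if (any(info$matches > info$aln_length))
      msgs <- c(msgs, "matches must not exceed aln_length")
    if (any(info$aln_length > info$read_length))
      msgs <- c(msgs, "aln_length must not exceed read_length")
    if (any(abs(info$identity - info$matches / info$aln_length) > 1e-9))
      msgs <- c(msgs, "identity must equal matches / aln_length")
    bad <- sum(vapply(seq_along(bl), function(i) {
      r <- bl[[i]]
      length(r) > 1L && any(IRanges::start(r)[-1L] <= IRanges::end(r)[-length(r)])
    }, logical(1)))
    if (bad > 0L)
      msgs <- c(msgs, sprintf("%d record(s) have unsorted or overlapping blocks", bad))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an AlignmentSet
#'
#' @param info data.frame of per-record fields (see
#'   [AlignmentSet-class]); `identity` is derived if missing.
#' @param blocks [IRanges::IRangesList] of genomic aligned blocks, parallel to
#'   the rows of `info`.
#' @return An [AlignmentSet-class].
#' @export
AlignmentSet <- function(info, blocks) {
  info <- as.data.frame(info, stringsAsFactors = FALSE)
  if (!"identity" %in% names(info))
    info$identity <- info$matches / info$aln_length
  if (!"is_primary" %in% names(info))
    info$is_primary <- TRUE
  if (!"qstart" %in% names(info)) info$qstart <- 1L
  if (!"qend" %in% names(info)) info$qend <- as.integer(info$aln_length)
  rownames(info) <- NULL
  if (!is(blocks, "CompressedIRangesList"))
    blocks <- methods::as(IRanges::IRangesList(blocks), "CompressedIRangesList")
  new("AlignmentSet", info = info, blocks = blocks)
}

#' SimConfig: parameters of the library-chemistry simulator
#'
#' Bundles all tunables of the synthetic experiment: the toy annotation
#' (gene count, exon counts, spliced-length range, homeolog triplets), the
#' mRNA pool (fraction of 5'-truncated, hence uncapped, molecules and how much
#' of the 5' end they lose), the two library chemistries (cap-dependent
#' capture and leakage probabilities; the extra 5' loss that template
#' switching incurs from incomplete cDNA synthesis), 3' oligo-dT priming
#' jitter, and the seed from which all randomness flows.
#'
#' @slot n_genes Number of base gene models.
#' @slot exons_per_gene Integer range (min, max) of exons per gene.
#' @slot spliced_length_range Integer range of spliced (mRNA) lengths, bp.
#' @slot p_truncated Probability a pool molecule is 5'-truncated (uncapped).
#' @slot truncation_extent Range (lo, hi] of the fraction of 5' length lost by
#'   a truncated molecule; drawn uniformly.
#' @slot cap_capture Probability the cap-dependent chemistry captures a capped
#'   molecule.
#' @slot cap_leakage Probability the cap-dependent chemistry captures an
#'   uncapped molecule.
#' @slot p_incomplete_synthesis Probability of an extra 5' loss under template
#'   switching (cap-blind capture).
#' @slot three_prime_jitter_sd Gaussian sd (bp) of the 3'-end jitter around
#'   the annotated TES; jitter is symmetric and capped at
#'   `three_prime_jitter_max`.
#' @slot three_prime_jitter_max Hard cap (bp) on |3' jitter|.
#' @slot n_reads_per_protocol Reads emitted per simulated library.
#' @slot n_molecules Size of the shared mRNA pool both libraries draw from;
#'   `NA` means `4 * n_reads_per_protocol`.
#' @slot homeolog_identity Nucleotide identity between homeologous copies;
#'   controls the alignment-length penalty of secondary hits.
#' @slot n_homeolog_triplets Number of homeolog triplets (copies placed on
#'   sister chromosomes and registered as a group).
#' @slot p_homeolog_multi Share of homeolog-derived reads that also report
#'   secondary alignments at the sister loci.
#' @slot error_rate Per-read sequencing error rate; 0 gives identity 1.0 so
#'   identity-threshold behaviour is exercised explicitly, not by noise.
#' @slot intron_length Integer range of simulated intron lengths, bp.
#' @slot intergenic_gap Integer range of gaps between neighbouring genes, bp.
#' @slot seed Integer seed; a fixed seed makes all outputs byte-identical.
#' @seealso [simConfig()], [simulateExperiment()]
#' @export
setClass("SimConfig",
  slots = c(
    n_genes = "integer", exons_per_gene = "integer",
    spliced_length_range = "integer", p_truncated = "numeric",
    truncation_extent = "numeric", cap_capture = "numeric",
    cap_leakage = "numeric", p_incomplete_synthesis = "numeric",
    three_prime_jitter_sd = "numeric", three_prime_jitter_max = "integer",
    n_reads_per_protocol = "integer", n_molecules = "integer",
    homeolog_identity = "numeric", n_homeolog_triplets = "integer",
    p_homeolog_multi = "numeric", error_rate = "numeric",
    intron_length = "integer", intergenic_gap = "integer", seed = "integer"),
  prototype = list(
    n_genes = 60L, exons_per_gene = c(2L, 9L),
    spliced_length_range = c(800L, 6500L), p_truncated = 0.4,
    truncation_extent = c(0, 0.8), cap_capture = 0.95,
    cap_leakage = 0.02, p_incomplete_synthesis = 0.3,
    three_prime_jitter_sd = 2, three_prime_jitter_max = 10L,
    n_reads_per_protocol = 1000L, n_molecules = NA_integer_,
    homeolog_identity = 0.97, n_homeolog_triplets = 5L,
    p_homeolog_multi = 0.25, error_rate = 0,
    intron_length = c(80L, 3000L), intergenic_gap = c(2000L, 8000L),
    seed = 1L))

setValidity("SimConfig", function(object) {
  msgs <- character()
  pr <- c(p_truncated = object@p_truncated, cap_capture = object@cap_capture,
    cap_leakage = object@cap_leakage,
    p_incomplete_synthesis = object@p_incomplete_synthesis,
    homeolog_identity = object@homeolog_identity,
    p_homeolog_multi = object@p_homeolog_multi, error_rate = object@error_rate)
  bad <- names(pr)[pr < 0 | pr > 1]
  if (length(bad))
    msgs <- c(msgs, paste("probabilities must lie in [0,1]:", paste(bad, collapse = ", ")))
  if (length(object@truncation_extent) != 2L ||
      any(object@truncation_extent < 0) || any(object@truncation_extent > 1) ||
      diff(object@truncation_extent) < 0)
    msgs <- c(msgs, "truncation_extent must be an increasing range within [0,1]")
  for (nm in c("exons_per_gene", "spliced_length_range", "intron_length",
               "intergenic_gap")) {
    r <- slot(object, nm)
    if (length(r) != 2L || any(r <= 0L) || r[2L] < r[1L])
      msgs <- c(msgs, sprintf("%s must be a positive increasing range", nm))
  }
  if (object@n_genes < 1L) msgs <- c(msgs, "n_genes must be >= 1")
  if (object@exons_per_gene[1L] < 1L)
    msgs <- c(msgs, "exons_per_gene must be >= 1")
  if (object@n_reads_per_protocol < 1L)
    msgs <- c(msgs, "n_reads_per_protocol must be >= 1")
  if (object@n_homeolog_triplets < 0L)
    msgs <- c(msgs, "n_homeolog_triplets must be >= 0")
  if (object@n_homeolog_triplets > object@n_genes)
    msgs <- c(msgs, "n_homeolog_triplets cannot exceed n_genes")
  if (object@three_prime_jitter_sd < 0)
    msgs <- c(msgs, "three_prime_jitter_sd must be >= 0")
  if (is.na(object@seed))
    msgs <- c(msgs, "seed must be a non-missing integer")
  if (length(msgs)) msgs else TRUE
})

#' Create a simulator configuration
#'
#' All arguments default to the study conditions described in
#' [SimConfig-class]; pass only what you want to change.
#'
#' @param ... Named slot values, e.g. `n_genes = 40`, `seed = 7`. Numeric
#'   values for integer slots are coerced.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(n_genes = 20, seed = 7)
#' cfg
#' @export
simConfig <- function(...) {
  args <- list(...)
  if (length(args) && (is.null(names(args)) || any(names(args) == "")))
    stop("all arguments to simConfig() must be named")
  sl <- getSlots("SimConfig")
  unknown <- setdiff(names(args), names(sl))
  if (length(unknown))
    stop("unknown SimConfig field(s): ", paste(unknown, collapse = ", "))
  for (nm in names(args))
    if (sl[[nm]] == "integer") args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list("SimConfig"), args))
}
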