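# PAF I/O. PAF is 0-based half-open; records are converted to the package's
# 1-based closed convention on read and back on write. Spliced block
# structure travels in the standard cg:Z: CIGAR tag (M/I/D consume the
# alignment, N spans introns); records without a CIGAR are single-block.

.parseCigar <- function(cig, tstart1) {
  # tstart1: 1-based genomic start; returns IRanges of aligned blocks
  ops <- gregexpr("[0-9]+[MIDNSH=X]", cig)[[1]]
  if (ops[1L] == -1L) stop("unparsable CIGAR: ", cig)
  toks <- regmatches(cig, gregexpr("[0-9]+[MIDNSH=X]", cig))[[1]]
  n <- as.integer(sub("[A-Z=]$", "", toks))
  op <- sub("^[0-9]+", "", toks)
  starts <- integer(0); ends <- integer(0)
  pos <- tstart1; bstart <- NA_integer_
  for (i in seq_along(op)) {
    if (op[i] %in% c("M", "=", "X", "D")) {
      if (is.na(bstart)) bstart <- pos
      pos <- pos + n[i]
    } else if (op[i] == "N") {
      if (!is.na(bstart)) {
        starts <- c(starts, bstart); ends <- c(ends, pos - 1L)
        bstart <- NA_integer_
      }
      pos <- pos + n[i]
    }
    # I, S, H consume no reference
  }
  if (!is.na(bstart)) { starts <- c(starts, bstart); ends <- c(ends, pos - 1L) }
  IRanges::IRanges(starts, ends)
}

.blocksToCigar <- function(blocks) {
  w <- IRanges::width(blocks)
  if (length(w) == 1L) return(sprintf("%dM", w))
  gaps <- IRanges::start(blocks)[-1L] - IRanges::end(blocks)[-length(blocks)] - 1L
  paste0(paste0(w[-length(w)], "M", gaps, "N", collapse = ""),
    w[length(w)], "M")
}

#' Read alignments from a PAF file
#'
#' Parses a standard 12+-column PAF into an [AlignmentSet-class]. Nucleotide
#' identity is computed as residue matches (column 10) divided by alignment
#' block length (column 11). Reads with several alignment lines keep one
#' record per line; the `tp:A:` tag (when present) marks secondary records.
#'
#' @param path Path to a PAF file.
#' @return An [AlignmentSet-class]; records appear in file order.
#' @export
readPAF <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(AlignmentSet(
      data.frame(read_id = character(), read_length = integer(),
        chrom = character(), strand = character(), qstart = integer(),
        qend = integer(), matches = integer(), aln_length = integer(),
        identity = numeric(), is_primary = logical()),
      IRanges::IRangesList()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L))
    stop(sprintf("PAF parse error at line %d: %d column(s), need >= 12",
      which(nf < 12L)[1L], nf[which(nf < 12L)[1L]]))
  alnlen <- vapply(fields, function(f) as.integer(f[11L]), integer(1))
  drop <- alnlen == 0L
  if (any(drop)) {
    warning(sprintf("rejecting %d PAF record(s) with zero alignment length", sum(drop)))
    fields <- fields[!drop]
  }
  if (!length(fields)) stop("no usable PAF records in ", path)
  getcol <- function(k) vapply(fields, `[[`, character(1), k)
  tagval <- function(prefix) vapply(fields, function(f) {
    if (length(f) <= 12L) return(NA_character_)
    hit <- startsWith(f[13:length(f)], prefix)
    if (any(hit)) sub(prefix, "", f[13:length(f)][hit][1L], fixed = TRUE)
    else NA_character_
  }, character(1))
  tstart1 <- as.integer(getcol(8L)) + 1L
  tend <- as.integer(getcol(9L))
  cg <- tagval("cg:Z:")
  blocks <- IRanges::IRangesList(lapply(seq_along(fields), function(i) {
    if (is.na(cg[i])) IRanges::IRanges(tstart1[i], tend[i])
    else .parseCigar(cg[i], tstart1[i])
  }))
  tp <- tagval("tp:A:")
  info <- data.frame(
    read_id = getcol(1L),
    read_length = as.integer(getcol(2L)),
    chrom = getcol(6L),
    strand = getcol(5L),
    qstart = as.integer(getcol(3L)) + 1L,
    qend = as.integer(getcol(4L)),
    matches = as.integer(getcol(10L)),
    aln_length = vapply(fields, function(f) as.integer(f[11L]), integer(1)),
    is_primary = is.na(tp) | tp == "P",
    stringsAsFactors = FALSE)
  AlignmentSet(info, blocks)
}

#' Write an AlignmentSet as PAF
#'
#' Inverse of [readPAF()]: emits one line per record with the spliced block
#' structure in a `cg:Z:` tag and primary/secondary status in `tp:A:`.
#' Chromosome lengths (column 7) are reported as the largest end coordinate
#' seen per chromosome unless supplied.
#'
#' @param alignments An [AlignmentSet-class].
#' @param path Output path.
#' @param chromLengths Optional named integer vector of target lengths.
#' @return `path`, invisibly.
#' @export
writePAF <- function(alignments, path, chromLengths = NULL) {
  info <- alignmentInfo(alignments)
  bl <- alignmentBlocks(alignments)
  if (is.null(chromLengths)) {
    ends <- vapply(seq_along(bl), function(i) max(IRanges::end(bl[[i]])), integer(1))
    chromLengths <- tapply(ends, info$chrom, max)
  }
  lines <- vapply(seq_len(nrow(info)), function(i) {
    b <- bl[[i]]
    paste(info$read_id[i], info$read_length[i], info$qstart[i] - 1L,
      info$qend[i], info$strand[i], info$chrom[i],
      as.integer(chromLengths[[info$chrom[i]]]),
      min(IRanges::start(b)) - 1L, max(IRanges::end(b)),
      info$matches[i], info$aln_length[i], 60L,
      sprintf("tp:A:%s", ifelse(info$is_primary[i], "P", "S")),
      sprintf("cg:Z:%s", .blocksToCigar(b)), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
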