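#' Read a homeolog-group table
#'
#' One group per row, member gene ids in tab-separated columns (the layout of
#' high-confidence homeologous-triplet tables distributed with polyploid
#' genome annotations). Rows with fewer than two ids are skipped with a
#' warning. When an annotation is supplied, member ids absent from it are
#' reported with a message (they stay in the table: reads can still hit
#' them in the alignments).
#'
#' @param path Path to the TSV.
#' @param annotation Optional [GeneAnnotation-class] used to report unknown
#'   ids.
#' @return A data.frame in long form: `group_id` (`HG001`, ... by row order)
#'   and `gene_id`, one row per member.
#' @export
readHomeologTable <- function(path, annotation = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- lapply(strsplit(lines, "\t", fixed = TRUE), function(x) x[nzchar(x)])
  small <- lengths(parts) < 2L
  if (any(small))
    warning(sprintf("skipping %d homeolog row(s) with fewer than 2 gene ids", sum(small)))
  parts <- parts[!small]
  if (!length(parts))
    return(data.frame(group_id = character(), gene_id = character(),
      stringsAsFactors = FALSE))
  dup <- vapply(parts, anyDuplicated, integer(1)) > 0L
  if (any(dup)) {
    warning(sprintf("removing duplicate ids within %d homeolog row(s)", sum(dup)))
    parts <- lapply(parts, unique)
  }
  out <- data.frame(
    group_id = rep(sprintf("HG%03d", seq_along(parts)), lengths(parts)),
    gene_id = unlist(parts, use.names = FALSE),
    stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    known <- unique(geneInfo(annotation)$gene_id)
    missing <- setdiff(out$gene_id, known)
    if (length(missing))
      message(sprintf("%d homeolog gene id(s) absent from the annotation: %s",
        length(missing), paste(utils::head(missing, 5L), collapse = ", ")))
  }
  out
}

#' Write a homeolog-group table
#'
#' @param homeologs Long-form data.frame (`group_id`, `gene_id`) as returned
#'   by [readHomeologTable()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeHomeologTable <- function(homeologs, path) {
  sp <- split(homeologs$gene_id, homeologs$group_id)
  writeLines(vapply(sp, paste, character(1), collapse = "\t"), path)
  invisible(path)
}

# deterministic TSV writer used by all report outputs
writeReportTSV <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA",
    scipen = 50L)
  invisible(path)
}

# run-level JSON summary; fixed field order, no timestamps, full precision
writeRunSummary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE, null = "null", na = "null")
  invisible(path)
}
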