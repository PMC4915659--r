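#' Run the full evaluation pipeline
#'
#' Orchestrates simulate (optional) -> classify -> protocol comparison ->
#' redundancy clustering -> homeolog resolution -> isoform classification and
#' writes all stage tables plus a run-level JSON summary into `outDir`. All
#' randomness flows from the single simulator seed, so a fixed config
#' produces byte-identical outputs.
#'
#' The config is a YAML file (or an equivalent named list) with either a
#' `simulate:` section of [simConfig()] fields, or an `inputs:` section
#' naming a `gff3` annotation, one `paf:` entry per library (named by
#' protocol) and optionally a `homeologs` table. An `options:` section can
#' set `identity_threshold`, `tol5`, `tol3`, `bin_width`, `window`,
#' `junction_fuzz`.
#'
#' @param config Path to a YAML config, or a named list.
#' @param outDir Run directory (created; existing files are overwritten).
#' @param seed Optional integer overriding the simulator seed.
#' @param identityThreshold,tol5,tol3,binWidth,window Optional overrides of
#'   the corresponding config options.
#' @return The run summary (also written as `summary.json`), invisibly.
#' @examples
#' \donttest{
#' out <- file.path(tempdir(), "capfl-run")
#' s <- runPipeline(list(simulate = list(n_genes = 12, n_reads_per_protocol = 60,
#'   seed = 7)), out)
#' s$protocols$cap_dependent$fl_pct_overall
#' }
#' @export
runPipeline <- function(config, outDir, seed = NULL,
                        identityThreshold = NULL, tol5 = NULL, tol3 = NULL,
                        binWidth = NULL, window = NULL) {
  cfg_path <- NULL
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("no such config file: ", config)
    cfg_path <- config
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path")
  opts <- config$options
  opt <- function(override, name, default)
    if (!is.null(override)) override else if (!is.null(opts[[name]])) opts[[name]] else default
  identityThreshold <- opt(identityThreshold, "identity_threshold", 0.90)
  tol5 <- opt(tol5, "tol5", 100)
  tol3 <- opt(tol3, "tol3", 5)
  binWidth <- opt(binWidth, "bin_width", 50)
  window <- opt(window, "window", 10000)
  fuzz <- opt(NULL, "junction_fuzz", 0)

  # resolve inputs before any stage runs
  if (!is.null(config$simulate)) {
    simargs <- config$simulate
    if (!is.null(seed)) simargs$seed <- seed
    scfg <- do.call(simConfig, simargs)
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    paths <- c(inp$gff3, unlist(inp$paf), inp$homeologs)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("missing input file(s): ", paste(missing, collapse = ", "))
  } else stop("config needs a 'simulate' or an 'inputs' section")

  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(cfg_path))
    file.copy(cfg_path, file.path(outDir, "config.yaml"), overwrite = TRUE)

  if (!is.null(config$simulate)) {
    message("stage simulate: seed ", scfg@seed)
    sim <- simulateExperiment(scfg)
    writeSimulation(sim, file.path(outDir, "sim"))
    annotation <- sim$annotation
    homeologs <- if (nrow(sim$homeologs)) sim$homeologs else NULL
    alnsets <- lapply(sim$libraries, `[[`, "alignments")
    truths <- lapply(sim$libraries, `[[`, "truth")
  } else {
    annotation <- readGFF3Genes(inp$gff3)
    homeologs <- if (!is.null(inp$homeologs))
      readHomeologTable(inp$homeologs, annotation) else NULL
    alnsets <- lapply(inp$paf, readPAF)
    if (is.null(names(alnsets)) || any(!nzchar(names(alnsets))))
      names(alnsets) <- sprintf("library_%d", seq_along(alnsets))
    truths <- NULL
  }

  summary <- list(
    options = list(identity_threshold = identityThreshold, tol5 = tol5,
      tol3 = tol3, bin_width = binWidth, window = window,
      junction_fuzz = fuzz),
    protocols = list())
  if (!is.null(config$simulate))
    summary$sim_config <- stats::setNames(
      lapply(slotNames(scfg), function(s) slot(scfg, s)), slotNames(scfg))

  assignments <- list()
  for (p in names(alnsets)) {
    message("stage classify: ", p)
    manifest <- if (!is.null(truths)) truths[[p]]$read_id else NULL
    asg <- classifyReads(alnsets[[p]], annotation,
      identityThreshold = identityThreshold, manifest = manifest)
    assignments[[p]] <- asg
    writeReportTSV(asg, file.path(outDir, paste0(p, ".assignments.tsv")))

    fl <- summarizeFullLength(asg)
    writeReportTSV(fl, file.path(outDir, paste0(p, ".fl_summary.tsv")))

    message("stage redundancy: ", p)
    cl <- clusterEnds(asg, tol5 = tol5, tol3 = tol3)
    writeReportTSV(cl, file.path(outDir, paste0(p, ".clusters.tsv")))
    red <- if (nrow(cl)) redundancyFraction(cl) else NA_real_

    message("stage isoforms: ", p)
    keptu <- .uniqueKept(alnsets[[p]], identityThreshold)
    iso <- classifyIsoforms(keptu, annotation, fuzz = fuzz)
    writeReportTSV(iso, file.path(outDir, paste0(p, ".isoforms.tsv")))
    isosum <- summarizeClasses(iso, asg, annotation)

    ucount <- table(asg$uniqueness)
    summary$protocols[[p]] <- list(
      n_reads = nrow(asg),
      uniqueness = as.list(stats::setNames(as.integer(ucount), names(ucount))),
      fl_pct_overall = fl$fl_pct[fl$size_fraction == "overall"],
      fl_by_fraction = as.list(stats::setNames(fl$fl_pct, fl$size_fraction)),
      redundancy_pct = red,
      n_clusters = nrow(cl),
      isoform_classes = as.list(isosum$class_counts),
      isoform_distinct_genes = as.list(isosum$distinct_genes))
  }

  if (!is.null(homeologs) && nrow(homeologs)) {
    message("stage homeologs")
    hsum <- list()
    for (p in names(alnsets)) {
      flags <- flagHomeologHits(alnsets[[p]], annotation, homeologs)
      multi <- flags$read_id[flags$multi_homeolog]
      sel <- alignmentInfo(alnsets[[p]])$read_id %in% multi
      resol <- resolveBestMatch(alnsets[[p]][sel], annotation,
        identityThreshold = identityThreshold)
      writeReportTSV(merge(flags, resol, by = "read_id", all.x = TRUE),
        file.path(outDir, paste0(p, ".homeologs.tsv")))
      hsum[[p]] <- summarizeHomeologResolution(flags, resol)
    }
    summary$homeologs <- hsum
  } else {
    message("stage homeologs: no homeolog table; skipped")
  }

  if (length(alnsets) == 2L) {
    message("stage compare")
    pn <- names(alnsets)
    cmp <- compareProtocols(assignments[[1L]], assignments[[2L]],
      labelA = pn[1L], labelB = pn[2L])
    writeReportTSV(cmp$tests, file.path(outDir, "comparison.tsv"))
    summary$comparison <- list(
      labels = pn,
      fl_overall = as.list(cmp$fl_overall),
      tests = lapply(seq_len(nrow(cmp$tests)), function(i)
        as.list(cmp$tests[i, ])))
  }

  writeRunSummary(summary, file.path(outDir, "summary.json"))
  invisible(summary)
}

# identity-filtered records of unique-mapping reads
.uniqueKept <- function(alignments, identityThreshold = 0.90) {
  fl <- filterIdentity(alignments, identityThreshold)
  part <- partitionMultiplicity(fl$kept, fl$rejected)
  uids <- part$read_id[part$uniqueness == "unique"]
  fl$kept[alignmentInfo(fl$kept)$read_id %in% uids]
}
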