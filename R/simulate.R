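# Synthetic two-chemistry library simulator. The generative model:
#   1. a toy multi-exon annotation (both strands, >= 2 chromosomes), with
#      homeolog triplets made by copying gene structures onto sister
#      chromosomes;
#   2. an mRNA pool with log-normal gene abundances in which a configurable
#      fraction of molecules has lost part of its 5' end (degradation /
#      shearing) and is therefore uncapped;
#   3. capture: the cap-dependent chemistry takes capped molecules with high
#      probability and uncapped ones only as leakage; template switching is
#      cap-blind and additionally inflicts an extra 5' loss (incomplete cDNA
#      synthesis) on a share of molecules;
#   4. oligo-dT 3' priming with small symmetric end jitter;
#   5. reads emitted as spliced PAF alignments over the toy genome, with full
#      per-read ground truth.
# Every stage draws its randomness from a seed derived from config@seed, so a
# fixed config reproduces byte-identical outputs.

# remove `b` bases from the genomic left / right edge of a sorted exon chain
.dropLeft <- function(starts, ends, b) {
  if (b <= 0L) return(list(starts = starts, ends = ends))
  w <- ends - starts + 1L
  cum <- cumsum(w)
  k <- which(cum > b)[1L]
  if (is.na(k)) stop("cannot remove more bases than the chain holds")
  before <- if (k == 1L) 0L else cum[k - 1L]
  starts <- starts[k:length(starts)]
  ends <- ends[k:length(ends)]
  starts[1L] <- starts[1L] + (b - before)
  list(starts = starts, ends = ends)
}

.dropRight <- function(starts, ends, b) {
  if (b <= 0L) return(list(starts = starts, ends = ends))
  w <- rev(ends - starts + 1L)
  cum <- cumsum(w)
  k <- which(cum > b)[1L]
  if (is.na(k)) stop("cannot remove more bases than the chain holds")
  before <- if (k == 1L) 0L else cum[k - 1L]
  n <- length(starts)
  starts <- starts[1:(n - k + 1L)]
  ends <- ends[1:(n - k + 1L)]
  ends[length(ends)] <- ends[length(ends)] - (b - before)
  list(starts = starts, ends = ends)
}

# walk an exon chain in transcript orientation: remove lost5 from the 5' end,
# lost3 from the 3' end, extend the 3' terminus by ext3 beyond the TES
.trimExonChain <- function(starts, ends, strand, lost5 = 0L, lost3 = 0L,
                           ext3 = 0L) {
  if (strand == "+") {
    ch <- .dropLeft(starts, ends, lost5)
    ch <- .dropRight(ch$starts, ch$ends, lost3)
    if (ext3 > 0L) ch$ends[length(ch$ends)] <- ch$ends[length(ch$ends)] + ext3
  } else {
    ch <- .dropRight(starts, ends, lost5)
    ch <- .dropLeft(ch$starts, ch$ends, lost3)
    if (ext3 > 0L) ch$starts[1L] <- ch$starts[1L] - ext3
  }
  IRanges::IRanges(ch$starts, ch$ends)
}

# exon lengths summing to L with a 30 bp floor per exon
.exonLengths <- function(L, k, minExon = 30L) {
  if (k == 1L) return(L)
  extra <- L - minExon * k
  if (extra < 0L) stop("spliced length too small for ", k, " exons")
  cuts <- sort(stats::runif(k - 1L))
  piece <- floor(diff(c(0, cuts, 1)) * extra)
  piece[k] <- extra - sum(piece[-k])
  as.integer(minExon + piece)
}

#' Generate a toy annotation with homeolog triplets
#'
#' Places `n_genes` non-overlapping multi-exon gene models on two base
#' chromosomes (`chr1A`, `chr2A`; strands alternate), then copies the first
#' `n_homeolog_triplets` gene structures onto sister chromosomes (`B` and `D`
#' subgenomes) and registers each original/copy trio as a homeolog group.
#' Copies share the exon geometry of their source, so a read from one locus
#' has an equally spliced candidate alignment at its sisters.
#'
#' @param config A [SimConfig-class]; uses `config@seed` (annotation stage).
#' @return list with `annotation` ([GeneAnnotation-class]) and `homeologs`
#'   (long-form data.frame `group_id`/`gene_id`; zero rows when no triplets).
#' @export
generateAnnotation <- function(config = simConfig()) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed)
  ng <- config@n_genes
  kr <- config@exons_per_gene
  lr <- config@spliced_length_range
  cursors <- new.env(parent = emptyenv())
  place <- function(chrom, widths, introns) {
    cur <- if (is.null(cursors[[chrom]])) 0L else cursors[[chrom]]
    gap <- sample(config@intergenic_gap[1L]:config@intergenic_gap[2L], 1L)
    start <- cur + gap
    starts <- integer(length(widths)); ends <- integer(length(widths))
    pos <- start
    for (j in seq_along(widths)) {
      starts[j] <- pos
      ends[j] <- pos + widths[j] - 1L
      pos <- ends[j] + 1L + if (j < length(widths)) introns[j] else 0L
    }
    cursors[[chrom]] <- ends[length(ends)]
    IRanges::IRanges(starts, ends)
  }
  structures <- vector("list", ng)
  exlist <- list()
  gene_ids <- character()
  base_chrom <- rep(c("chr1A", "chr2A"), length.out = ng)
  base_strand <- rep(c("+", "-"), length.out = ng)
  for (i in seq_len(ng)) {
    k <- sample(kr[1L]:kr[2L], 1L)
    L <- sample(lr[1L]:lr[2L], 1L)
    widths <- .exonLengths(L, k)
    introns <- if (k > 1L) sample(config@intron_length[1L]:config@intron_length[2L],
      k - 1L, replace = TRUE) else integer(0)
    structures[[i]] <- list(widths = widths, introns = introns)
    gid <- sprintf("G%03d", i)
    tid <- paste0(gid, ".1")
    rg <- place(base_chrom[i], widths, introns)
    exlist[[tid]] <- GenomicRanges::GRanges(base_chrom[i], rg, base_strand[i])
    gene_ids[tid] <- gid
  }
  hom <- data.frame(group_id = character(), gene_id = character(),
    stringsAsFactors = FALSE)
  if (config@n_homeolog_triplets > 0L) {
    rows <- list()
    for (t in seq_len(config@n_homeolog_triplets)) {
      src_gid <- sprintf("G%03d", t)
      members <- src_gid
      for (sub in c("B", "D")) {
        chrom <- sub("A$", sub, base_chrom[t])
        gid <- paste0(src_gid, sub)
        tid <- paste0(gid, ".1")
        rg <- place(chrom, structures[[t]]$widths, structures[[t]]$introns)
        exlist[[tid]] <- GenomicRanges::GRanges(chrom, rg, base_strand[t])
        gene_ids[tid] <- gid
        members <- c(members, gid)
      }
      rows[[t]] <- data.frame(group_id = sprintf("HG%03d", t),
        gene_id = members, stringsAsFactors = FALSE)
    }
    hom <- do.call(rbind, rows)
  }
  ann <- GeneAnnotation(methods::as(GenomicRanges::GRangesList(exlist), "GRangesList"),
    geneIds = gene_ids)
  list(annotation = ann, homeologs = hom)
}

#' Simulate an mRNA pool over an annotation
#'
#' Draws molecules from the annotated transcripts with log-normal abundance
#' weights. With probability `p_truncated` a molecule loses a
#' `truncation_extent` share of its 5' end (and with it its cap); intact
#' molecules are capped and full length.
#'
#' @param annotation A [GeneAnnotation-class].
#' @param config A [SimConfig-class]; uses `config@seed` (pool stage).
#' @param n Pool size; default `config@n_molecules`, or
#'   `4 * config@n_reads_per_protocol` when that is `NA`.
#' @return data.frame, one row per molecule: `molecule_id`, `transcript_id`,
#'   `gene_id`, `spliced_length`, `capped`, `bases_lost_5p`.
#' @export
simulateMolecules <- function(annotation, config = simConfig(), n = NULL) {
  stopifnot(is(annotation, "GeneAnnotation"), length(annotation) > 0L)
  validObject(config)
  if (is.null(n))
    n <- if (is.na(config@n_molecules)) 4L * config@n_reads_per_protocol
         else config@n_molecules
  set.seed(config@seed + 1L)
  an <- geneInfo(annotation)
  w <- stats::rlnorm(nrow(an), meanlog = 0, sdlog = 1)
  idx <- sample.int(nrow(an), n, replace = TRUE, prob = w)
  spl <- an$spliced_length[idx]
  capped <- stats::runif(n) >= config@p_truncated
  frac <- stats::runif(n, config@truncation_extent[1L], config@truncation_extent[2L])
  lost5 <- ifelse(capped, 0L,
    pmin(pmax(1L, as.integer(floor(frac * spl))), pmax(spl - 50L, 1L)))
  data.frame(
    molecule_id = sprintf("m%06d", seq_len(n)),
    transcript_id = an$transcript_id[idx],
    gene_id = an$gene_id[idx],
    spliced_length = spl,
    capped = capped,
    bases_lost_5p = as.integer(lost5),
    stringsAsFactors = FALSE)
}

#' Simulate one sequencing library from a molecule pool
#'
#' Applies the protocol's capture rule, the extra template-switch 5' loss,
#' and 3' oligo-dT jitter, then emits each captured molecule as a spliced
#' alignment over the toy genome together with its ground truth. Reads from
#' homeolog-group loci additionally report secondary alignments at the sister
#' loci for a `p_homeolog_multi` share of reads, with the alignment length
#' shortened by `(1 - homeolog_identity) * read_length` — the signal the
#' best-match resolution filter works on.
#'
#' @param molecules Pool from [simulateMolecules()].
#' @param protocol `"cap_dependent"` or `"template_switch"`.
#' @param annotation The [GeneAnnotation-class] the pool was drawn from.
#' @param config A [SimConfig-class]; uses `config@seed` (library stage, one
#'   stream per protocol).
#' @param homeologs Long-form homeolog table (`group_id`/`gene_id`) or NULL.
#' @return list with `alignments` ([AlignmentSet-class]) and `truth`
#'   (data.frame, one row per read: `read_id`, `gene_id`, `transcript_id`,
#'   `protocol`, `capped`, `bases_lost_5p`, `bases_lost_3p`,
#'   `three_prime_ext`, `spliced_length`, `read_length`, `size_fraction`,
#'   `n_secondary`).
#' @export
simulateLibrary <- function(molecules, protocol = c("cap_dependent", "template_switch"),
                            annotation, config = simConfig(), homeologs = NULL) {
  protocol <- match.arg(protocol)
  validObject(config)
  stopifnot(is.data.frame(molecules), nrow(molecules) > 0L)
  set.seed(config@seed + if (protocol == "cap_dependent") 2L else 3L)
  n0 <- nrow(molecules)
  u <- stats::runif(n0)
  keep <- if (protocol == "cap_dependent") {
    ifelse(molecules$capped, u < config@cap_capture, u < config@cap_leakage)
  } else rep(TRUE, n0)
  if (!any(keep))
    stop("no molecules captured under ", protocol,
      "; enlarge the molecule pool (n_molecules) or raise capture rates")
  cap <- molecules[keep, , drop = FALSE]
  nr <- config@n_reads_per_protocol
  if (nrow(cap) >= nr) {
    cap <- cap[sample.int(nrow(cap), nr), , drop = FALSE]
  } else {
    warning(sprintf("%s: only %d molecules captured, fewer than n_reads_per_protocol = %d",
      protocol, nrow(cap), nr))
  }
  n <- nrow(cap)
  lost5 <- cap$bases_lost_5p
  spl <- cap$spliced_length
  if (protocol == "template_switch" && config@p_incomplete_synthesis > 0) {
    hit <- stats::runif(n) < config@p_incomplete_synthesis
    frac <- stats::runif(n, config@truncation_extent[1L], config@truncation_extent[2L])
    room <- pmax(spl - lost5 - 50L, 0L)
    extra <- ifelse(hit, pmin(pmax(1L, as.integer(floor(frac * (spl - lost5)))), room), 0L)
    extra[room == 0L] <- 0L
    lost5 <- lost5 + as.integer(extra)
  }
  if (config@three_prime_jitter_sd > 0) {
    j <- as.integer(round(stats::rnorm(n, 0, config@three_prime_jitter_sd)))
    j <- pmin(pmax(j, -config@three_prime_jitter_max), config@three_prime_jitter_max)
  } else j <- integer(n)
  lost3 <- pmax(0L, -j)
  lost3 <- pmin(lost3, pmax(spl - lost5 - 50L, 0L))
  ext3 <- pmax(0L, j)
  read_length <- spl - lost5 - lost3 + ext3
  prot_tag <- if (protocol == "cap_dependent") "cd" else "ts"
  read_id <- sprintf("%s_%05d", prot_tag, seq_len(n))

  an <- geneInfo(annotation)
  ex <- exonRanges(annotation)
  exStarts <- lapply(seq_along(ex), function(i) GenomicRanges::start(ex[[i]]))
  exEnds <- lapply(seq_along(ex), function(i) GenomicRanges::end(ex[[i]]))
  names(exStarts) <- names(exEnds) <- an$transcript_id
  tx_of_gene <- stats::setNames(an$transcript_id, an$gene_id)
  strand_of_tx <- stats::setNames(an$strand, an$transcript_id)
  chrom_of_tx <- stats::setNames(an$chrom, an$transcript_id)

  sisters <- list()
  if (!is.null(homeologs) && nrow(homeologs)) {
    sp <- split(homeologs$gene_id, homeologs$group_id)
    for (grp in sp) for (g in grp) sisters[[g]] <- setdiff(grp, g)
  }
  multi <- if (length(sisters)) {
    (cap$gene_id %in% names(sisters)) & (stats::runif(n) < config@p_homeolog_multi)
  } else rep(FALSE, n)

  matches <- as.integer(round((1 - config@error_rate) * read_length))
  info_rows <- vector("list", n)
  block_rows <- vector("list", n)
  n_secondary <- integer(n)
  for (i in seq_len(n)) {
    tid <- cap$transcript_id[i]
    strand <- strand_of_tx[[tid]]
    prim <- .trimExonChain(exStarts[[tid]], exEnds[[tid]], strand,
      lost5 = lost5[i], lost3 = lost3[i], ext3 = ext3[i])
    rows <- data.frame(read_id = read_id[i], read_length = read_length[i],
      chrom = chrom_of_tx[[tid]], strand = strand, qstart = 1L,
      qend = read_length[i], matches = matches[i],
      aln_length = read_length[i], is_primary = TRUE,
      stringsAsFactors = FALSE)
    blocks <- list(prim)
    if (multi[i]) {
      red <- max(1L, as.integer(round((1 - config@homeolog_identity) * read_length[i])))
      aln_sec <- read_length[i] - red
      if (aln_sec >= 50L) {
        for (sg in sisters[[cap$gene_id[i]]]) {
          stid <- tx_of_gene[[sg]]
          sec <- .trimExonChain(exStarts[[stid]], exEnds[[stid]], strand_of_tx[[stid]],
            lost5 = lost5[i], lost3 = spl[i] - lost5[i] - aln_sec, ext3 = 0L)
          rows <- rbind(rows, data.frame(read_id = read_id[i],
            read_length = read_length[i], chrom = chrom_of_tx[[stid]],
            strand = strand_of_tx[[stid]], qstart = 1L, qend = aln_sec,
            matches = as.integer(round(config@homeolog_identity * aln_sec)),
            aln_length = aln_sec, is_primary = FALSE,
            stringsAsFactors = FALSE))
          blocks <- c(blocks, list(sec))
          n_secondary[i] <- n_secondary[i] + 1L
        }
      }
    }
    info_rows[[i]] <- rows
    block_rows[[i]] <- blocks
  }
  info <- do.call(rbind, info_rows)
  blocks <- IRanges::IRangesList(do.call(c, block_rows))
  aln <- AlignmentSet(info, blocks)
  truth <- data.frame(
    read_id = read_id, gene_id = cap$gene_id, transcript_id = cap$transcript_id,
    protocol = protocol, capped = cap$capped, bases_lost_5p = lost5,
    bases_lost_3p = lost3, three_prime_ext = ext3, spliced_length = spl,
    read_length = read_length,
    size_fraction = assignSizeFraction(read_length),
    n_secondary = n_secondary,
    stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(alignments = aln, truth = truth)
}

#' Simulate a full two-chemistry experiment
#'
#' Generates the annotation and homeolog triplets, draws one shared mRNA pool
#' (both libraries are prepared from the same RNA), and sequences it once
#' with the cap-dependent chemistry and once by template switching.
#'
#' @param config A [SimConfig-class].
#' @return list with `annotation`, `homeologs`, `config` and `libraries`
#'   (named list of [simulateLibrary()] results, one per protocol).
#' @examples
#' sim <- simulateExperiment(simConfig(n_genes = 12, n_reads_per_protocol = 50,
#'   n_homeolog_triplets = 2, seed = 7))
#' sapply(sim$libraries, function(l) nrow(l$truth))
#' @export
simulateExperiment <- function(config = simConfig()) {
  validObject(config)
  gen <- generateAnnotation(config)
  mol <- simulateMolecules(gen$annotation, config)
  libs <- lapply(c(cap_dependent = "cap_dependent",
                   template_switch = "template_switch"),
    function(p) simulateLibrary(mol, p, gen$annotation, config, gen$homeologs))
  list(annotation = gen$annotation, homeologs = gen$homeologs,
    config = config, libraries = libs)
}

#' Write a simulated experiment to disk
#'
#' Emits `annotation.gff3`, `homeologs.tsv`, one PAF and one truth TSV per
#' protocol, and `config.json`. Outputs are byte-deterministic for a fixed
#' config.
#'
#' @param sim Result of [simulateExperiment()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(annotation = file.path(dir, "annotation.gff3"),
    homeologs = file.path(dir, "homeologs.tsv"),
    config = file.path(dir, "config.json"))
  writeGFF3Genes(sim$annotation, paths[["annotation"]])
  writeHomeologTable(sim$homeologs, paths[["homeologs"]])
  an <- geneInfo(sim$annotation)
  chromLengths <- tapply(an$span_end + 20000L, an$chrom, max)
  for (p in names(sim$libraries)) {
    paf <- file.path(dir, paste0(p, ".paf"))
    tru <- file.path(dir, paste0(p, ".truth.tsv"))
    writePAF(sim$libraries[[p]]$alignments, paf, chromLengths = chromLengths)
    writeReportTSV(sim$libraries[[p]]$truth, tru)
    paths[[paste0(p, "_paf")]] <- paf
    paths[[paste0(p, "_truth")]] <- tru
  }
  cfg <- sim$config
  cfg_list <- stats::setNames(lapply(slotNames(cfg), function(s) slot(cfg, s)),
    slotNames(cfg))
  writeRunSummary(cfg_list, paths[["config"]])
  invisible(paths)
}
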