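# End-tolerant redundancy clustering: reads of the same locus whose 5' ends
# agree within tol5 bp and 3' ends within tol3 bp (both inclusive) are
# putatively redundant observations of the same molecule. Clusters are the
# connected components of the pairwise both-tolerances graph (single
# linkage), so chains can span more than one tolerance width end to end; the
# estimate is therefore an upper bound on redundancy at the given tolerances.

# union-find over pairs within a 5'-sorted sliding window; any edge has
# |d5| <= tol5, so limiting j to that window loses no edges
.componentsByTolerance <- function(e5, e3, tol5, tol3) {
  n <- length(e5)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  ord <- order(e5, e3)
  for (a in seq_len(n - 1L)) {
    i <- ord[a]
    for (b in (a + 1L):n) {
      j <- ord[b]
      if (e5[j] - e5[i] > tol5) break
      if (abs(e3[j] - e3[i]) <= tol3) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Cluster reads by 5'/3' end agreement
#'
#' Within each locus group (assigned reads: `gene_id` + strand; unassigned
#' unique reads: connected overlap groups on the same chromosome and strand),
#' reads whose transcript-oriented 5' ends differ by at most `tol5` bp and 3'
#' ends by at most `tol3` bp (both inclusive) are linked; clusters are the
#' connected components of that graph. The representative is the longest
#' member (ties broken by read id).
#'
#' @param assignments [classifyReads()] table; only `unique` reads are used.
#' @param tol5 5'-end tolerance in bp, default 100.
#' @param tol3 3'-end tolerance in bp, default 5.
#' @return data.frame with one row per cluster: `cluster_id`, `gene_id`
#'   (`NA` for overlap-grouped unassigned reads), `strand`, `n_members`,
#'   `representative`, `members` (comma-separated read ids).
#' @export
clusterEnds <- function(assignments, tol5 = 100, tol3 = 5) {
  if (tol5 < 0 || tol3 < 0) stop("tolerances must be non-negative")
  a <- assignments[assignments$uniqueness == "unique" & !is.na(assignments$e5), ]
  if (!nrow(a))
    return(data.frame(cluster_id = character(), gene_id = character(),
      strand = character(), n_members = integer(),
      representative = character(), members = character(),
      stringsAsFactors = FALSE))
  a <- a[order(a$read_id), , drop = FALSE]
  grp <- ifelse(is.na(a$gene_id), NA_character_,
    paste(a$gene_id, a$strand, sep = "/"))
  # unassigned reads: group by genomic overlap on (chrom, strand)
  un <- which(is.na(grp))
  if (length(un)) {
    gr <- GenomicRanges::GRanges(a$chrom[un],
      IRanges::IRanges(a$read_left[un], a$read_right[un]), a$strand[un])
    red <- GenomicRanges::reduce(gr, ignore.strand = FALSE)
    hit <- GenomicRanges::findOverlaps(gr, red, select = "first")
    grp[un] <- paste0("overlap_group_", hit, "/", a$strand[un])
  }
  out <- list()
  for (g in unique(grp)) {
    sel <- which(grp == g)
    comp <- .componentsByTolerance(a$e5[sel], a$e3[sel], tol5, tol3)
    for (cid in unique(comp)) {
      mem <- sel[comp == cid]
      len <- a$read_length[mem]
      rep_id <- a$read_id[mem][order(-len, a$read_id[mem])][1L]
      out[[length(out) + 1L]] <- data.frame(
        gene_id = a$gene_id[mem[1L]], strand = a$strand[mem[1L]],
        n_members = length(mem), representative = rep_id,
        members = paste(sort(a$read_id[mem]), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$members), , drop = FALSE]
  res <- cbind(cluster_id = sprintf("C%05d", seq_len(nrow(res))), res)
  rownames(res) <- NULL
  res
}

#' Redundancy percentage from end clusters
#'
#' `100 * (n_reads - n_clusters) / n_reads`: the share of reads that are
#' putatively redundant with an earlier read of their cluster. Zero when
#' every cluster is a singleton.
#'
#' @param clusters Result of [clusterEnds()].
#' @return Percentage in `[0, 100]`.
#' @export
redundancyFraction <- function(clusters) {
  n_reads <- sum(clusters$n_members)
  if (!n_reads) stop("no reads in clusters")
  100 * (n_reads - nrow(clusters)) / n_reads
}
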