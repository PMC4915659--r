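#' Histogram of signed end offsets around an anchor
#'
#' Bins signed 5' or 3' offsets into half-open `binWidth` bins with one bin
#' edge exactly at 0 (the annotated TSS or TES), inside a symmetric `window`;
#' offsets outside the window are tallied separately. Mirrors the density
#' panels used to compare library chemistries: mass at or upstream of the TSS
#' indicates capture of genuine transcript starts.
#'
#' @param offsets Integer vector of signed offsets (bp).
#' @param anchor `"TSS"` or `"TES"`.
#' @param sizeFraction Optional label carried into the result.
#' @param binWidth Bin width in bp, default 50.
#' @param window Half-window in bp, default 10000 (offsets with
#'   `|offset| <= window` are binned).
#' @return An object of class `OffsetProfile`: list with `anchor`,
#'   `size_fraction`, `bin_width`, `window`, `breaks`, `counts` (named by
#'   lower bin edge), `n_in_window`, `n_outside`, and
#'   `fraction_at_or_upstream` (TSS) or `fraction_at_or_downstream` (TES),
#'   computed over all supplied offsets.
#' @export
buildProfile <- function(offsets, anchor = c("TSS", "TES"), sizeFraction = NA,
                         binWidth = 50, window = 10000) {
  anchor <- match.arg(anchor)
  if (length(binWidth) != 1L || is.na(binWidth) || binWidth <= 0)
    stop("binWidth must be a positive number")
  if (window <= 0) stop("window must be positive")
  offsets <- offsets[!is.na(offsets)]
  half <- ceiling(window / binWidth)
  # one extra top bin so an offset exactly at +window has a [lo, hi) home
  breaks <- seq.int(-half, half + 1L) * binWidth
  inside <- abs(offsets) <= window
  idx <- findInterval(offsets[inside], breaks, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  names(counts) <- breaks[-length(breaks)]
  out <- list(anchor = anchor, size_fraction = sizeFraction,
    bin_width = binWidth, window = window, breaks = breaks, counts = counts,
    n_in_window = sum(inside), n_outside = sum(!inside))
  if (anchor == "TSS") {
    out$fraction_at_or_upstream <- if (length(offsets)) mean(offsets <= 0) else NA_real_
  } else {
    out$fraction_at_or_downstream <- if (length(offsets)) mean(offsets >= 0) else NA_real_
  }
  structure(out, class = "OffsetProfile")
}

#' @export
print.OffsetProfile <- function(x, ...) {
  cat(sprintf("OffsetProfile at %s (fraction %s): %d in +/-%d bp window, %d outside; bin %d bp\n",
    x$anchor, as.character(x$size_fraction), x$n_in_window, x$window,
    x$n_outside, x$bin_width))
  invisible(x)
}

# exact two-sided p by enumeration of all C(n+m, n) group labelings of the
# pooled midranks: p = Pr(min(Ua, Ub) <= observed min)
.mwEnumerate <- function(r, n, Uobs) {
  N <- length(r)
  m <- N - n
  sets <- utils::combn(N, n)
  ua <- colSums(matrix(r[sets], nrow = n)) - n * (n + 1) / 2
  stat <- pmin(ua, n * m - ua)
  mean(stat <= Uobs + 1e-9)
}

#' Mann-Whitney U test (exact or tie-corrected normal)
#'
#' U counts pairs `(a, b)` with `a < b`, ties counted one half; the reported
#' statistic is `min(U_a, U_b)`. The exact two-sided p-value is the
#' permutation probability of a statistic at least as extreme, obtained by
#' full enumeration of all `choose(n + m, n)` labelings when that count is at
#' most `1e5`; for larger tie-free samples the same exact null is evaluated
#' with [stats::pwilcox()]. The normal approximation uses the tie-corrected
#' variance and a 0.5 continuity correction. Mode `"auto"` enumerates when
#' feasible and otherwise uses the normal approximation.
#'
#' @param a,b Numeric samples, both non-empty.
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @return list with `U`, `U_a`, `U_b`, `p_value`, `method`.
#' @examples
#' mannWhitney(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1 by enumeration
#' @export
mannWhitney <- function(a, b, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  n <- length(a); m <- length(b); N <- n + m
  r <- rank(c(a, b))
  Ua <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  Ub <- n * m - Ua
  U <- min(Ua, Ub)
  ties <- any(duplicated(c(a, b)))
  feasible <- choose(N, n) <= 1e5
  method <- NULL
  if (mode == "normal_approx") {
    method <- "normal_approx"
  } else if (feasible) {
    method <- "exact_enumeration"
  } else if (mode == "exact") {
    if (!ties) method <- "exact_pwilcox"
    else {
      warning("exact enumeration infeasible for tied samples of this size; ",
        "using the tie-corrected normal approximation")
      method <- "normal_approx"
    }
  } else {
    method <- "normal_approx"
  }
  p <- switch(method,
    exact_enumeration = .mwEnumerate(r, n, U),
    exact_pwilcox = min(1, 2 * stats::pwilcox(U, n, m)),
    normal_approx = {
      tt <- table(c(a, b))
      sigma2 <- n * m / 12 * ((N + 1) - sum(tt^3 - tt) / (N * (N - 1)))
      if (sigma2 <= 0) 1
      else min(1, 2 * stats::pnorm((U - n * m / 2 + 0.5) / sqrt(sigma2)))
    })
  list(U = U, U_a = Ua, U_b = Ub, p_value = p, method = method)
}

#' Compare two protocols' end offsets and full-length rates
#'
#' For each size fraction and each anchor (5' offsets at the TSS, 3' offsets
#' at the TES) this tabulates sample sizes, median offsets, the Mann-Whitney
#' U and p-value between the two protocols, and per-protocol full-length
#' percentages; whole-run FL percentages are attached. Only unique,
#' gene-assigned reads enter. A fraction empty in either protocol yields a
#' row with `p_value = NA` and a warning.
#'
#' @param assignmentsA,assignmentsB [classifyReads()] tables for the two
#'   protocols.
#' @param labelA,labelB Protocol display names.
#' @param mode Test mode passed to [mannWhitney()].
#' @param bonferroni If TRUE, add a `p_adj` column (Bonferroni over the
#'   emitted tests); off by default.
#' @return list of class `protocolComparison`: `tests` (data.frame per
#'   anchor x fraction), `fl_overall` (named numeric, percent), `labels`.
#' @export
compareProtocols <- function(assignmentsA, assignmentsB,
                             labelA = "cap_dependent",
                             labelB = "template_switch",
                             mode = "auto", bonferroni = FALSE) {
  ua <- assignmentsA[assignmentsA$uniqueness == "unique" & !is.na(assignmentsA$gene_id), ]
  ub <- assignmentsB[assignmentsB$uniqueness == "unique" & !is.na(assignmentsB$gene_id), ]
  fracs <- intersect(sizeFractionLevels(),
    unique(c(ua$size_fraction, ub$size_fraction)))
  rows <- list()
  for (anchor in c("TSS", "TES")) {
    col <- if (anchor == "TSS") "five_prime_offset" else "three_prime_offset"
    for (f in fracs) {
      xa <- ua[ua$size_fraction == f, col]
      xb <- ub[ub$size_fraction == f, col]
      fa <- ua$is_full_length[ua$size_fraction == f]
      fb <- ub$is_full_length[ub$size_fraction == f]
      if (!length(xa) || !length(xb)) {
        warning(sprintf("size fraction %s empty for one protocol; p set to NA", f))
        tst <- list(U = NA_real_, p_value = NA_real_, method = NA_character_)
      } else {
        tst <- mannWhitney(xa, xb, mode = mode)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        anchor = anchor, size_fraction = f,
        n_a = length(xa), n_b = length(xb),
        median_a = if (length(xa)) stats::median(xa) else NA_real_,
        median_b = if (length(xb)) stats::median(xb) else NA_real_,
        U = tst$U, p_value = tst$p_value, method = tst$method,
        fl_pct_a = if (length(fa)) 100 * mean(fa) else NA_real_,
        fl_pct_b = if (length(fb)) 100 * mean(fb) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, rows)
  if (bonferroni)
    tests$p_adj <- pmin(1, tests$p_value * sum(!is.na(tests$p_value)))
  fl_overall <- stats::setNames(
    c(100 * mean(ua$is_full_length), 100 * mean(ub$is_full_length)),
    c(labelA, labelB))
  structure(list(tests = tests, fl_overall = fl_overall,
    labels = c(labelA, labelB)), class = "protocolComparison")
}

#' @export
print.protocolComparison <- function(x, ...) {
  cat(sprintf("Protocol comparison: %s vs %s\n", x$labels[1], x$labels[2]))
  cat(sprintf("  overall FL%%: %.2f vs %.2f\n", x$fl_overall[1], x$fl_overall[2]))
  print(x$tests, digits = 4)
  invisible(x)
}
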