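#' Stitch peaks into larger regions
#'
#' Transitively merges peaks on the same chromosome whose gap is at most
#' `stitch_distance` bp (inclusive boundary: a gap exactly equal to the
#' distance merges).  Each region spans from the minimum constituent start
#' to the maximum constituent end and carries the exact sum of constituent
#' tags per condition; stitching is idempotent.
#'
#' @param peaks peak tibble with one or more condition tag columns.
#' @param stitch_distance maximum gap merged, in bp (default 12500, the
#'   usual stitching window of rank-based super-enhancer calling).
#' @param conditions tag column names to carry through (default: every
#'   numeric column other than the coordinates).
#' @return tibble `region_id`, `chrom`, `start`, `end`, `n_peaks`,
#'   `peak_ids` (list column) and one summed tag column per condition.
#' @export
stitch_peaks <- function(peaks, stitch_distance = 12500, conditions = NULL) {
  check_peaks(peaks)
  conditions <- conditions %||% setdiff(
    names(peaks)[vapply(peaks, is.numeric, logical(1))],
    c("start", "end")
  )
  if (!nrow(peaks)) {
    out <- tibble(region_id = character(), chrom = character(),
                  start = numeric(), end = numeric(), n_peaks = integer(),
                  peak_ids = list())
    for (cc in conditions) out[[cc]] <- numeric()
    return(out)
  }
  gr <- intervals_to_granges(peaks)
  merged <- GenomicRanges::reduce(gr, min.gapwidth = stitch_distance + 1)
  hits <- GenomicRanges::findOverlaps(gr, merged)
  member <- S4Vectors::subjectHits(hits)  # one region per peak

  ids <- if ("peak_id" %in% names(peaks)) peaks$peak_id else
    as.character(seq_len(nrow(peaks)))
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1,
    end = as.numeric(GenomicRanges::end(merged)),
    n_peaks = as.integer(tabulate(member, nbins = length(merged))),
    peak_ids = unname(split(ids, factor(member, seq_len(length(merged)))))
  )
  for (cc in conditions) {
    agg <- rowsum(peaks[[cc]], member)
    v <- numeric(length(merged))
    v[as.integer(rownames(agg))] <- agg[, 1]
    out[[cc]] <- v
  }
  out <- arrange(out, .data$chrom, .data$start)
  out$region_id <- sprintf("region_%05d", seq_len(nrow(out)))
  out[, c("region_id", setdiff(names(out), "region_id"))]
}

#' Locate the rank-score tangent threshold
#'
#' Finds the super-enhancer cutoff on a rank-score curve: scores are sorted
#' ascending, both axes are min-max normalized to `[0, 1]`, and the
#' threshold is the point where a line of slope 1 is tangent to the curve —
#' computed as the position minimizing `y - x`, the support-line form of
#' "the tangent to the plotted rank-scores is one" (for a convex curve the
#' minimizer of `y - x` is exactly the point with unit derivative).  Ties,
#' including a perfectly linear curve where the slope is 1 everywhere, take
#' the highest rank, so a linear curve yields zero super calls.  Regions
#' whose score strictly exceeds the threshold score are super.
#'
#' A windowed centered-difference slope (window `max(1, floor(n/100))`
#' ranks) is returned with the curve for diagnostics.
#'
#' @param scores non-negative region scores (any order); at least 3.
#' @return list: `threshold_rank` (number of regions above the threshold,
#'   i.e. the super count), `threshold_score`, and `curve`, a tibble with
#'   ascending-sorted `score`, normalized `x`, `y`, the diagnostic `slope`
#'   and the gap `y_minus_x`.  All scores equal yields zero supers with a
#'   warning.  The threshold is invariant under uniform scaling of scores.
#' @examples
#' s <- ((1:1000) / 1000)^2
#' find_se_threshold(s)$threshold_rank
#' @export
find_se_threshold <- function(scores) {
  if (length(scores) < 3) abort("need at least 3 region scores")
  if (any(scores < 0)) abort("scores must be non-negative")
  n <- length(scores)
  s <- sort(scores)
  if (s[n] == s[1]) {
    warn("all region scores equal; no super-enhancers called")
    return(list(threshold_rank = 0L, threshold_score = s[n],
                curve = tibble(score = s, x = seq(0, 1, length.out = n),
                               y = rep(0, n), slope = rep(0, n),
                               y_minus_x = -seq(0, 1, length.out = n))))
  }
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - s[1]) / (s[n] - s[1])
  gap <- y - x
  # Highest index attaining the minimum (within floating-point tolerance):
  # conservative on plateaus and makes the exactly-linear curve (gap
  # identically 0 up to rounding) call nothing.
  t_idx <- max(which(gap <= min(gap) + 1e-9))
  threshold_score <- s[t_idx]
  n_super <- sum(scores > threshold_score)

  w <- max(1L, floor(n / 100))
  lo <- pmax(seq_len(n) - w, 1L)
  hi <- pmin(seq_len(n) + w, n)
  slope <- (y[hi] - y[lo]) / (x[hi] - x[lo])

  list(
    threshold_rank = as.integer(n_super),
    threshold_score = threshold_score,
    curve = tibble(score = s, x = x, y = y, slope = slope, y_minus_x = gap)
  )
}

#' Call super-enhancers for one condition
#'
#' The full rank-based procedure: stitch peaks into regions
#' ([stitch_peaks()]), rank regions by total normalized tag count in the
#' chosen condition (descending), locate the tangent-slope-1 threshold on
#' the rank-score curve ([find_se_threshold()]), and flag regions above it
#' as super-enhancers.  Deterministic: ranking ties break by chromosome and
#' start coordinate.
#'
#' @param peaks peak tibble.
#' @param condition tag column to rank by.
#' @param stitch_distance stitching gap in bp (default 12500).
#' @param exclude_tss_window when positive, peaks whose midpoint lies within
#'   this distance of an annotated TSS are removed before stitching
#'   (requires `genes`); 0 (default) disables the exclusion.
#' @param genes gene annotation tibble, only needed for TSS exclusion.
#' @return an `se_call` object: `regions` (stitched tibble plus `rank` and
#'   `is_super`), `threshold_rank`, `threshold_score`, `n_super`, `curve`,
#'   and `parameters`.
#' @examples
#' sim <- simulate_peaks(n_background = 200, n_superenhancers = 3, seed = 1)
#' cl <- call_super_enhancers(sim$peaks, "stimulated")
#' cl$n_super
#' @export
call_super_enhancers <- function(peaks, condition, stitch_distance = 12500,
                                 exclude_tss_window = 0, genes = NULL) {
  check_peaks(peaks, if (nrow(peaks)) condition else character())
  if (exclude_tss_window > 0) {
    if (is.null(genes)) abort("TSS exclusion requires a gene annotation")
    check_genes(genes)
    mid <- floor((peaks$start + peaks$end) / 2)
    near <- vapply(seq_len(nrow(peaks)), function(i) {
      any(genes$chrom == peaks$chrom[i] &
            abs(genes$tss - mid[i]) <= exclude_tss_window)
    }, logical(1))
    peaks <- peaks[!near, , drop = FALSE]
  }
  regions <- stitch_peaks(peaks, stitch_distance, conditions = condition)
  if (!nrow(regions)) {
    return(structure(
      list(regions = mutate(regions, rank = integer(), is_super = logical()),
           threshold_rank = 0L, threshold_score = NA_real_, n_super = 0L,
           curve = tibble(), condition = condition,
           parameters = list(stitch_distance = stitch_distance,
                             exclude_tss_window = exclude_tss_window)),
      class = "se_call"
    ))
  }
  scores <- regions[[condition]]
  if (nrow(regions) < 3) {
    warn("fewer than 3 regions; no threshold fitted, no supers called")
    th <- list(threshold_rank = 0L, threshold_score = max(scores),
               curve = tibble())
  } else {
    th <- find_se_threshold(scores)
  }
  ord <- order(-scores, regions$chrom, regions$start)
  regions$rank <- NA_integer_
  regions$rank[ord] <- seq_len(nrow(regions))
  regions$is_super <- scores > th$threshold_score
  regions <- arrange(regions, .data$rank)
  structure(
    list(
      regions = regions,
      threshold_rank = th$threshold_rank,
      threshold_score = th$threshold_score,
      n_super = sum(regions$is_super),
      curve = th$curve,
      condition = condition,
      parameters = list(stitch_distance = stitch_distance,
                        exclude_tss_window = exclude_tss_window)
    ),
    class = "se_call"
  )
}

#' @export
print.se_call <- function(x, ...) {
  cat("<se_call>\n")
  cat("  condition:", x$condition, "\n")
  cat("  regions:", nrow(x$regions), "  super-enhancers:", x$n_super, "\n")
  cat(sprintf("  threshold score: %.1f (rank %d)\n",
              x$threshold_score, x$threshold_rank))
  invisible(x)
}

#' @export
tidy.se_call <- function(x, ...) {
  select(x$regions, -"peak_ids")
}

#' @export
glance.se_call <- function(x, ...) {
  tibble(
    condition = x$condition,
    n_regions = nrow(x$regions),
    n_super = x$n_super,
    threshold_rank = x$threshold_rank,
    threshold_score = x$threshold_score,
    stitch_distance = x$parameters$stitch_distance
  )
}

#' Compare two super-enhancer calls
#'
#' Splits the super regions of two calls into shared and exclusive sets,
#' where "shared" means overlapping (by at least 1 bp) a super region of
#' the other call.  Counts are reported from each side, since overlap is
#' not one-to-one.
#'
#' @param call_a,call_b `se_call` objects on the same assembly.
#' @return list: `shared_a`, `shared_b` (super regions of each call that
#'   overlap a super of the other), `a_only`, `b_only`, and `counts`, a
#'   one-row tibble `n_super_a`, `n_super_b`, `shared_from_a`,
#'   `shared_from_b`, `a_only`, `b_only`.
#' @export
compare_se_sets <- function(call_a, call_b) {
  stopifnot(inherits(call_a, "se_call"), inherits(call_b, "se_call"))
  sa <- call_a$regions[call_a$regions$is_super, , drop = FALSE]
  sb <- call_b$regions[call_b$regions$is_super, , drop = FALSE]
  if (nrow(sa) && nrow(sb)) {
    chroms <- unique(c(as.character(sa$chrom), as.character(sb$chrom)))
    ga <- intervals_to_granges(sa, seqlevels = chroms)
    gb <- intervals_to_granges(sb, seqlevels = chroms)
    a_shared <- GenomicRanges::countOverlaps(ga, gb) > 0
    b_shared <- GenomicRanges::countOverlaps(gb, ga) > 0
  } else {
    a_shared <- rep(FALSE, nrow(sa))
    b_shared <- rep(FALSE, nrow(sb))
  }
  list(
    shared_a = sa[a_shared, , drop = FALSE],
    shared_b = sb[b_shared, , drop = FALSE],
    a_only = sa[!a_shared, , drop = FALSE],
    b_only = sb[!b_shared, , drop = FALSE],
    counts = tibble(
      n_super_a = nrow(sa), n_super_b = nrow(sb),
      shared_from_a = sum(a_shared), shared_from_b = sum(b_shared),
      a_only = sum(!a_shared), b_only = sum(!b_shared)
    )
  )
}

#' Tag gain at shared super-enhancers, split by signature proximity
#'
#' Splits shared super-enhancer regions by whether their nearest gene is an
#' activation signature gene, reports the per-region tag gain
#' (condition b minus condition a), and compares the two splits with a
#' two-sided Welch t test.  With fewer than 2 regions in either split the
#' comparison is refused (statistic and p reported as `NA`) while the gains
#' are still returned.
#'
#' @param regions stitched-region tibble (e.g. `shared_a` from
#'   [compare_se_sets()]) with tag columns for both conditions.
#' @param genes gene annotation tibble.
#' @param signature_genes character vector of signature gene ids.
#' @param condition_a,condition_b tag columns (reference, stimulated).
#' @return list: `gains` (tibble `region_id`, `nearest_gene`,
#'   `near_signature`, `gain`) and `test`, a one-row tibble `mean_gain_sig`,
#'   `mean_gain_other`, `statistic`, `p_value`.  An empty split is an
#'   error.
#' @export
se_group_gain <- function(regions, genes, signature_genes,
                          condition_a, condition_b) {
  check_peaks(regions, c(condition_a, condition_b))
  if (!"region_id" %in% names(regions)) {
    regions$region_id <- sprintf("region_%05d", seq_len(nrow(regions)))
  }
  tmp <- regions
  tmp$peak_id <- tmp$region_id
  assigned <- assign_nearest_gene(tmp, genes)
  gains <- tibble(
    region_id = assigned$region_id,
    nearest_gene = assigned$nearest_gene,
    near_signature = assigned$nearest_gene %in% signature_genes,
    gain = assigned[[condition_b]] - assigned[[condition_a]]
  )
  g_sig <- gains$gain[gains$near_signature]
  g_oth <- gains$gain[!gains$near_signature]
  if (!length(g_sig) || !length(g_oth)) {
    abort("one of the signature/other splits is empty")
  }
  if (length(g_sig) < 2 || length(g_oth) < 2) {
    warn("a split has fewer than 2 regions; comparison refused")
    stat <- NA_real_; p <- NA_real_
  } else if (sd(c(g_sig, g_oth)) == 0) {
    stat <- 0; p <- 1
  } else if (sd(g_sig) == 0 && sd(g_oth) == 0) {
    warn("gains are constant within both splits; comparison refused")
    stat <- NA_real_; p <- NA_real_
  } else {
    tt <- t.test(g_sig, g_oth)
    stat <- unname(tt$statistic); p <- tt$p.value
  }
  list(
    gains = gains,
    test = tibble(
      n_sig = length(g_sig), n_other = length(g_oth),
      mean_gain_sig = mean(g_sig), mean_gain_other = mean(g_oth),
      statistic = stat, p_value = p
    )
  )
}
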