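#' Threshold peaks by normalized tag count
#'
#' Keeps peaks with at least `min_tags` normalized tags in the given
#' condition (inclusive: a peak with exactly `min_tags` stays).
#'
#' @param peaks peak tibble with a numeric tag column per condition.
#' @param condition name of the tag column (default `"tags"`).
#' @param min_tags tag floor (default 40).
#' @return the filtered peak tibble.
#' @export
threshold_peaks <- function(peaks, condition = "tags", min_tags = 40) {
  check_peaks(peaks, condition)
  peaks[peaks[[condition]] >= min_tags, , drop = FALSE]
}

#' Pairwise peak overlap table
#'
#' For an ordered list of per-condition peak sets, each thresholded at
#' `min_tags`, returns the square matrix whose off-diagonal `(i, j)` entry
#' counts the set-`i` peaks overlapping (by at least 1 bp) at least one
#' set-`j` peak — each peak counted at most once — and whose diagonal is the
#' thresholded size of each set.
#'
#' @param peak_sets named list of peak tibbles.
#' @param condition tag column name used for thresholding, recycled across
#'   sets (default `"tags"`).
#' @param min_tags tag floor applied to every set (default 40).
#' @return integer matrix with the sets' names on both dimensions.
#' @export
overlap_table <- function(peak_sets, condition = "tags", min_tags = 40) {
  if (!length(peak_sets)) abort("need at least one peak set")
  condition <- rep_len(condition, length(peak_sets))
  th <- purrr::map2(peak_sets, condition, threshold_peaks, min_tags = min_tags)
  chroms <- unique(unlist(lapply(th, function(p) as.character(p$chrom))))
  gr <- lapply(th, intervals_to_granges, seqlevels = chroms)
  nm <- names(peak_sets) %||% paste0("set", seq_along(peak_sets))
  n <- length(th)
  out <- matrix(0L, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- if (i == j) nrow(th[[i]]) else
        sum(GenomicRanges::countOverlaps(gr[[i]], gr[[j]]) > 0)
    }
  }
  out
}

#' Classify peaks by activation fold change
#'
#' Labels each peak `up` when the pseudocounted tag ratio
#' `(tags_b + pc) / (tags_a + pc)` strictly exceeds `fold` (mirroring "more
#' than two-fold up-regulated"), `down` in the mirrored case, and
#' `unchanged` otherwise.  Swapping the two conditions swaps `up` and
#' `down` labels exactly.
#'
#' @param peaks peak tibble.
#' @param condition_a,condition_b tag columns for the reference and
#'   stimulated conditions.
#' @param fold fold threshold (strict inequality; default 2).
#' @param pseudocount added to both counts before the ratio (default 1).
#' @return `peaks` with added columns `fold_change` and `label`.
#' @export
classify_fold_change <- function(peaks, condition_a, condition_b,
                                 fold = 2, pseudocount = 1) {
  check_peaks(peaks, c(condition_a, condition_b))
  ratio <- (peaks[[condition_b]] + pseudocount) /
    (peaks[[condition_a]] + pseudocount)
  peaks$fold_change <- ratio
  peaks$label <- ifelse(ratio > fold, "up",
                        ifelse(1 / ratio > fold, "down", "unchanged"))
  peaks
}

#' Aggregate tag counts around binding sites
#'
#' Sums per-condition tag counts within `+/- window_bp` of each site center
#' (half-open window `[center - window_bp, center + window_bp)`), reporting
#' per-condition totals and per-site means.  Tag libraries are tibbles of
#' tag positions: `chrom`, `pos` plus one numeric count column per
#' condition.
#'
#' @param sites site tibble with `chrom` and either `pos` or
#'   `start`/`end` (center = midpoint, floored).
#' @param tags tag-position tibble (`chrom`, `pos`, condition columns).
#' @param conditions names of the tag count columns to aggregate.
#' @param window_bp half-window in bp (default 1000).
#' @return tibble `condition`, `total`, `mean_per_site`, `n_sites`; the
#'   per-site-by-condition matrix is in attribute `per_site`.
#' @export
aggregate_tags_at_sites <- function(sites, tags, conditions,
                                    window_bp = 1000) {
  if (!nrow(sites)) abort("empty site set")
  if (!all(c("chrom", "pos") %in% names(tags))) {
    abort("`tags` needs columns chrom and pos")
  }
  for (cc in conditions) {
    if (!cc %in% names(tags)) abort(paste0("condition column missing: ", cc))
  }
  center <- if ("pos" %in% names(sites)) sites$pos else
    floor((sites$start + sites$end) / 2)
  win <- GenomicRanges::GRanges(
    sites$chrom,
    IRanges::IRanges(start = center - window_bp + 1L, end = center + window_bp)
  )
  tg <- GenomicRanges::GRanges(tags$chrom,
                               IRanges::IRanges(tags$pos + 1L, tags$pos + 1L))
  hits <- GenomicRanges::findOverlaps(win, tg)
  per_site <- matrix(0, nrow(sites), length(conditions),
                     dimnames = list(NULL, conditions))
  if (length(hits)) {
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    for (cc in conditions) {
      agg <- rowsum(tags[[cc]][si], qi)
      per_site[as.integer(rownames(agg)), cc] <- agg[, 1]
    }
  }
  out <- tibble(
    condition = conditions,
    total = unname(colSums(per_site)),
    mean_per_site = unname(colMeans(per_site)),
    n_sites = nrow(sites)
  )
  attr(out, "per_site") <- per_site
  out
}

#' Gene-body to promoter spreading ratio
#'
#' Quantifies spreading of a histone mark from the promoter into the gene
#' body: the ratio of tag *density* (tags per bp) in the strand-aware body
#' window (`TSS + body_span[1]` to `TSS + body_span[2]`, downstream) to the
#' density in the promoter window (`TSS +/- promoter_halfwidth`).  Uniform
#' coverage gives exactly 1; a focal TSS peak gives a ratio below 1; mark
#' spread along the body moves the ratio up towards (and past) 1.  The
#' ratio is invariant under uniform scaling of coverage depth.
#'
#' @param profile TSS-anchored per-base profile: tibble `offset` (bp
#'   relative to the TSS, positive downstream, already strand-corrected)
#'   and `coverage`.  See [simulate_tag_profile()] and
#'   [tag_profile_around()].
#' @param promoter_halfwidth promoter half-window in bp (default 1000).
#' @param body_span numeric length-2 downstream window in bp (default
#'   `c(1000, 4000)`, the first 4 kb minus the promoter).
#' @param pseudo_density density floor used when the promoter window is
#'   empty (flagged with a warning).
#' @return the density ratio (body / promoter), a single number.  When the
#'   profile truncates a window the available positions are used with a
#'   warning.
#' @export
spreading_ratio <- function(profile, promoter_halfwidth = 1000,
                            body_span = c(1000, 4000),
                            pseudo_density = 1e-6) {
  if (!all(c("offset", "coverage") %in% names(profile))) {
    abort("`profile` needs columns offset and coverage")
  }
  stopifnot(length(body_span) == 2, body_span[1] < body_span[2])
  prom <- profile$offset >= -promoter_halfwidth &
    profile$offset < promoter_halfwidth
  body <- profile$offset >= body_span[1] & profile$offset < body_span[2]
  if (sum(prom) < 2 * promoter_halfwidth || sum(body) < diff(body_span)) {
    warn("profile does not cover the full windows; using available positions")
  }
  if (!sum(body)) abort("profile has no positions in the body window")
  prom_density <- if (sum(prom)) sum(profile$coverage[prom]) / sum(prom) else 0
  body_density <- sum(profile$coverage[body]) / sum(body)
  if (prom_density == 0) {
    warn("empty promoter window; pseudo-density applied")
    prom_density <- pseudo_density
  }
  body_density / prom_density
}

#' Build a TSS-anchored profile from a tag library
#'
#' Extracts the per-base, strand-corrected coverage around one gene's TSS so
#' it can be fed to [spreading_ratio()].  For a minus-strand gene offsets are
#' mirrored (positive = into the gene body).
#'
#' @param tags tag-position tibble (`chrom`, `pos`, one count column).
#' @param gene one-row gene annotation tibble.
#' @param condition count column name (default `"tags"`).
#' @param upstream,downstream window extents in bp.
#' @return tibble `offset`, `coverage`.
#' @export
tag_profile_around <- function(tags, gene, condition = "tags",
                               upstream = 2000, downstream = 4000) {
  check_genes(gene)
  stopifnot(nrow(gene) == 1)
  offset <- seq(-upstream, downstream - 1)
  pos <- if (gene$strand == "+") gene$tss + offset else gene$tss - offset
  sel <- tags$chrom == gene$chrom
  cov <- numeric(length(offset))
  idx <- match(pos, tags$pos[sel])
  hit <- !is.na(idx)
  cov[hit] <- tags[[condition]][sel][idx[hit]]
  tibble(offset = offset, coverage = cov)
}

#' Binding-site frequency in promoter windows
#'
#' For each factor's binding-site set and each gene group, the fraction of
#' group genes with at least one site within `+/- window` bp of the TSS
#' (sites located by their midpoint), or the mean in-window site tag count
#' when `statistic = "mean_tags"`.  A pooled row aggregates the sites of all
#' factors.
#'
#' @param site_sets named list of site tibbles (`chrom`, `start`, `end`,
#'   optionally a `tags` column).
#' @param genes gene annotation tibble.
#' @param gene_groups named list of gene id vectors; every id must be
#'   annotated, and empty groups are an error.
#' @param window promoter half-window in bp (default 1000).
#' @param statistic `"frequency"` (default) or `"mean_tags"`.
#' @return tibble `factor`, `group`, `n_genes`, `value`.
#' @export
promoter_binding_frequency <- function(site_sets, genes, gene_groups,
                                       window = 1000,
                                       statistic = c("frequency", "mean_tags")) {
  statistic <- match.arg(statistic)
  check_genes(genes)
  if (!length(gene_groups)) abort("need at least one gene group")
  for (nm in names(gene_groups)) {
    if (!length(gene_groups[[nm]])) abort(paste0("empty gene group: ", nm))
    missing <- setdiff(gene_groups[[nm]], genes$gene_id)
    if (length(missing)) {
      abort(paste0("group ", nm, " has unannotated gene(s): ",
                   paste(head(missing, 5), collapse = ", ")))
    }
  }
  pooled <- bind_rows(site_sets)
  all_sets <- c(site_sets, list(pooled = pooled))

  per_gene_value <- function(sites) {
    if (!nrow(sites)) return(setNames(numeric(nrow(genes)), genes$gene_id))
    mid <- floor((sites$start + sites$end) / 2)
    counts <- vapply(seq_len(nrow(genes)), function(i) {
      inwin <- sites$chrom == genes$chrom[i] &
        abs(mid - genes$tss[i]) <= window
      if (statistic == "frequency") sum(inwin)
      else if ("tags" %in% names(sites)) sum(sites$tags[inwin]) else sum(inwin)
    }, numeric(1))
    setNames(counts, genes$gene_id)
  }

  purrr::map_dfr(names(all_sets), function(fct) {
    v <- per_gene_value(all_sets[[fct]])
    purrr::map_dfr(names(gene_groups), function(grp) {
      ids <- gene_groups[[grp]]
      val <- if (statistic == "frequency") mean(v[ids] > 0) else mean(v[ids])
      tibble(factor = fct, group = grp, n_genes = length(ids), value = val)
    })
  })
}

#' Partition a gene group by expression level
#'
#' Splits a gene group into strata by mean RPKM across the matrix samples,
#' using half-open bins `[e_i, e_{i+1})`.  Genes missing from the matrix are
#' dropped with a warning.
#'
#' @param gene_group character vector of gene ids.
#' @param expr expression tibble.
#' @param bin_edges strictly increasing numeric edges; use `Inf` for an open
#'   top bin.
#' @return tibble `gene_id`, `mean_rpkm`, `stratum` (a `[lo,hi)` label).
#' @export
stratify_by_expression <- function(gene_group, expr, bin_edges) {
  if (any(diff(bin_edges) <= 0)) abort("bin_edges must be strictly increasing")
  if (length(bin_edges) < 2) abort("need at least two bin edges")
  m <- expr_to_matrix(expr)
  missing <- setdiff(gene_group, rownames(m))
  if (length(missing)) {
    warn(paste0(length(missing), " gene(s) missing from matrix; dropped"))
  }
  ids <- intersect(gene_group, rownames(m))
  mu <- rowMeans(m[ids, , drop = FALSE])
  lab <- paste0("[", fmt_num(bin_edges[-length(bin_edges)]), ",",
                fmt_num(bin_edges[-1]), ")")
  stratum <- cut(mu, breaks = bin_edges, labels = lab, right = FALSE)
  tibble(gene_id = ids, mean_rpkm = mu,
         stratum = as.character(stratum))
}

#' Assign peaks to their nearest TSS
#'
#' Midpoint-to-TSS distance on the same chromosome; exact ties go to the
#' gene with the smaller TSS coordinate.  Peaks on chromosomes without any
#' annotated gene are dropped with a warning.
#'
#' @param peaks peak tibble.
#' @param genes gene annotation tibble.
#' @return `peaks` with added columns `nearest_gene` and `tss_distance`.
#' @export
assign_nearest_gene <- function(peaks, genes) {
  check_peaks(peaks)
  check_genes(genes)
  mid <- floor((peaks$start + peaks$end) / 2)
  nearest <- character(nrow(peaks))
  dist <- numeric(nrow(peaks))
  for (cc in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == cc)
    g <- genes[genes$chrom == cc, , drop = FALSE]
    if (!nrow(g)) {
      nearest[pi] <- NA_character_
      dist[pi] <- NA_real_
      next
    }
    g <- g[order(g$tss, g$gene_id), , drop = FALSE]
    dd <- abs(outer(mid[pi], g$tss, "-"))
    j <- apply(dd, 1, which.min)   # ties -> first = smaller tss
    nearest[pi] <- g$gene_id[j]
    dist[pi] <- dd[cbind(seq_along(pi), j)]
  }
  drop <- is.na(nearest)
  if (any(drop)) {
    warn(paste0(sum(drop), " peak(s) on chromosomes without genes; dropped"))
  }
  out <- peaks[!drop, , drop = FALSE]
  out$nearest_gene <- nearest[!drop]
  out$tss_distance <- dist[!drop]
  out
}

#' Proximity enrichment of a peak subset near signature genes
#'
#' Tests whether peaks in a subset (e.g. activation-gained enhancers) are
#' more likely than the remaining peaks to have a signature gene as their
#' nearest gene.  Each peak is assigned to its nearest TSS
#' ([assign_nearest_gene()]); the 2x2 table (peak in subset?) x (nearest
#' gene in signature?) is tested with Pearson's chi-squared statistic
#' (1 degree of freedom, no continuity correction).
#'
#' @param peaks peak tibble covering every peak considered.
#' @param subset_ids peak ids forming the subset.
#' @param genes gene annotation tibble.
#' @param signature_genes character vector of signature gene ids.
#' @return tibble `statistic`, `df`, `p_value`, `n_peaks`; the 2x2 table is
#'   in attribute `table`.  Any expected cell below 1 is an error
#'   recommending an exact test.
#' @export
proximity_enrichment <- function(peaks, subset_ids, genes, signature_genes) {
  assigned <- assign_nearest_gene(peaks, genes)
  tab <- table(
    in_subset = factor(assigned$peak_id %in% subset_ids, c(TRUE, FALSE)),
    near_signature = factor(assigned$nearest_gene %in% signature_genes,
                            c(TRUE, FALSE))
  )
  res <- chisq_2x2(tab)
  attr(res, "table") <- tab
  res
}

# Pearson chi-squared on a 2x2 table, df = 1, no continuity correction.
# Independent proportions give statistic 0 and p = 1.
chisq_2x2 <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1)) {
    abort("expected cell count below 1; use an exact test instead")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble(
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = ct$p.value,
    n_peaks = sum(tab)
  )
}

#' Classify genes as digital or analog responders
#'
#' Separates all-or-none ("digital") induction from graded ("analog")
#' responses across a sorted-cell stimulation series with one reference
#' (unstimulated) condition.  A gene is `digital` when its minimum treated
#' condition mean is at least `induction_fold` times the reference mean and
#' its coefficient of variation across treated conditions is at most
#' `max_treated_cv` (induced, then uniformly high).  A gene is `analog` when
#' its treated means are strictly monotone in condition order with a total
#' treated-range fold of at least 2.  Everything else is `other`.  The
#' thresholds are package defaults, not values fixed by any reference
#' dataset.
#'
#' Genes are additionally ranked for "most highly induced / most
#' consistently expressed" selection by
#' `induction fold * (1 - treated CV)`.
#'
#' @param expr expression tibble (e.g. sorted-cell condition series).
#' @param sample_info sample annotation; the first condition is the
#'   reference and at least two treated conditions are required.
#' @param induction_fold minimum induction of the weakest treated condition
#'   over the reference (default 4).
#' @param max_treated_cv maximum CV across treated conditions for the
#'   digital class (default 0.15).
#' @param pseudocount applied to zero reference means.
#' @return tibble `gene_id`, `label`, `induction`, `treated_cv`,
#'   `rank_score`, ordered as in `expr`.
#' @export
classify_digital_analog <- function(expr, sample_info, induction_fold = 4,
                                    max_treated_cv = 0.15, pseudocount = 1) {
  m <- expr_to_matrix(expr)
  cm <- condition_mean_matrix(m, sample_info)
  if (ncol(cm) < 3) abort("need one reference and at least 2 treated conditions")
  ref <- pmax(cm[, 1], pseudocount)
  treated <- cm[, -1, drop = FALSE]
  tmin <- apply(treated, 1, min)
  tmax <- apply(treated, 1, max)
  tmu <- rowMeans(treated)
  tcv <- apply(treated, 1, sd) / tmu
  induction <- tmin / ref
  mono_up <- apply(treated, 1, function(v) all(diff(v) > 0))
  mono_dn <- apply(treated, 1, function(v) all(diff(v) < 0))
  range_fold <- tmax / pmax(tmin, pseudocount)

  label <- rep("other", nrow(cm))
  label[(mono_up | mono_dn) & range_fold >= 2] <- "analog"
  label[induction >= induction_fold & tcv <= max_treated_cv] <- "digital"
  tibble(
    gene_id = rownames(cm),
    label = label,
    induction = unname(induction),
    treated_cv = unname(tcv),
    rank_score = unname(induction * (1 - tcv))
  )
}
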