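# Fixture builders and independent brute-force oracles.  The oracles are
# deliberately naive O(n*m) loops so they share no code path with the
# package's interval engine.

# Build an expression tibble + sample_info from a genes x samples matrix.
make_expr <- function(m, conditions, replicate = NULL) {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  expr <- tibble::tibble(gene_id = rownames(m))
  for (j in seq_len(ncol(m))) expr[[colnames(m)[j]]] <- unname(m[, j])
  si <- tibble::tibble(
    sample = colnames(m),
    condition = factor(conditions, levels = unique(conditions)),
    replicate = replicate %||% seq_len(ncol(m))
  )
  list(expr = expr, sample_info = si)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_peaks <- function(chrom, start, end, tags = NULL, ids = NULL) {
  tibble::tibble(
    chrom = chrom, start = start, end = end,
    peak_id = ids %||% paste0("pk", seq_along(start)),
    tags = tags %||% rep(100, length(start))
  )
}

random_intervals <- function(n, chroms = c("chr1", "chr2", "chr3"),
                             max_pos = 1e6, max_width = 5000) {
  start <- floor(runif(n, 0, max_pos))
  make_peaks(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + 1 + floor(runif(n, 0, max_width)),
    tags = round(runif(n, 0, 200), 2)
  )
}

# --- brute-force oracles ----------------------------------------------------

# Number of `a` intervals overlapping (>= 1 shared bp, half-open) any `b`.
bf_overlap_count <- function(a, b) {
  hits <- vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i])
  }, logical(1))
  sum(hits)
}

# Transitive stitching by linear scan; returns regions sorted by
# chrom/start with constituent count and summed tags.
bf_stitch <- function(peaks, dist) {
  out <- list()
  for (cc in sort(unique(peaks$chrom))) {
    p <- peaks[peaks$chrom == cc, , drop = FALSE]
    p <- p[order(p$start, p$end), , drop = FALSE]
    cur_start <- p$start[1]; cur_end <- p$end[1]
    cur_n <- 1L; cur_tags <- p$tags[1]
    flush <- function() {
      out[[length(out) + 1]] <<- tibble::tibble(
        chrom = cc, start = cur_start, end = cur_end,
        n_peaks = cur_n, tags = cur_tags
      )
    }
    for (i in seq_len(nrow(p))[-1]) {
      if (p$start[i] - cur_end <= dist) {
        cur_end <- max(cur_end, p$end[i])
        cur_n <- cur_n + 1L
        cur_tags <- cur_tags + p$tags[i]
      } else {
        flush()
        cur_start <- p$start[i]; cur_end <- p$end[i]
        cur_n <- 1L; cur_tags <- p$tags[i]
      }
    }
    flush()
  }
  dplyr::arrange(dplyr::bind_rows(out), chrom, start)
}

# Nearest TSS per peak midpoint; ties -> smaller TSS coordinate.
bf_nearest_tss <- function(peaks, genes) {
  mid <- floor((peaks$start + peaks$end) / 2)
  vapply(seq_len(nrow(peaks)), function(i) {
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    if (!nrow(g)) return(NA_character_)
    d <- abs(g$tss - mid[i])
    cand <- g[d == min(d), , drop = FALSE]
    cand$gene_id[which.min(cand$tss)]
  }, character(1))
}

# Pearson chi-squared on a 2x2 table, closed form, no correction.
bf_chisq_2x2 <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

make_genes <- function(chrom, tss, strand = "+", ids = NULL,
                       span = c(0, 10000)) {
  tibble::tibble(
    gene_id = ids %||% paste0("gene", seq_along(tss)),
    chrom = chrom, tss = tss, strand = strand,
    gene_start = pmax(0, tss - ifelse(strand == "+", span[1], span[2])),
    gene_end = tss + ifelse(strand == "+", span[2], span[1]) + 1
  )
}

# Minimal hand-built signature model for scoring tests.
make_model <- function(gene_ids, loadings, gene_means = NULL) {
  structure(
    list(
      loadings = tibble::tibble(gene_id = gene_ids, loading = loadings,
                                gene_mean = gene_means %||% rep(0, length(loadings))),
      sample_scores = tibble::tibble(sample = character(),
                                     condition = character(),
                                     score = numeric()),
      variance_explained = NA_real_,
      reference_condition = "ref",
      condition_order = "ref",
      top_set = character(), bottom_set = character(),
      fraction = NA_real_, scaled = FALSE
    ),
    class = "signature_model"
  )
}

# Planted-truth helpers for super-enhancer calls.
se_truth_overlap <- function(call, truth_regions) {
  sup <- call$regions[call$regions$is_super, , drop = FALSE]
  recovered <- vapply(seq_len(nrow(truth_regions)), function(i) {
    any(sup$chrom == truth_regions$chrom[i] &
          sup$start < truth_regions$end[i] &
          sup$end > truth_regions$start[i])
  }, logical(1))
  false_calls <- vapply(seq_len(nrow(sup)), function(i) {
    !any(truth_regions$chrom == sup$chrom[i] &
           truth_regions$start < sup$end[i] &
           truth_regions$end > sup$start[i])
  }, logical(1))
  list(recovered = sum(recovered), false_calls = sum(false_calls),
       n_super = nrow(sup))
}
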