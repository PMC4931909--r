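# Internal helpers shared across modules.

# Convert a gene_id + sample-columns tibble to a numeric matrix (genes x
# samples).  The first column must be `gene_id`; everything else is coerced.
expr_to_matrix <- function(expr) {
  stopifnot(is.data.frame(expr), ncol(expr) >= 2)
  if (names(expr)[1] != "gene_id") {
    abort("expression table must have `gene_id` as its first column")
  }
  ids <- as.character(expr$gene_id)
  if (anyDuplicated(ids)) {
    abort(paste0(
      "duplicate gene id(s): ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  m <- as.matrix(expr[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

# Condition labels in analysis order.  `condition` may be a factor (its level
# order wins) or a character vector (order of first appearance).
condition_levels <- function(sample_info) {
  check_sample_info(sample_info)
  cond <- sample_info$condition
  if (is.factor(cond)) as.character(levels(cond))[levels(cond) %in% cond] else unique(as.character(cond))
}

check_sample_info <- function(sample_info) {
  if (!is.data.frame(sample_info) ||
      !all(c("sample", "condition") %in% names(sample_info))) {
    abort("`sample_info` must be a data frame with columns `sample` and `condition`")
  }
  invisible(sample_info)
}

# Match expression columns to sample_info rows; errors on samples missing
# from the map.
match_samples <- function(m, sample_info) {
  check_sample_info(sample_info)
  missing <- setdiff(colnames(m), sample_info$sample)
  if (length(missing)) {
    abort(paste0(
      "sample(s) absent from sample_info: ", paste(missing, collapse = ", ")
    ))
  }
  sample_info[match(colnames(m), sample_info$sample), , drop = FALSE]
}

# Per-condition mean matrix (genes x conditions), replicates collapsed.
condition_mean_matrix <- function(m, sample_info) {
  si <- match_samples(m, sample_info)
  lev <- condition_levels(sample_info)
  lev <- lev[lev %in% si$condition]
  out <- vapply(lev, function(cc) {
    rowMeans(m[, si$condition == cc, drop = FALSE])
  }, numeric(nrow(m)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(m), dimnames = list(rownames(m), lev))
  out
}

# lognormal meanlog/sdlog for a multiplicative noise term with mean 1 and
# coefficient of variation cv.
lnorm_cv_params <- function(cv) {
  sdlog <- sqrt(log(1 + cv^2))
  list(meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

check_peaks <- function(peaks, conditions = character()) {
  if (!is.data.frame(peaks) ||
      !all(c("chrom", "start", "end") %in% names(peaks))) {
    abort("a peak table needs columns `chrom`, `start`, `end`")
  }
  if (any(peaks$start >= peaks$end)) {
    bad <- which(peaks$start >= peaks$end)[1]
    abort(paste0("interval start >= end at row ", bad,
                 " (coordinates are 0-based half-open)"))
  }
  for (cc in conditions) {
    if (!cc %in% names(peaks)) {
      abort(paste0("condition column `", cc, "` not found in peak table"))
    }
    if (any(peaks[[cc]] < 0, na.rm = TRUE)) {
      abort(paste0("negative tag count in column `", cc, "`"))
    }
  }
  invisible(peaks)
}

check_genes <- function(genes) {
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!is.data.frame(genes) || !all(need %in% names(genes))) {
    abort("a gene annotation needs columns gene_id, chrom, tss, strand")
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("gene strand must be '+' or '-'")
  }
  invisible(genes)
}

# Intervals (0-based half-open) -> GRanges (1-based closed).  A shared
# seqlevels universe avoids spurious level-mismatch warnings when comparing
# sets that cover different chromosomes.
intervals_to_granges <- function(x, seqlevels = NULL) {
  GenomicRanges::GRanges(
    seqnames = factor(as.character(x$chrom),
                      levels = seqlevels %||% unique(as.character(x$chrom))),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}
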