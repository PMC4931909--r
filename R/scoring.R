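#' Score samples on the activation axis
#'
#' Projects each sample onto the signature model's PC1 loadings: expression
#' is restricted to the genes shared between model and matrix, mean-centered
#' gene-wise, and dotted with the loadings.  Scaled scores divide by the
#' maximum absolute raw score so the most extreme sample sits at +/-1 and
#' every score lies in `[-1, 1]`.
#'
#' Centering defaults to the gene-wise mean of the samples being scored
#' (`"scored"`), which makes the score usable on external platforms where
#' absolute levels are not comparable to the training data.  `"model"`
#' centers on the model's stored training means instead, and `"none"` uses
#' the matrix as given.
#'
#' @param expr expression tibble to score.
#' @param model a `signature_model`.
#' @param center `"scored"`, `"model"` or `"none"`.
#' @param genes which model genes to use: `"signature"` (union of top and
#'   bottom sets when present, otherwise all model genes) or `"all"`.
#' @param min_overlap minimum fraction of the selected model genes that must
#'   be present in `expr` (default 0.5; an error reports the missing
#'   fraction below that).
#' @return tibble `sample`, `raw_score`, `scaled_score`, `rank` (1 = highest
#'   scaled score), with attributes `n_genes_used` and `genes_missing`.
#'   All raw scores zero yields scaled scores of 0 with a warning.
#' @examples
#' sim <- simulate_expression(n_genes = 200, noise_cv = 0, seed = 1)
#' fit <- fit_pc1(sim$expr, sim$sample_info)
#' score_samples(sim$expr, fit)
#' @export
score_samples <- function(expr, model, center = c("scored", "model", "none"),
                          genes = c("signature", "all"), min_overlap = 0.5) {
  stopifnot(inherits(model, "signature_model"))
  center <- match.arg(center)
  genes <- match.arg(genes)
  m <- expr_to_matrix(expr)

  ld <- model$loadings
  if (genes == "signature" && (length(model$top_set) || length(model$bottom_set))) {
    ld <- ld[ld$gene_id %in% c(model$top_set, model$bottom_set), , drop = FALSE]
  }
  shared <- intersect(ld$gene_id, rownames(m))
  missing <- setdiff(ld$gene_id, rownames(m))
  if (length(shared) / nrow(ld) < min_overlap) {
    abort(sprintf(
      "only %.1f%% of the %d model genes are present (%.1f%% missing); need at least %.0f%%",
      100 * length(shared) / nrow(ld), nrow(ld),
      100 * length(missing) / nrow(ld), 100 * min_overlap
    ))
  }
  ld <- ld[match(shared, ld$gene_id), , drop = FALSE]
  X <- m[shared, , drop = FALSE]
  Xc <- switch(center,
    scored = X - rowMeans(X),
    model = X - ld$gene_mean,
    none = X
  )
  raw <- unname(drop(crossprod(Xc, ld$loading)))
  mx <- max(abs(raw))
  if (mx == 0) {
    warn("all raw scores are zero; scaled scores reported as 0")
    scaled <- raw
  } else {
    scaled <- raw / mx
  }
  out <- tibble(
    sample = colnames(m),
    raw_score = raw,
    scaled_score = scaled
  )
  out$rank <- rank(-out$scaled_score, ties.method = "min")
  attr(out, "n_genes_used") <- length(shared)
  attr(out, "genes_missing") <- missing
  out
}

#' Rank experiment groups by mean activation score
#'
#' Averages scaled scores within labelled groups of one experiment and
#' orders the groups.  The score ranks samples within an experiment; it is
#' not an absolute metric across experiments, so score each experiment in a
#' separate call.
#'
#' @param scores output of [score_samples()].
#' @param groups tibble `sample`, `group` labelling every scored sample.
#' @return tibble `group`, `n`, `mean_scaled_score`, `rank`, ordered by
#'   decreasing mean; exact ties share a rank and are flagged in the `tied`
#'   column.
#' @export
rank_experiment_groups <- function(scores, groups) {
  if (!all(c("sample", "group") %in% names(groups))) {
    abort("`groups` needs columns `sample` and `group`")
  }
  unknown <- setdiff(scores$sample, groups$sample)
  if (length(unknown)) {
    abort(paste0("unlabelled sample(s): ", paste(unknown, collapse = ", ")))
  }
  joined <- left_join(scores, groups, by = "sample")
  out <- joined |>
    group_by(.data$group) |>
    summarise(n = n(),
              mean_scaled_score = mean(.data$scaled_score),
              .groups = "drop") |>
    arrange(dplyr::desc(.data$mean_scaled_score))
  out$rank <- rank(-out$mean_scaled_score, ties.method = "min")
  out$tied <- duplicated(out$mean_scaled_score) |
    duplicated(out$mean_scaled_score, fromLast = TRUE)
  out
}

#' Permutation test for a gene-group expression trend
#'
#' Tests whether a gene group's mean expression change between two
#' conditions is extreme relative to randomly composed gene groups.  The
#' observed statistic is the mean over the group of per-gene condition-mean
#' differences (condition `b` minus condition `a`).  The null is built by
#' drawing `n_permutations` random gene sets of the same size (without
#' replacement) from the full gene universe and recomputing the statistic; a
#' normal distribution is fitted to the null and the two-tailed p-value is
#' `2 * pnorm(-|z|)`, floored at machine precision.  The empirical
#' permutation-rank p-value is reported alongside.
#'
#' The normal approximation is accurate for universes of hundreds of genes
#' or more; on tiny universes (tens of genes) it can deviate from the exact
#' enumeration tail by up to about 0.1.
#'
#' @param expr expression tibble.
#' @param sample_info sample annotation.
#' @param gene_group character vector of gene ids (at least 2, all present).
#' @param condition_a,condition_b the two conditions compared.
#' @param n_permutations number of random gene sets (default 10000).
#' @param seed integer seed; the test is deterministic per seed.
#' @return a `perm_trend_test` object: `observed_statistic`, `null_mean`,
#'   `null_sd`, `z`, `p_two_tailed`, `p_empirical`, `n_permutations`,
#'   `group_size`, `universe_size`, `seed`.  A zero-spread null with a
#'   matching observed statistic returns `z = 0`, `p = 1`; otherwise it is a
#'   "degenerate null" error.
#' @examples
#' sim <- simulate_expression(n_genes = 300, seed = 2)
#' grp <- sim$truth$gene_id[sim$truth$class == "analog_up"]
#' tt <- permutation_trend_test(sim$expr, sim$sample_info, grp,
#'                              "C1", "C5", n_permutations = 500, seed = 7)
#' glance(tt)
#' @export
permutation_trend_test <- function(expr, sample_info, gene_group,
                                   condition_a, condition_b,
                                   n_permutations = 10000, seed = 1L) {
  m <- expr_to_matrix(expr)
  cm <- condition_mean_matrix(m, sample_info)
  for (cc in c(condition_a, condition_b)) {
    if (!cc %in% colnames(cm)) abort(paste0("condition not present: ", cc))
  }
  if (length(gene_group) < 2) abort("gene_group needs at least 2 genes")
  missing <- setdiff(gene_group, rownames(cm))
  if (length(missing)) {
    abort(paste0("gene(s) not in matrix: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  d <- cm[, condition_b] - cm[, condition_a]
  k <- length(gene_group)
  n <- length(d)
  observed <- mean(d[gene_group])

  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_permutations),
           function(i) mean(d[sample.int(n, k)]), numeric(1))
  })
  null_mean <- mean(perm)
  null_sd <- sd(perm)
  if (null_sd == 0) {
    if (isTRUE(all.equal(observed, null_mean))) {
      z <- 0
      p <- 1
    } else {
      abort("degenerate null: permutation statistics have zero spread")
    }
  } else {
    z <- (observed - null_mean) / null_sd
    p <- max(2 * pnorm(-abs(z)), .Machine$double.xmin)
  }
  p_emp <- (1 + sum(abs(perm - null_mean) >= abs(observed - null_mean))) /
    (n_permutations + 1)

  structure(
    list(
      observed_statistic = observed,
      null_mean = null_mean,
      null_sd = null_sd,
      z = z,
      p_two_tailed = p,
      p_empirical = p_emp,
      n_permutations = n_permutations,
      group_size = k,
      universe_size = n,
      condition_a = condition_a,
      condition_b = condition_b,
      null_values = perm,
      seed = seed
    ),
    class = "perm_trend_test"
  )
}

#' @export
print.perm_trend_test <- function(x, ...) {
  cat("<perm_trend_test>\n")
  cat(sprintf("  observed mean difference (%s - %s): %.4g\n",
              x$condition_b, x$condition_a, x$observed_statistic))
  cat(sprintf("  null: mean %.4g, sd %.4g over %d permutations\n",
              x$null_mean, x$null_sd, x$n_permutations))
  cat(sprintf("  z = %.3f, two-tailed p = %.3g (empirical %.3g)\n",
              x$z, x$p_two_tailed, x$p_empirical))
  invisible(x)
}

#' @export
tidy.perm_trend_test <- function(x, ...) {
  tibble(
    estimate = x$observed_statistic,
    null_mean = x$null_mean,
    null_sd = x$null_sd,
    statistic = x$z,
    p.value = x$p_two_tailed,
    p.empirical = x$p_empirical
  )
}

#' @export
glance.perm_trend_test <- function(x, ...) {
  tibble(
    observed_statistic = x$observed_statistic,
    z = x$z,
    p_two_tailed = x$p_two_tailed,
    p_empirical = x$p_empirical,
    n_permutations = x$n_permutations,
    group_size = x$group_size,
    universe_size = x$universe_size,
    seed = x$seed
  )
}

#' Compare a gene group's expression between two datasets
#'
#' Computes per-gene differences of mean expression between two matrices
#' (e.g. inhibitor-treated versus untreated) for a gene group, and a
#' group-level paired two-sided t test on those differences, optionally
#' repeated within expression strata.  When every paired difference is
#' exactly zero the statistic is 0 and p = 1 by convention.
#'
#' @param expr_a,expr_b expression tibbles sharing the group's genes; means
#'   are taken across each table's samples.
#' @param gene_group character vector of gene ids.
#' @param bin_edges optional increasing RPKM bin edges (passed to
#'   [stratify_by_expression()] on `expr_a`); empty strata are skipped with
#'   a warning.
#' @return tibble with one row per stratum (or a single `all` row):
#'   `stratum`, `n_genes`, `mean_a`, `mean_b`, `mean_diff`, `pct_change`,
#'   `statistic`, `p_value`; the per-gene table is in attribute `genes`.
#' @export
compare_group_expression <- function(expr_a, expr_b, gene_group,
                                     bin_edges = NULL) {
  ma <- expr_to_matrix(expr_a)
  mb <- expr_to_matrix(expr_b)
  shared <- intersect(intersect(gene_group, rownames(ma)), rownames(mb))
  dropped <- setdiff(gene_group, shared)
  if (length(dropped)) {
    warn(paste0(length(dropped), " group gene(s) missing from a matrix; dropped"))
  }
  if (length(shared) < 2) abort("fewer than 2 shared group genes")
  a <- rowMeans(ma[shared, , drop = FALSE])
  b <- rowMeans(mb[shared, , drop = FALSE])
  genes <- tibble(gene_id = shared, mean_a = a, mean_b = b, diff = b - a)

  if (is.null(bin_edges)) {
    genes$stratum <- "all"
  } else {
    strat <- stratify_by_expression(shared, expr_a, bin_edges)
    genes <- left_join(genes, strat[, c("gene_id", "stratum")], by = "gene_id")
  }

  one <- function(g, label) {
    if (nrow(g) < 2) {
      warn(paste0("stratum ", label, " has fewer than 2 genes; skipped"))
      return(NULL)
    }
    if (all(g$diff == 0)) {
      stat <- 0; p <- 1
    } else {
      tt <- t.test(g$diff)
      stat <- unname(tt$statistic); p <- tt$p.value
    }
    tibble(stratum = label, n_genes = nrow(g),
           mean_a = mean(g$mean_a), mean_b = mean(g$mean_b),
           mean_diff = mean(g$diff),
           pct_change = 100 * mean(g$diff) / mean(g$mean_a),
           statistic = stat, p_value = p)
  }
  out <- bind_rows(lapply(split(genes, genes$stratum),
                          function(g) one(g, g$stratum[1])))
  attr(out, "genes") <- genes
  out
}
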