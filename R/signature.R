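#' Select variable genes for the activation axis
#'
#' Collapses replicates to condition means and keeps genes that are both
#' expressed and responsive: maximum condition mean above `min_rpkm` (10 RPKM
#' by default) and at least `min_fold` (2 by default) between the extreme
#' condition means.  The fold denominator is floored at `pseudocount` so
#' genes silent in one condition stay finite.
#'
#' @param expr expression tibble (`gene_id` + sample columns).
#' @param sample_info sample annotation (see [read_expression_table()]).
#' @param min_rpkm expression floor applied to the maximum condition mean
#'   (strictly greater than).
#' @param min_fold minimum max/min condition-mean ratio (at least).
#' @param pseudocount floor for the fold denominator.
#' @return character vector of gene ids (warns when empty).
#' @examples
#' sim <- simulate_expression(n_genes = 100, seed = 1)
#' length(filter_variable_genes(sim$expr, sim$sample_info))
#' @export
filter_variable_genes <- function(expr, sample_info, min_rpkm = 10,
                                  min_fold = 2, pseudocount = 1) {
  m <- expr_to_matrix(expr)
  cm <- condition_mean_matrix(m, sample_info)
  if (ncol(cm) < 2) abort("need at least 2 conditions")
  hi <- apply(cm, 1, max)
  lo <- apply(cm, 1, min)
  keep <- hi > min_rpkm & hi / pmax(lo, pseudocount) >= min_fold
  out <- rownames(cm)[keep]
  if (!length(out)) warn("no genes pass the variable-gene filter")
  out
}

#' Fit the principal activation axis (PC1)
#'
#' Computes the first principal component of the expression matrix with
#' samples as observations and genes as features.  Genes are mean-centered
#' (no unit-variance scaling by default); the loadings are the unit-norm
#' first right-singular direction and the sample scores its projection.  The
#' sign is fixed so that the mean score of the reference condition does not
#' exceed the mean score of the highest-signal condition, making larger
#' scores mean stronger activation.
#'
#' @param expr expression tibble.
#' @param sample_info sample annotation; the condition order (factor levels
#'   or first appearance) defines reference = first, highest signal = last.
#' @param genes optional gene id subset (e.g. from
#'   [filter_variable_genes()]).
#' @param scale also scale genes to unit variance before the fit (off by
#'   default; zero-variance genes are dropped with a warning when on).
#' @param reference_condition condition anchoring the sign convention;
#'   defaults to the first condition.
#' @return a `signature_model`: list with `loadings` (tibble `gene_id`,
#'   `loading`, `gene_mean`), `sample_scores` (tibble `sample`, `condition`,
#'   `score`), `variance_explained`, `reference_condition`, and empty
#'   signature sets until [extract_deciles()] / [derive_signature()] fill
#'   them.
#' @examples
#' sim <- simulate_expression(n_genes = 200, noise_cv = 0, seed = 1)
#' fit <- fit_pc1(sim$expr, sim$sample_info)
#' fit$variance_explained
#' @export
fit_pc1 <- function(expr, sample_info, genes = NULL, scale = FALSE,
                    reference_condition = NULL) {
  m <- expr_to_matrix(expr)
  si <- match_samples(m, sample_info)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing)) {
      abort(paste0("gene(s) not in matrix: ",
                   paste(head(missing, 5), collapse = ", ")))
    }
    m <- m[genes, , drop = FALSE]
  }
  if (nrow(m) < 2) abort("need at least 2 genes")
  if (ncol(m) < 2) abort("need at least 2 samples")

  X <- t(m)                       # samples x genes
  mu <- unname(colMeans(X))
  Xc <- sweep(X, 2, mu)
  if (scale) {
    sds <- apply(Xc, 2, sd)
    drop <- sds == 0
    if (any(drop)) {
      warn(paste0(sum(drop), " zero-variance gene(s) dropped before scaling"))
      Xc <- Xc[, !drop, drop = FALSE]
      mu <- mu[!drop]
    }
    Xc <- sweep(Xc, 2, apply(Xc, 2, sd), "/")
  }
  if (max(abs(Xc)) < .Machine$double.eps * 100) {
    abort("no principal axis: matrix has zero variance")
  }
  sv <- svd(Xc)
  loadings <- sv$v[, 1]
  scores <- unname(drop(Xc %*% loadings))
  ve <- sv$d[1]^2 / sum(sv$d^2)

  lev <- condition_levels(sample_info)
  lev <- lev[lev %in% si$condition]
  ref <- reference_condition %||% lev[1]
  if (!ref %in% si$condition) abort("reference condition has no samples")
  hi <- lev[length(lev)]
  if (mean(scores[si$condition == ref]) > mean(scores[si$condition == hi])) {
    loadings <- -loadings
    scores <- -scores
  }

  structure(
    list(
      loadings = tibble(gene_id = colnames(Xc), loading = loadings,
                        gene_mean = mu),
      sample_scores = tibble(sample = rownames(X),
                             condition = as.character(si$condition),
                             score = scores),
      variance_explained = ve,
      reference_condition = ref,
      condition_order = lev,
      top_set = character(),
      bottom_set = character(),
      fraction = NA_real_,
      scaled = scale
    ),
    class = "signature_model"
  )
}

#' @export
print.signature_model <- function(x, ...) {
  cat("<signature_model>\n")
  cat("  genes:", nrow(x$loadings), "  samples:", nrow(x$sample_scores), "\n")
  cat(sprintf("  PC1 variance explained: %.4f\n", x$variance_explained))
  cat("  reference condition:", x$reference_condition, "\n")
  if (length(x$top_set)) {
    cat("  signature sets: ", length(x$top_set), " top / ",
        length(x$bottom_set), " bottom (fraction ", x$fraction, ")\n",
        sep = "")
  }
  invisible(x)
}

#' Extract the extreme loading deciles
#'
#' Sorts genes by PC1 loading (descending, ties broken by gene id so the
#' result is fully deterministic) and returns the first and last
#' `ceiling(fraction * n)` genes.  When twice that count would exceed the
#' number of genes, both sets are capped at `floor(n / 2)` so they stay
#' disjoint.
#'
#' @param model a `signature_model`.
#' @param fraction fraction of genes per set, in `(0, 0.5]` (default 0.10,
#'   the extreme deciles).
#' @return list with character vectors `top_set` and `bottom_set`.
#' @export
extract_deciles <- function(model, fraction = 0.10) {
  stopifnot(inherits(model, "signature_model"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 0.5) {
    abort("fraction must lie in (0, 0.5]")
  }
  ld <- model$loadings
  ord <- order(-ld$loading, ld$gene_id)
  n <- nrow(ld)
  k <- ceiling(fraction * n)
  if (2 * k > n) {
    warn("fraction too large for disjoint sets; capping at floor(n/2)")
    k <- floor(n / 2)
  }
  sorted <- ld$gene_id[ord]
  list(top_set = head(sorted, k), bottom_set = tail(sorted, k))
}

#' Derive a replicate-consistent activation signature
#'
#' Fits the activation axis separately on each replicate dataset and on the
#' combined dataset, removes genes that are weakly or inconsistently
#' expressed in the reference condition, and keeps as signature genes only
#' those falling in the top (bottom) `fraction` of every fit.  The combined
#' fit, restricted to the surviving genes, is returned for downstream
#' scoring.
#'
#' The reference filters mirror the derivation used for RNA-seq replicates:
#' a gene is dropped when its reference-condition mean in the combined data
#' is below `min_ref_rpkm` (100 RPKM), or when the standard deviation of its
#' reference-condition level across the replicate datasets exceeds
#' `max_ref_cv` (20%) of the mean reference level.  The extreme-`fraction`
#' cut is sized on the full fitted gene universe and the filters then veto
#' membership, so dropping a weakly expressed gene does not shrink the
#' loading rank window for the others (see the methods vignette).
#'
#' @param replicates list of expression tibbles, one per replicate dataset.
#' @param combined expression tibble pooling the replicates.
#' @param sample_info sample annotation covering every sample id appearing
#'   in any dataset.
#' @param min_ref_rpkm reference-condition expression floor.
#' @param max_ref_cv maximum reference-condition coefficient of variation
#'   across replicate datasets (skipped with fewer than 2 replicates).
#' @param fraction per-set fraction passed to [extract_deciles()].
#' @param genes optional gene universe; defaults to the genes shared by all
#'   datasets.
#' @param reference_condition reference condition label; defaults to the
#'   first condition.
#' @return a `signature_model` restricted to the surviving genes with
#'   `top_set` / `bottom_set` filled; the element `derivation` records the
#'   per-dataset fits, the per-dataset decile sets and the dropped genes.
#'   Empty intersections yield empty sets with a warning, not an error.
#' @examples
#' sim <- simulate_expression(n_genes = 300, seed = 4)
#' reps <- split_replicates(sim$expr, sim$sample_info)
#' sig <- derive_signature(reps, sim$expr, sim$sample_info)
#' length(sig$top_set)
#' @export
derive_signature <- function(replicates, combined, sample_info,
                             min_ref_rpkm = 100, max_ref_cv = 0.20,
                             fraction = 0.10, genes = NULL,
                             reference_condition = NULL) {
  if (!length(replicates)) abort("need at least one replicate dataset")
  datasets <- c(unname(replicates), list(combined))
  names(datasets) <- c(paste0("replicate_", seq_along(replicates)), "combined")
  mats <- lapply(datasets, expr_to_matrix)
  universe <- Reduce(intersect, lapply(mats, rownames))
  if (!is.null(genes)) universe <- intersect(universe, genes)
  if (length(universe) < 2) abort("shared gene universe has fewer than 2 genes")

  fits <- lapply(datasets, fit_pc1, sample_info = sample_info,
                 genes = universe, reference_condition = reference_condition)
  ref <- fits$combined$reference_condition

  ref_mean <- function(m) {
    si <- match_samples(m, sample_info)
    rowMeans(m[universe, si$condition == ref, drop = FALSE])
  }
  combined_ref <- ref_mean(mats$combined)
  low <- combined_ref < min_ref_rpkm

  if (length(replicates) >= 2) {
    rep_ref <- vapply(mats[seq_along(replicates)], ref_mean,
                      numeric(length(universe)))
    ref_sd <- apply(rep_ref, 1, sd)
    ref_mu <- rowMeans(rep_ref)
    noisy <- ref_sd > max_ref_cv * ref_mu
  } else {
    noisy <- rep(FALSE, length(universe))
  }
  surviving <- universe[!(low | noisy)]
  if (length(surviving) < 2) {
    warn("fewer than 2 genes survive the reference filters")
  }

  per_set <- lapply(fits, function(f) {
    sets <- extract_deciles(f, fraction)
    list(top_set = intersect(sets$top_set, surviving),
         bottom_set = intersect(sets$bottom_set, surviving))
  })
  top <- Reduce(intersect, lapply(per_set, `[[`, "top_set"))
  bottom <- Reduce(intersect, lapply(per_set, `[[`, "bottom_set"))
  if (!length(top) && !length(bottom)) {
    warn("signature intersection is empty")
  }

  model <- fits$combined
  model$loadings <- model$loadings[model$loadings$gene_id %in% surviving, ,
                                   drop = FALSE]
  model$top_set <- sort(top)
  model$bottom_set <- sort(bottom)
  model$fraction <- fraction
  model$derivation <- list(
    n_universe = length(universe),
    n_surviving = length(surviving),
    dropped_low_reference = universe[low],
    dropped_noisy_reference = universe[noisy & !low],
    per_dataset_sets = per_set,
    parameters = list(min_ref_rpkm = min_ref_rpkm, max_ref_cv = max_ref_cv,
                      fraction = fraction)
  )
  model
}

#' Split a pooled expression matrix into replicate datasets
#'
#' Convenience inverse of pooling: returns one expression tibble per
#' replicate label in `sample_info`.
#'
#' @param expr pooled expression tibble.
#' @param sample_info sample annotation with a `replicate` column.
#' @return named list of expression tibbles.
#' @export
split_replicates <- function(expr, sample_info) {
  check_sample_info(sample_info)
  if (!"replicate" %in% names(sample_info)) {
    abort("sample_info needs a `replicate` column")
  }
  reps <- unique(sample_info$replicate)
  setNames(lapply(reps, function(r) {
    keep <- sample_info$sample[sample_info$replicate == r]
    expr[, c("gene_id", intersect(names(expr), keep)), drop = FALSE]
  }), paste0("replicate_", reps))
}

#' Serialize / restore a signature model as JSON
#'
#' @param model a `signature_model`.
#' @param path output path.
#' @return `path` (write) or the restored model (read).
#' @export
write_signature_model <- function(model, path) {
  stopifnot(inherits(model, "signature_model"))
  payload <- list(
    loadings = model$loadings,
    sample_scores = model$sample_scores,
    variance_explained = model$variance_explained,
    reference_condition = model$reference_condition,
    condition_order = model$condition_order,
    top_set = model$top_set,
    bottom_set = model$bottom_set,
    fraction = model$fraction,
    scaled = isTRUE(model$scaled)
  )
  jsonlite::write_json(payload, path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_signature_model
#' @export
read_signature_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      loadings = as_tibble(p$loadings),
      sample_scores = as_tibble(p$sample_scores),
      variance_explained = p$variance_explained,
      reference_condition = p$reference_condition,
      condition_order = p$condition_order,
      top_set = as.character(p$top_set %||% character()),
      bottom_set = as.character(p$bottom_set %||% character()),
      fraction = p$fraction %||% NA_real_,
      scaled = isTRUE(p$scaled)
    ),
    class = "signature_model"
  )
}

#' @export
tidy.signature_model <- function(x, ...) {
  mutate(
    x$loadings,
    in_top = .data$gene_id %in% x$top_set,
    in_bottom = .data$gene_id %in% x$bottom_set
  )
}

#' @export
glance.signature_model <- function(x, ...) {
  tibble(
    n_genes = nrow(x$loadings),
    n_samples = nrow(x$sample_scores),
    variance_explained = x$variance_explained,
    n_top = length(x$top_set),
    n_bottom = length(x$bottom_set),
    fraction = x$fraction,
    reference_condition = x$reference_condition
  )
}
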