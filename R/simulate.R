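#' Simulate a graded-stimulation expression matrix with ground truth
#'
#' Generates an RPKM-like gene-by-sample matrix emulating a stimulation
#' series: a reference (unstimulated) condition followed by conditions of
#' strictly increasing signal strength.  Four gene classes are planted:
#'
#' * `analog_up`: condition mean `baseline * (1 + (effect - 1) * s_c)`,
#'   increasing with the planted signal strength `s_c`;
#' * `analog_down`: mirrored, `baseline * (1 + (effect - 1) * (1 - s_c))`,
#'   decreasing from `baseline * effect` to `baseline`;
#' * `digital`: `baseline` in the reference condition and
#'   `baseline * effect` in every non-reference condition (all-or-none
#'   induction); digital baselines are drawn low, matching genes that are
#'   near-silent before stimulation;
#' * `null`: constant at `baseline`.
#'
#' Replicate columns are independent draws of multiplicative log-normal noise
#' with the requested coefficient of variation, so `noise_cv = 0` returns the
#' closed-form means exactly.  The generator is a pure function of its
#' arguments and `seed`.
#'
#' @param n_genes number of genes.
#' @param class_proportions named numeric proportions for
#'   `analog_up`, `analog_down`, `digital`, `null`; must sum to 1
#'   (tolerance 1e-9).
#' @param signal_strengths per-condition signal strengths in `[0, 1]`,
#'   strictly increasing; the first condition is the reference.  The default
#'   places two middle conditions close together, mimicking stimulation doses
#'   of near-identical potency.
#' @param effect_size_range fold-change range (`> 1`) for non-null genes.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param n_replicates replicate columns per condition.
#' @param baseline_meanlog,baseline_sdlog log-normal baseline parameters for
#'   analog and null genes.
#' @param digital_baseline_meanlog log-normal mean (log scale) of digital
#'   gene baselines.
#' @param condition_names optional condition labels (reference first).
#' @param seed integer seed.
#' @return a list with
#'   * `expr`: tibble `gene_id` + one column per sample;
#'   * `sample_info`: tibble `sample`, `condition` (factor in series order),
#'     `replicate`;
#'   * `truth`: tibble `gene_id`, `class`, `baseline`, `effect_size`;
#'   * `signal_strengths`: named per-condition strengths;
#'   * `params`: the generator call parameters.
#' @examples
#' sim <- simulate_expression(n_genes = 50, noise_cv = 0, seed = 1)
#' head(sim$truth)
#' @export
simulate_expression <- function(n_genes = 3000,
                                class_proportions = c(analog_up = 0.10,
                                                      analog_down = 0.10,
                                                      digital = 0.05,
                                                      null = 0.75),
                                signal_strengths = c(0, 0.45, 0.55, 0.6, 1),
                                effect_size_range = c(2, 8),
                                noise_cv = 0.10,
                                n_replicates = 2,
                                baseline_meanlog = log(300),
                                baseline_sdlog = 0.4,
                                digital_baseline_meanlog = log(20),
                                condition_names = NULL,
                                seed = 1L) {
  need <- c("analog_up", "analog_down", "digital", "null")
  if (!all(need %in% names(class_proportions))) {
    abort("class_proportions must name analog_up, analog_down, digital, null")
  }
  class_proportions <- class_proportions[need]
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    abort("class_proportions must sum to 1 (tolerance 1e-9)")
  }
  if (length(signal_strengths) < 2) abort("need at least 2 conditions")
  if (any(diff(signal_strengths) <= 0)) {
    abort("signal_strengths must be strictly increasing")
  }
  if (any(effect_size_range <= 1)) abort("effect sizes must exceed 1")
  if (noise_cv < 0) abort("noise_cv must be non-negative")

  k <- length(signal_strengths)
  conds <- condition_names %||% paste0("C", seq_len(k))
  stopifnot(length(conds) == k)
  names(signal_strengths) <- conds

  # Integer class counts that sum to n_genes (largest-remainder allocation).
  raw <- class_proportions * n_genes
  counts <- floor(raw)
  rem <- n_genes - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  classes <- rep(names(counts), counts)

  withr::with_seed(seed, {
    width <- max(4, nchar(n_genes))
    gene_id <- sprintf(paste0("gene_%0", width, "d"), seq_len(n_genes))
    baseline <- ifelse(
      classes == "digital",
      rlnorm(n_genes, digital_baseline_meanlog, baseline_sdlog),
      rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
    )
    effect <- ifelse(
      classes == "null", 1,
      runif(n_genes, effect_size_range[1], effect_size_range[2])
    )

    # Closed-form condition means, genes x conditions.
    s <- matrix(signal_strengths, nrow = n_genes, ncol = k, byrow = TRUE)
    mean_mat <- matrix(baseline, n_genes, k)
    up <- classes == "analog_up"
    dn <- classes == "analog_down"
    dg <- classes == "digital"
    mean_mat[up, ] <- baseline[up] * (1 + (effect[up] - 1) * s[up, , drop = FALSE])
    mean_mat[dn, ] <- baseline[dn] * (1 + (effect[dn] - 1) * (1 - s[dn, , drop = FALSE]))
    mean_mat[dg, ] <- baseline[dg] *
      (1 + (effect[dg] - 1) * (s[dg, , drop = FALSE] > s[1, 1]))

    samples <- paste0(rep(conds, each = n_replicates), "_r",
                      rep(seq_len(n_replicates), k))
    vals <- mean_mat[, rep(seq_len(k), each = n_replicates), drop = FALSE]
    if (noise_cv > 0) {
      p <- lnorm_cv_params(noise_cv)
      vals <- vals * matrix(rlnorm(length(vals), p$meanlog, p$sdlog),
                            nrow = n_genes)
    }
    colnames(vals) <- samples

    expr <- tibble(gene_id = gene_id)
    for (j in seq_along(samples)) expr[[samples[j]]] <- vals[, j]
    sample_info <- tibble(
      sample = samples,
      condition = factor(rep(conds, each = n_replicates), levels = conds),
      replicate = rep(seq_len(n_replicates), k)
    )
    truth <- tibble(gene_id = gene_id, class = classes,
                    baseline = baseline, effect_size = effect)
    list(
      expr = expr, sample_info = sample_info, truth = truth,
      signal_strengths = signal_strengths,
      params = list(n_genes = n_genes, class_proportions = class_proportions,
                    signal_strengths = signal_strengths,
                    effect_size_range = effect_size_range,
                    noise_cv = noise_cv, n_replicates = n_replicates,
                    seed = seed)
    )
  })
}

#' Simulate per-condition peak landscapes with planted events
#'
#' Builds two-condition (unstimulated/stimulated) peak sets with known
#' structure: background peaks whose normalized tags are shared across
#' conditions up to noise, a planted subset multiplied by `gain_fold` (> 2)
#' in the stimulated condition, and planted super-enhancer regions, each a
#' cluster of `peaks_per_se` high-tag peaks within a span smaller than the
#' usual stitching distance.  Background peaks are kept at least
#' `isolation_bp` away from planted regions so each planted region stitches
#' into exactly one merged region.
#'
#' Background tags are drawn from a light-tailed gamma (mean
#' `background_mean`, shape `background_shape`), emulating a homogeneous
#' pool of typical enhancers so that the planted regions form the distinct
#' upper tail of the rank-score curve.  Real acetylation landscapes are
#' heavier-tailed — there the tangent threshold falls inside the continuum
#' of strong enhancers rather than at a clean gap (see the methods
#' vignette).
#'
#' @param n_background number of background peaks.
#' @param n_gain number of background peaks receiving the stimulated gain.
#' @param gain_fold fold gain in the stimulated condition; must exceed 2.
#' @param n_superenhancers number of planted super-enhancer regions.
#' @param peaks_per_se constituent peaks per planted region.
#' @param se_span span (bp) containing each planted region's peaks.
#' @param genome tibble `chrom`, `length` describing the assembly.
#' @param noise_cv coefficient of variation of cross-condition tag noise.
#' @param background_mean,background_shape gamma tag parameters for
#'   background peaks (scale = mean / shape).
#' @param se_peak_meanlog,se_peak_sdlog log-normal tag parameters for planted
#'   super-enhancer constituent peaks.
#' @param se_stim_fold fold applied to planted-region tags in the stimulated
#'   condition (recycled across regions).
#' @param peak_width width (bp) of every simulated peak.
#' @param isolation_bp exclusion zone around planted regions.
#' @param conditions the two condition (tag column) names.
#' @param seed integer seed.
#' @return list with `peaks` (tibble `chrom, start, end, peak_id, strand` plus
#'   one tag column per condition) and `truth` (list: `gain_peaks`,
#'   `se_regions` tibble, `params`).
#' @export
simulate_peaks <- function(n_background = 2000,
                           n_gain = 100,
                           gain_fold = 4,
                           n_superenhancers = 20,
                           peaks_per_se = 10,
                           se_span = 8000,
                           genome = tibble(chrom = c("chr1", "chr2", "chr3"),
                                           length = 1e8),
                           noise_cv = 0.05,
                           background_mean = 100,
                           background_shape = 50,
                           se_peak_meanlog = log(1500),
                           se_peak_sdlog = 0.3,
                           se_stim_fold = 1,
                           peak_width = 500,
                           isolation_bp = 15000,
                           conditions = c("unstimulated", "stimulated"),
                           seed = 1L) {
  if (gain_fold <= 2) abort("gain_fold must exceed 2")
  if (n_gain > n_background) abort("n_gain cannot exceed n_background")
  stopifnot(length(conditions) == 2)
  footprint <- n_superenhancers * (se_span + 2 * isolation_bp) +
    (n_background + 1) * 2 * peak_width
  if (footprint > sum(genome$length)) {
    abort("genome too small to place the requested non-overlapping regions")
  }

  withr::with_seed(seed, {
    # Place planted regions first: rejection-sample non-overlapping spans
    # (padded by isolation_bp) across chromosomes.
    se_regions <- tibble(chrom = character(), start = numeric(), end = numeric())
    tries <- 0
    while (nrow(se_regions) < n_superenhancers) {
      tries <- tries + 1
      if (tries > 200 * max(1, n_superenhancers)) {
        abort("genome too small to place non-overlapping planted regions")
      }
      ci <- sample.int(nrow(genome), 1)
      len <- genome$length[ci]
      if (len < se_span + 2 * isolation_bp) next
      st <- floor(runif(1, isolation_bp, len - se_span - isolation_bp))
      clash <- se_regions$chrom == genome$chrom[ci] &
        se_regions$start < st + se_span + 2 * isolation_bp &
        se_regions$end > st - 2 * isolation_bp
      if (any(clash)) next
      se_regions <- bind_rows(se_regions,
                              tibble(chrom = genome$chrom[ci],
                                     start = st, end = st + se_span))
    }
    se_regions <- arrange(se_regions, .data$chrom, .data$start)
    se_regions$se_id <- sprintf("se_%03d", seq_len(nrow(se_regions)))

    # Background positions: uniform, thinned so consecutive background peaks
    # stay more than isolation_bp apart (each remains its own stitched
    # region) and clear of the planted exclusion zones.
    placed <- vector("list", nrow(genome))
    target <- ceiling(n_background * genome$length / sum(genome$length)) + 50
    for (ci in seq_len(nrow(genome))) {
      cand <- sort(floor(runif(4 * target[ci], 0,
                               genome$length[ci] - peak_width)))
      keep <- c(TRUE, diff(cand) > isolation_bp + peak_width)
      cand <- cand[keep]
      reg <- se_regions[se_regions$chrom == genome$chrom[ci], , drop = FALSE]
      if (nrow(reg)) {
        inside <- rep(FALSE, length(cand))
        for (r in seq_len(nrow(reg))) {
          inside <- inside | (cand + peak_width > reg$start[r] - isolation_bp &
                                cand < reg$end[r] + isolation_bp)
        }
        cand <- cand[!inside]
      }
      placed[[ci]] <- tibble(chrom = genome$chrom[ci], start = cand)
    }
    bg <- bind_rows(placed)
    if (nrow(bg) < n_background) {
      abort("genome too small to place the requested background peaks")
    }
    bg <- bg[sort(sample.int(nrow(bg), n_background)), , drop = FALSE]
    bg$end <- bg$start + peak_width

    base_tags <- stats::rgamma(n_background, shape = background_shape,
                               scale = background_mean / background_shape)
    gain_idx <- sample.int(n_background, n_gain)
    fold <- rep(1, n_background)
    fold[gain_idx] <- gain_fold
    noise <- function(n) {
      if (noise_cv > 0) {
        p <- lnorm_cv_params(noise_cv)
        rlnorm(n, p$meanlog, p$sdlog)
      } else rep(1, n)
    }
    bg[[conditions[1]]] <- base_tags
    bg[[conditions[2]]] <- base_tags * fold * noise(n_background)

    # Planted super-enhancer constituent peaks.
    se_fold <- rep_len(se_stim_fold, nrow(se_regions))
    se_peaks <- purrr::map_dfr(seq_len(nrow(se_regions)), function(r) {
      slots <- floor(seq(se_regions$start[r],
                         se_regions$end[r] - peak_width,
                         length.out = peaks_per_se))
      tg <- rlnorm(peaks_per_se, se_peak_meanlog, se_peak_sdlog)
      out <- tibble(chrom = se_regions$chrom[r], start = slots,
                    end = slots + peak_width)
      out[[conditions[1]]] <- tg
      out[[conditions[2]]] <- tg * se_fold[r] * noise(peaks_per_se)
      out
    })

    peaks <- bind_rows(bg, se_peaks)
    peaks <- arrange(peaks, .data$chrom, .data$start)
    peaks$peak_id <- sprintf("peak_%05d", seq_len(nrow(peaks)))
    peaks$strand <- "+"
    peaks <- peaks[, c("chrom", "start", "end", "peak_id", "strand",
                       conditions)]

    gain_ids <- peaks$peak_id[match(
      paste(bg$chrom[gain_idx], bg$start[gain_idx]),
      paste(peaks$chrom, peaks$start)
    )]
    list(
      peaks = peaks,
      truth = list(
        gain_peaks = sort(gain_ids),
        se_regions = se_regions[, c("se_id", "chrom", "start", "end")],
        params = list(n_background = n_background, n_gain = n_gain,
                      gain_fold = gain_fold,
                      n_superenhancers = n_superenhancers,
                      peaks_per_se = peaks_per_se, se_span = se_span,
                      noise_cv = noise_cv, seed = seed)
      )
    )
  })
}

#' Simulate a TSS-anchored per-base tag profile
#'
#' Emulates the coverage shapes seen at promoters: `focal_tss` concentrates
#' tags in a narrow peak at the transcription start site (at least 80% within
#' +/-500 bp), `spread_body` distributes tags uniformly from the promoter
#' across the first 4,000 bp of the gene body (the spreading pattern), and
#' `uniform` is flat across the whole window.
#'
#' @param shape one of `"focal_tss"`, `"spread_body"`, `"uniform"`.
#' @param window_bp total window width in bp (at least 4000); the window is
#'   centred so that offsets run from `-window_bp/2` to `window_bp/2 - 1`
#'   relative to the TSS, strand-corrected (positive = downstream).
#' @param depth mean per-base tag density of the profile.
#' @param noise_sd per-base additive Gaussian jitter (truncated at 0).
#' @param seed integer seed.
#' @return tibble `offset`, `coverage`.
#' @export
simulate_tag_profile <- function(shape = c("focal_tss", "spread_body", "uniform"),
                                 window_bp = 12000,
                                 depth = 10,
                                 noise_sd = 0,
                                 seed = 1L) {
  shape <- match.arg(shape)
  if (window_bp < 4000) abort("window_bp must be at least 4000")
  if (depth <= 0) abort("depth must be positive")
  half <- floor(window_bp / 2)
  offset <- seq(-half, half - 1)
  n <- length(offset)
  total <- depth * n
  withr::with_seed(seed, {
    coverage <- switch(shape,
      uniform = rep(depth, n),
      focal_tss = {
        # 90% of tags in a Gaussian of sd 250 bp at the TSS, rest uniform.
        core <- stats::dnorm(offset, 0, 250)
        0.9 * total * core / sum(core) + 0.1 * total / n
      },
      spread_body = {
        # Uniform over promoter plus first 4000 bp of the body.
        span <- offset >= -1000 & offset < 4000
        v <- numeric(n)
        v[span] <- total / sum(span)
        v
      }
    )
    if (noise_sd > 0) {
      coverage <- pmax(0, coverage + stats::rnorm(n, 0, noise_sd))
    }
    tibble(offset = offset, coverage = coverage)
  })
}
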