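test_that("scoring reproduces the hand dot-product oracle", {
  model <- make_model(c("g1", "g2"), c(0.8, -0.6))
  # columns are samples: A = (1, 1), B = (2, -1), already centered
  expr <- tibble::tibble(gene_id = c("g1", "g2"), A = c(1, 1), B = c(2, -1))
  res <- score_samples(expr, model, center = "none")
  expect_equal(res$raw_score, c(0.8 * 1 - 0.6 * 1, 0.8 * 2 - 0.6 * -1),
               tolerance = 1e-12)
  expect_equal(res$raw_score, c(0.2, 2.2), tolerance = 1e-12)
  expect_equal(res$scaled_score, c(0.2 / 2.2, 1.0), tolerance = 1e-12)
})

test_that("a sample equal to the gene-wise mean scores zero", {
  model <- make_model(c("g1", "g2"), c(0.7, 0.3))
  # third sample is the average of the first two, hence equals the gene mean
  expr <- tibble::tibble(gene_id = c("g1", "g2"),
                         a = c(10, 2), b = c(4, 8), c = c(7, 5))
  res <- score_samples(expr, model, center = "scored")
  expect_equal(res$raw_score[res$sample == "c"], 0, tolerance = 1e-12)
})

test_that("scaled scores stay in [-1, 1] with the extreme sample at 1", {
  sim <- simulate_expression(n_genes = 300, seed = 21)
  fit <- fit_pc1(sim$expr, sim$sample_info)
  res <- score_samples(sim$expr, fit)
  expect_true(all(abs(res$scaled_score) <= 1 + 1e-12))
  expect_equal(max(abs(res$scaled_score)), 1)

  # invariant under sample relabeling
  expr2 <- sim$expr
  names(expr2)[-1] <- paste0("x", seq_along(names(expr2)[-1]))
  res2 <- score_samples(expr2, fit)
  expect_equal(res2$raw_score, res$raw_score)
})

test_that("raw scores are invariant to per-gene constant shifts", {
  sim <- simulate_expression(n_genes = 100, seed = 5)
  fit <- fit_pc1(sim$expr, sim$sample_info)
  shifted <- sim$expr
  shift <- seq_len(nrow(shifted))
  for (s in names(shifted)[-1]) shifted[[s]] <- shifted[[s]] + shift
  expect_equal(score_samples(shifted, fit)$raw_score,
               score_samples(sim$expr, fit)$raw_score, tolerance = 1e-9)
})

test_that("scores on noiseless data are monotone in planted strength", {
  sim <- simulate_expression(n_genes = 500, noise_cv = 0, seed = 1)
  fit <- fit_pc1(sim$expr, sim$sample_info)
  res <- score_samples(sim$expr, fit)
  si <- sim$sample_info
  strength <- sim$signal_strengths[as.character(
    si$condition[match(res$sample, si$sample)])]
  expect_equal(cor(res$scaled_score, strength, method = "spearman"), 1)
  expect_equal(max(abs(res$scaled_score)), 1)
})

test_that("scoring errors on insufficient gene overlap and degenerate input", {
  model <- make_model(paste0("g", 1:10), seq(-1, 1, length.out = 10))
  expr <- tibble::tibble(gene_id = paste0("g", 1:4),
                         a = 1:4, b = 4:1)
  expect_error(score_samples(expr, model), "50")

  flat <- tibble::tibble(gene_id = paste0("g", 1:10), a = rep(2, 10),
                         b = rep(2, 10))
  expect_warning(res <- score_samples(flat, model), "zero")
  expect_equal(res$scaled_score, c(0, 0))
})

test_that("group ranking averages, orders and flags ties", {
  scores <- tibble::tibble(sample = c("a", "b", "c", "d"),
                           raw_score = c(1, 2, 1, 2),
                           scaled_score = c(0.2, 0.9, 0.2, 0.9),
                           rank = c(3L, 1L, 3L, 1L))
  groups <- tibble::tibble(sample = c("a", "b", "c", "d"),
                           group = c("g1", "g1", "g2", "g2"))
  out <- rank_experiment_groups(scores, groups)
  expect_equal(out$mean_scaled_score, c(0.55, 0.55))
  expect_true(all(out$tied))

  single <- rank_experiment_groups(scores[1:2, ],
                                   groups[1:2, ] |>
                                     dplyr::mutate(group = "only"))
  expect_equal(single$mean_scaled_score, 0.55)

  expect_error(rank_experiment_groups(scores, groups[1:2, ]), "unlabelled")
})

test_that("group = universe collapses the permutation test to z = 0, p = 1", {
  sim <- simulate_expression(n_genes = 40, seed = 9)
  tt <- permutation_trend_test(sim$expr, sim$sample_info,
                               sim$expr$gene_id, "C1", "C5",
                               n_permutations = 50, seed = 1)
  expect_equal(tt$z, 0)
  expect_equal(tt$p_two_tailed, 1)
})

test_that("normal-approximation p agrees with exact enumeration on 8 genes", {
  d <- (1:8) / 10
  expr <- tibble::tibble(gene_id = paste0("g", 1:8),
                         s1 = rep(1, 8), s2 = 1 + d)
  si <- tibble::tibble(sample = c("s1", "s2"), condition = c("a", "b"))
  group <- c("g7", "g8")

  # oracle: enumerate all choose(8, 2) = 28 groups
  combos <- combn(8, 2)
  stats <- apply(combos, 2, function(ix) mean(d[ix]))
  obs <- mean(d[7:8])
  exact_p <- mean(abs(stats - mean(stats)) >= abs(obs - mean(stats)) - 1e-12)

  tt <- permutation_trend_test(expr, si, group, "a", "b",
                               n_permutations = 20000, seed = 3)
  expect_lt(abs(tt$p_two_tailed - exact_p), 0.1)  # documented bound
  expect_lt(abs(tt$p_empirical - exact_p), 0.05)
})

test_that("the permutation test is deterministic per seed", {
  sim <- simulate_expression(n_genes = 100, seed = 2)
  grp <- sim$expr$gene_id[1:10]
  a <- permutation_trend_test(sim$expr, sim$sample_info, grp, "C1", "C5",
                              n_permutations = 200, seed = 42)
  b <- permutation_trend_test(sim$expr, sim$sample_info, grp, "C1", "C5",
                              n_permutations = 200, seed = 42)
  expect_identical(glance(a), glance(b))
})

test_that("p-values fall monotonically with planted effect size", {
  p_at_effect <- vapply(c(1.5, 3, 6), function(eff) {
    m <- matrix(100, 60, 2, dimnames = list(sprintf("g%02d", 1:60), c("s1", "s2")))
    m[1:8, 2] <- 100 * eff   # planted group induced in condition b
    m[, 2] <- m[, 2] + seq(0, 5.9, 0.1)  # mild gradient so the null has spread
    fx <- make_expr(m, conditions = c("a", "b"))
    permutation_trend_test(fx$expr, fx$sample_info, sprintf("g%02d", 1:8),
                           "a", "b", n_permutations = 2000, seed = 1)$p_two_tailed
  }, numeric(1))
  expect_true(all(diff(p_at_effect) < 0))
})

test_that("group expression comparison handles identity and scaling", {
  sim <- simulate_expression(n_genes = 60, seed = 4)
  grp <- sim$expr$gene_id[1:10]
  same <- compare_group_expression(sim$expr, sim$expr, grp)
  expect_equal(same$mean_diff, 0)
  expect_equal(same$p_value, 1)

  halved <- sim$expr
  for (s in names(halved)[-1]) halved[[s]] <- halved[[s]] / 2
  expect_warning(
    res <- compare_group_expression(sim$expr, halved, grp,
                                    bin_edges = c(0, 150, 400, Inf)),
    "fewer than 2 genes"
  )
  expect_true(all(abs(res$pct_change - (-50)) < 1e-9))
})

test_that("an inhibitor-like shrink of the signature group is detected", {
  sim <- simulate_expression(n_genes = 500, noise_cv = 0, seed = 8)
  up <- sim$truth$gene_id[sim$truth$class == "analog_up"]
  nulls <- sim$truth$gene_id[sim$truth$class == "null"]
  treated <- sim$expr
  sel <- treated$gene_id %in% up
  for (s in names(treated)[-1]) {
    treated[[s]][sel] <- treated[[s]][sel] * 0.6  # dampened induction
  }
  hit <- compare_group_expression(sim$expr, treated, up)
  expect_lt(hit$mean_diff, 0)
  expect_lt(hit$p_value, 0.01)
  unaffected <- compare_group_expression(sim$expr, treated, nulls)
  expect_equal(unaffected$mean_diff, 0)
})
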