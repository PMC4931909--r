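test_that("tag thresholding is inclusive at the floor", {
  pk <- make_peaks("chr1", c(0, 100, 200), c(50, 150, 250),
                   tags = c(39, 40, 41))
  kept <- threshold_peaks(pk, min_tags = 40)
  expect_setequal(kept$peak_id, c("pk2", "pk3"))
  empty <- threshold_peaks(pk[0, ], min_tags = 40)
  expect_equal(nrow(empty), 0)
  expect_error(threshold_peaks(pk, condition = "nope"), "nope")
})

test_that("overlap tables count each peak once with a thresholded diagonal", {
  A <- make_peaks("chr1", c(0, 200), c(100, 300), tags = c(50, 60))
  B <- make_peaks("chr1", 90, 110, tags = 70)
  tab <- overlap_table(list(A = A, B = B))
  expect_equal(tab["A", "A"], 2L)
  expect_equal(tab["B", "B"], 1L)
  expect_equal(tab["A", "B"], 1L)
  expect_equal(tab["B", "A"], 1L)

  # disjoint chromosomes never overlap
  C <- make_peaks("chr2", c(0, 200), c(100, 300), tags = c(50, 60))
  tab2 <- overlap_table(list(A = A, C = C))
  expect_equal(tab2["A", "C"], 0L)
  expect_equal(tab2["C", "A"], 0L)

  # thresholding applies to both sides
  tab3 <- overlap_table(list(A = A, B = B), min_tags = 65)
  expect_equal(tab3["A", "A"], 0L)
  expect_equal(tab3["B", "A"], 0L)
})

test_that("overlap counts match the brute-force oracle and its bounds", {
  withr::local_seed(31)
  A <- random_intervals(400)
  B <- random_intervals(300)
  tab <- overlap_table(list(A = A, B = B), min_tags = 0)
  expect_equal(tab["A", "B"], bf_overlap_count(A, B))
  expect_equal(tab["B", "A"], bf_overlap_count(B, A))
  expect_lte(tab["A", "B"], min(nrow(A), nrow(B)))

  # A region-wise subset of B overlaps completely
  sub <- B[1:50, ]
  sub$peak_id <- paste0("s", 1:50)
  tabs <- overlap_table(list(S = sub, B = B), min_tags = 0)
  expect_equal(tabs["S", "B"], 50L)
})

test_that("fold-change classification is strict, pseudocounted and antisymmetric", {
  pk <- make_peaks("chr1", c(0, 100, 200), c(50, 150, 250))
  pk$np <- c(10, 10, 0)
  pk$pcc <- c(25, 20, 5)
  out <- classify_fold_change(pk, "np", "pcc", pseudocount = 0)
  expect_equal(out$label[1:2], c("up", "unchanged"))  # 2.5 > 2; 2 not > 2
  out_pc <- classify_fold_change(pk, "np", "pcc", pseudocount = 1)
  expect_equal(out_pc$label[3], "up")                 # 6/1 > 2

  swapped <- classify_fold_change(pk, "pcc", "np", pseudocount = 1)
  map <- c(up = "down", down = "up", unchanged = "unchanged")
  expect_equal(swapped$label, unname(map[out_pc$label]))
})

test_that("site aggregation equals the closed form and a brute-force sum", {
  # uniform coverage: one tag of weight d at every base
  sites <- tibble::tibble(chrom = "chr1", pos = c(5000, 9000, 13000))
  tags <- tibble::tibble(chrom = "chr1", pos = 0:20000,
                         condA = 3, condB = 5)
  res <- aggregate_tags_at_sites(sites, tags, c("condA", "condB"),
                                 window_bp = 1000)
  expect_equal(res$total, c(3, 5) * 3 * 2000)
  expect_equal(res$mean_per_site, c(3, 5) * 2000)

  # irregular fixture vs per-base brute force
  withr::local_seed(12)
  tags2 <- tibble::tibble(chrom = "chr1",
                          pos = sort(sample(0:20000, 500)),
                          condA = runif(500, 0, 4),
                          condB = runif(500, 0, 4))
  res2 <- aggregate_tags_at_sites(sites, tags2, c("condA", "condB"),
                                  window_bp = 750)
  bf <- sapply(c("condA", "condB"), function(cc) {
    sum(sapply(sites$pos, function(p) {
      sum(tags2[[cc]][tags2$pos >= p - 750 & tags2$pos < p + 750])
    }))
  })
  expect_equal(res2$total, unname(bf))
  expect_error(aggregate_tags_at_sites(sites[0, ], tags, "condA"), "empty")
})

test_that("monotone planted acetylation yields monotone aggregate totals", {
  sites <- tibble::tibble(chrom = "chr1", pos = seq(10000, 90000, 10000))
  strengths <- c(C1 = 0.1, C2 = 0.4, C3 = 0.7, C4 = 1)
  tags <- tibble::tibble(chrom = "chr1", pos = rep(sites$pos, each = 11) +
                           rep(-5:5, 9))
  for (cc in names(strengths)) tags[[cc]] <- 50 * strengths[[cc]]
  res <- aggregate_tags_at_sites(sites, tags, names(strengths), window_bp = 500)
  expect_true(all(diff(res$total) > 0))
})

test_that("spreading ratio is exact on uniform coverage and scale invariant", {
  u <- simulate_tag_profile("uniform", depth = 4, seed = 1)
  expect_identical(spreading_ratio(u), 1)

  f <- simulate_tag_profile("focal_tss", seed = 1)
  s <- simulate_tag_profile("spread_body", seed = 1)
  rf <- spreading_ratio(f)
  rs <- spreading_ratio(s)
  expect_lt(rf, 1)
  expect_equal(rs, 1, tolerance = 1e-9)
  expect_gt(rs, rf)

  scaled <- f
  scaled$coverage <- scaled$coverage * 17.3
  expect_equal(spreading_ratio(scaled), rf, tolerance = 1e-12)
})

test_that("spreading ratio flags truncated windows and empty promoters", {
  short <- tibble::tibble(offset = -500:2499, coverage = 1)
  expect_warning(r <- spreading_ratio(short), "available positions")
  expect_equal(r, 1)
  empty_prom <- tibble::tibble(offset = 1000:3999, coverage = 1)
  expect_warning(expect_warning(spreading_ratio(empty_prom), "available"),
                 "pseudo-density")
})

test_that("TSS-anchored profiles are strand aware", {
  tags <- tibble::tibble(chrom = "chr1", pos = c(990, 1010), tags = c(3, 7))
  plus <- make_genes("chr1", 1000, "+")
  minus <- make_genes("chr1", 1000, "-")
  p <- tag_profile_around(tags, plus, upstream = 50, downstream = 50)
  m <- tag_profile_around(tags, minus, upstream = 50, downstream = 50)
  expect_equal(p$coverage[p$offset == 10], 7)
  expect_equal(m$coverage[m$offset == 10], 3)  # downstream flips on minus
})

test_that("promoter binding frequency counts in-window sites per group", {
  genes <- make_genes("chr1", c(1000, 5000, 9000, 13000),
                      ids = paste0("g", 1:4))
  none <- promoter_binding_frequency(
    list(batf = tibble::tibble(chrom = character(), start = numeric(),
                               end = numeric())),
    genes, list(all = genes$gene_id)
  )
  expect_true(all(none$value == 0))

  sites <- tibble::tibble(chrom = "chr1", start = c(900, 4500), end = c(1000, 4700))
  res <- promoter_binding_frequency(list(batf = sites), genes,
                                    list(grp = genes$gene_id))
  expect_equal(res$value[res$factor == "batf"], 0.5)  # 2 of 4 in-window

  enriched <- promoter_binding_frequency(
    list(batf = sites), genes,
    list(all = genes$gene_id, bound = c("g1", "g2"))
  )
  v <- enriched[enriched$factor == "batf", ]
  expect_gt(v$value[v$group == "bound"], v$value[v$group == "all"])
  expect_error(promoter_binding_frequency(list(batf = sites), genes,
                                          list(empty = character())), "empty")
})

test_that("expression stratification partitions by arithmetic on the means", {
  m <- cbind(a = c(5, 50, 500), b = c(5, 50, 500))
  rownames(m) <- c("lo", "mid", "hi")
  fx <- make_expr(m, conditions = c("x", "y"))
  one <- stratify_by_expression(rownames(m), fx$expr, c(0, Inf))
  expect_equal(unique(one$stratum), "[0,Inf)")
  multi <- stratify_by_expression(rownames(m), fx$expr, c(0, 10, 100, Inf))
  expect_equal(multi$stratum, c("[0,10)", "[10,100)", "[100,Inf)"))
  expect_warning(stratify_by_expression(c("lo", "ghost"), fx$expr, c(0, Inf)),
                 "missing")
  expect_error(stratify_by_expression("lo", fx$expr, c(10, 10)), "increasing")
})

test_that("nearest-gene assignment matches brute force and breaks ties low", {
  genes <- make_genes("chr1", c(1000, 3000), ids = c("low", "high"))
  pk <- make_peaks("chr1", 1975, 2025)  # midpoint 2000, equidistant
  out <- assign_nearest_gene(pk, genes)
  expect_equal(out$nearest_gene, "low")

  withr::local_seed(17)
  peaks <- random_intervals(300, max_pos = 1e5)
  genes2 <- make_genes(sample(c("chr1", "chr2", "chr3"), 40, replace = TRUE),
                       floor(runif(40, 0, 1e5)), ids = sprintf("g%02d", 1:40))
  got <- assign_nearest_gene(peaks, genes2)
  expect_equal(got$nearest_gene, bf_nearest_tss(peaks, genes2))
})

test_that("proximity enrichment reproduces the textbook 2x2 chi-squared", {
  # construct peaks/genes whose nearest-gene table is [[30,70],[10,90]]
  counts <- c(sig_sub = 30, non_sub = 70, sig_rest = 10, non_rest = 90)
  genes <- make_genes("chr1", seq(10000, by = 10000,
                                  length.out = sum(counts)),
                      ids = sprintf("g%03d", seq_len(sum(counts))))
  sig_genes <- genes$gene_id[c(1:30, 101:110)]
  pk <- make_peaks("chr1", genes$tss - 50, genes$tss + 50,
                   ids = sprintf("p%03d", seq_len(sum(counts))))
  subset_ids <- pk$peak_id[1:100]
  res <- proximity_enrichment(pk, subset_ids, genes, sig_genes)
  expect_equal(res$statistic, 12.5, tolerance = 1e-9)
  expect_equal(res$statistic, bf_chisq_2x2(attr(res, "table")),
               tolerance = 1e-9)
  expect_equal(res$df, 1)

  # identical proportions in both rows: independence
  sig2 <- genes$gene_id[c(1:30, 101:130)]
  ind <- proximity_enrichment(pk, subset_ids, genes, sig2)
  expect_equal(ind$statistic, 0, tolerance = 1e-12)
  expect_equal(ind$p_value, 1, tolerance = 1e-12)
})

test_that("proximity enrichment refuses tables with tiny expected counts", {
  genes <- make_genes("chr1", seq(10000, by = 10000, length.out = 10),
                      ids = paste0("g", 1:10))
  pk <- make_peaks("chr1", genes$tss - 50, genes$tss + 50,
                   ids = paste0("p", 1:10))
  expect_error(
    proximity_enrichment(pk, pk$peak_id[1], genes, genes$gene_id[1]),
    "exact test"
  )
})

test_that("digital and analog response classes follow the stated rules", {
  m <- rbind(
    dig = c(20, 200, 200, 200, 200),
    ana = c(20, 40, 60, 80, 120),
    oth = c(20, 30, 25, 40, 20)
  )
  fx <- make_expr(m, conditions = paste0("C", 1:5))
  out <- classify_digital_analog(fx$expr, fx$sample_info)
  expect_equal(out$label, c("digital", "analog", "other"))
  expect_equal(out$induction[1], 10)
  expect_equal(out$treated_cv[1], 0)
})

test_that("planted digital genes are recovered at the default thresholds", {
  # induction is planted above the classifier's 4-fold definition so the
  # planted class and the rule agree; noise then tests robustness
  sim <- simulate_expression(
    n_genes = 1000, noise_cv = 0.05, n_replicates = 3,
    effect_size_range = c(6, 10), seed = 19
  )
  out <- classify_digital_analog(sim$expr, sim$sample_info)
  dg <- sim$truth$class == "digital"
  expect_gte(mean(out$label[dg] == "digital"), 0.90)
  # null genes are never called digital
  expect_true(all(out$label[sim$truth$class == "null"] != "digital"))
})
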