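test_that("median ranks use the midpoint convention and drop missing", {
  rk <- data.frame(gene_id = "g1", method = "MS", dataset = "CR1%",
                   replicate = 1:3, rank = c(10, 30, 20))
  expect_equal(median_rank_table(rk)$median_rank, 20)
  rk2 <- rk[1:2, ]
  rk2$rank <- c(10, 20)
  expect_equal(median_rank_table(rk2)$median_rank, 15)
  rk3 <- rk
  rk3$rank[2] <- NA
  out <- median_rank_table(rk3)
  expect_equal(out$median_rank, 15)
  expect_equal(out$n_replicates, 2L)
})

test_that("method preference classification follows the rank-ratio band", {
  expect_equal(classify_method_preference(100, 200), "A_better")
  expect_equal(classify_method_preference(105, 100), "neither")
  expect_equal(classify_method_preference(1500, 1400), "undetectable")
  expect_equal(classify_method_preference(130, 100), "B_better")
  expect_error(classify_method_preference(0, 10), "must be")

  # mirror consistency away from the band boundaries
  set.seed(9)
  for (i in 1:200) {
    a <- runif(1, 1, 900)
    b <- runif(1, 1, 900)
    r <- a / b
    # the band endpoints are not reciprocal (0.9 != 1/1.1), so mirror
    # consistency is only claimed away from the boundary zones
    if ((r > 0.88 && r < 0.92) || (r > 1.08 && r < 1.14)) next
    ab <- classify_method_preference(a, b)
    ba <- classify_method_preference(b, a)
    if (ab == "A_better") expect_equal(ba, "B_better")
    if (ab == "B_better") expect_equal(ba, "A_better")
    if (ab == "neither" && a / b > 1 / 1.1 && a / b < 1 / 0.9)
      expect_equal(ba, "neither")
  }
})

test_that("gene characteristics report causal content and effect sizes", {
  # two genes; gene gA has 1 causal of 4 markers with known beta and maf
  n <- 200
  set.seed(10)
  geno <- cbind(
    m1 = rbinom(n, 2, 0.1), m2 = rbinom(n, 2, 0.3),
    m3 = rbinom(n, 2, 0.2), m4 = rbinom(n, 2, 0.4),
    m5 = rbinom(n, 2, 0.25)
  )
  storage.mode(geno) <- "integer"
  markers <- data.frame(marker_id = colnames(geno),
                        gene_id = c(rep("gA", 4), "gB"),
                        class = "nonsynonymous", stringsAsFactors = FALSE)
  st <- genotype_study(geno, markers)
  ds <- build_analysis_dataset(st, 0.01, include_rare = FALSE)
  truth <- data.frame(endpoint = "Q1", gene_id = "gA", marker_id = "m1",
                      beta = 0.5, stringsAsFactors = FALSE)

  ch <- gene_characteristics("gA", truth, ds, "Q1")
  expect_equal(ch$markers_per_gene, 4)
  expect_equal(ch$causal_marker_count, 1L)
  expect_equal(ch$causal_marker_pct, 25)
  f <- ds$markers$maf[ds$markers$marker_id == "m1"]
  expect_equal(ch$strongest_effect, 0.5 * sqrt(2 * f * (1 - f)))
  expect_true(is.na(ch$second_relative_effect_pct))

  # closed-form check at the stated parameters
  expect_equal(0.5 * sqrt(2 * 0.1 * 0.9), 0.2121, tolerance = 1e-3)

  # two causal markers: relative second effect in percent
  truth2 <- rbind(truth, data.frame(endpoint = "Q1", gene_id = "gA",
                                    marker_id = "m2", beta = 0.2))
  ch2 <- gene_characteristics("gA", truth2, ds, "Q1")
  e1 <- 0.5 * sqrt(2 * f * (1 - f))
  f2 <- ds$markers$maf[ds$markers$marker_id == "m2"]
  e2 <- 0.2 * sqrt(2 * f2 * (1 - f2))
  expect_equal(ch2$second_relative_effect_pct,
               100 * min(e1, e2) / max(e1, e2))

  # no causal markers: zero counts, missing effect fields
  ch0 <- gene_characteristics("gB", truth, ds, "Q1")
  expect_equal(ch0$causal_marker_count, 0L)
  expect_true(is.na(ch0$strongest_effect))
})

test_that("supermarker characteristics use the collapsed column SD", {
  fx <- sim_fixture(seed = 35, n = 400, genes = 30)
  ds <- build_analysis_dataset(fx$study, 0.05, include_rare = TRUE,
                               min_mac = 1)
  sm_genes <- unique(ds$markers$gene_id[ds$markers$class == "supermarker"])
  causal_q1 <- unique(fx$truth$gene_id[fx$truth$endpoint == "Q1"])
  gn <- intersect(sm_genes, causal_q1)[1]
  if (!is.na(gn)) {
    ch <- gene_characteristics(gn, fx$truth, ds, "Q1")
    expect_gte(ch$causal_marker_count, 0L)
    expect_true(is.finite(ch$markers_per_gene))
  }
})

test_that("group comparison reproduces exact Mann-Whitney p-values", {
  chars <- data.frame(markers_per_gene = c(1, 2, 3, 10, 11, 12),
                      causal_marker_count = 1,
                      causal_marker_pct = 50,
                      strongest_effect = 0.1, strongest_freq = 0.1,
                      second_relative_effect_pct = NA_real_)
  labels <- rep(c("A_better", "B_better"), each = 3)
  out <- compare_groups(chars, labels)
  row <- out[out$characteristic == "markers_per_gene", ]
  expect_equal(row$p, wilcox.test(c(1, 2, 3), c(10, 11, 12))$p.value)
  expect_equal(row$p, 0.1)  # exact enumeration: 2 / choose(6, 3)
  expect_equal(row$mean_a, 2)
  expect_equal(row$mean_b, 11)

  # identical groups: rank test p = 1
  chars2 <- chars
  chars2$markers_per_gene <- rep(c(1, 2, 3), 2)
  out2 <- compare_groups(chars2, labels)
  expect_equal(out2$p[out2$characteristic == "markers_per_gene"], 1)

  # singleton group: mean reported, SD and p missing
  labels3 <- c("A_better", rep("B_better", 5))
  out3 <- compare_groups(chars, labels3)
  row3 <- out3[out3$characteristic == "markers_per_gene", ]
  expect_equal(row3$mean_a, 1)
  expect_true(is.na(row3$sd_a))
  expect_true(is.na(row3$p))
})
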