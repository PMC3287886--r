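test_that("marginal OLS matches the closed-form four-point fit", {
  fit <- fit_marginal(c(0, 1, 1, 2), endpoint_model("y", family = "linear"),
                      data.frame(y = c(1, 2, 3, 4)))
  expect_equal(fit$beta, 1.5)
  expect_equal(fit$se, sqrt(0.25 / 2))
  expect_equal(fit$t, 1.5 / sqrt(0.25 / 2))  # 4.2426
  expect_false(fit$flagged)
})

test_that("degenerate markers are flagged, not fatal", {
  d <- data.frame(y = rnorm(20))
  fit <- fit_marginal(rep(1, 20), endpoint_model("y", family = "linear"), d)
  expect_true(fit$flagged)
  expect_true(is.na(fit$t))
})

test_that("marginal fits agree with lm/glm including covariates", {
  set.seed(5)
  n <- 200
  d <- data.frame(Q1 = rnorm(n), Q2 = rnorm(n),
                  age = sample(20:70, n, TRUE), sex = rbinom(n, 1, 0.5),
                  smoking = rbinom(n, 1, 0.3))
  d$AFF <- rbinom(n, 1, plogis(-0.5 + 0.3 * d$Q1))
  d$Q4 <- rnorm(n)
  g <- generank:::sim_hwe_genotypes(n, c(0.1, 0.25, 0.4))

  lin <- fit_marginals(g, endpoint_model("Q1"), d)
  for (j in 1:3) {
    ref <- summary(lm(Q1 ~ Q2 + age + sex + smoking + g[, j], d))
    expect_equal(lin$beta[j], unname(ref$coefficients[6, 1]))
    expect_equal(lin$t[j], unname(ref$coefficients[6, 3]))
    expect_equal(lin$p[j], unname(ref$coefficients[6, 4]))
  }

  logi <- fit_marginals(g, endpoint_model("AFF"), d)
  for (j in 1:3) {
    ref <- summary(glm(AFF ~ Q1 + Q2 + Q4 + age + sex + smoking + g[, j],
                       binomial, d))
    expect_equal(logi$beta[j], unname(ref$coefficients[8, 1]),
                 tolerance = 1e-5)
    expect_equal(logi$t[j], unname(ref$coefficients[8, 3]),
                 tolerance = 1e-4)
  }

  # covariate-free fast logistic path equals per-marker glm
  fast <- fast_logistic_marginals(g, d$AFF)
  for (j in 1:3) {
    ref <- summary(glm(d$AFF ~ g[, j], binomial))
    expect_equal(fast$beta[j], unname(ref$coefficients[2, 1]),
                 tolerance = 1e-6)
    expect_equal(fast$t[j], unname(ref$coefficients[2, 3]),
                 tolerance = 1e-5)
  }
})

test_that("null marginal statistics are calibrated", {
  set.seed(6)
  n <- 1000
  g <- generank:::sim_hwe_genotypes(n, runif(2000, 0.05, 0.5))
  d <- data.frame(y = rnorm(n))
  marg <- fit_marginals(g, endpoint_model("y", family = "linear"), d)
  expect_lt(abs(mean(abs(marg$t) > 1.96) - 0.05), 0.015)
})

test_that("maximum statistic takes max |t| with first-marker tie break", {
  m <- data.frame(t = c(1.2, -2.5, 0.3), flagged = FALSE)
  expect_equal(score_max(m)$score, 2.5)
  expect_equal(score_max(m)$argmax, 2L)
  m1 <- data.frame(t = -1.7, flagged = FALSE)
  expect_equal(score_max(m1)$score, 1.7)
  mt <- data.frame(t = c(2, -2), flagged = FALSE)
  expect_equal(score_max(mt)$score, 2)
  expect_equal(score_max(mt)$argmax, 1L)
  expect_equal(score_max(mt, signed = TRUE)$score, 2)
  mall <- data.frame(t = c(NA, NA), flagged = TRUE)
  expect_true(is.na(score_max(mall)$score))
})

test_that("Hotelling T2 matches closed forms and handles singular genes", {
  # single marker: T2 = t^2
  g1 <- matrix(c(0, 1, 2, 1, 0, 1), ncol = 1)
  expect_equal(score_hotelling(data.frame(t = 3, flagged = FALSE), g1)$score,
               9)

  # 2 x 2 closed form at genotype correlation r
  set.seed(8)
  n <- 4000
  z <- rbinom(n, 2, 0.5)
  g2 <- cbind(z, z)
  g2[sample(n, n / 2), 2] <- rbinom(n / 2, 2, 0.5)
  r <- cor(g2)[1, 2]
  ht <- score_hotelling(data.frame(t = c(2, 2), flagged = FALSE), g2)
  expect_equal(ht$score, (4 + 4 - 2 * r * 4) / (1 - r^2), tolerance = 1e-10)
  expect_equal(ht$df, 2L)

  # duplicated column: pseudo-inverse reduces to the deduplicated score
  gd <- cbind(g2[, 1], g2[, 1])
  htd <- score_hotelling(data.frame(t = c(2, 2), flagged = FALSE), gd)
  expect_equal(htd$score, 4, tolerance = 1e-8)
  expect_equal(htd$df, 1L)

  # pseudo-inverse equals plain inverse on nonsingular correlation matrices
  for (k in 2:5) {
    gg <- generank:::sim_hwe_genotypes(500, runif(k, 0.2, 0.5))
    tv <- rnorm(k)
    ht <- score_hotelling(data.frame(t = tv, flagged = FALSE), gg)
    rr <- cor(gg)
    expect_equal(ht$score, as.numeric(tv %*% solve(rr) %*% tv),
                 tolerance = 1e-8)
  }
})

test_that("multivariate LRT equals the glm/lm deviance difference", {
  fx <- sim_fixture(seed = 31, n = 250, genes = 20)
  ds <- build_analysis_dataset(fx$study, 0.05, include_rare = TRUE)
  idx <- ds$gene_index[[which.max(lengths(ds$gene_index))]]
  g <- ds$geno[, idx, drop = FALSE]

  mv <- score_multivariate(g, endpoint_model("Q1"), fx$pheno)
  full <- lm(fx$pheno$Q1 ~ fx$pheno$Q2 + fx$pheno$age + fx$pheno$sex +
               fx$pheno$smoking + g)
  null <- lm(fx$pheno$Q1 ~ fx$pheno$Q2 + fx$pheno$age + fx$pheno$sex +
               fx$pheno$smoking)
  n <- nrow(fx$pheno)
  expect_equal(mv$score, n * log(sum(resid(null)^2) / sum(resid(full)^2)),
               tolerance = 1e-10)

  mva <- score_multivariate(g, endpoint_model("AFF"), fx$pheno)
  fulla <- glm(fx$pheno$AFF ~ fx$pheno$Q1 + fx$pheno$Q2 + fx$pheno$Q4 +
                 fx$pheno$age + fx$pheno$sex + fx$pheno$smoking + g,
               family = binomial)
  nulla <- update(fulla, . ~ . - g)
  expect_equal(mva$score, deviance(nulla) - deviance(fulla),
               tolerance = 1e-6)

  # zero-variance gene scores exactly 0 with df 0
  g0 <- matrix(0, nrow(fx$pheno), 2)
  mv0 <- score_multivariate(g0, endpoint_model("Q1"), fx$pheno)
  expect_equal(mv0$score, 0)
  expect_equal(mv0$df, 0L)

  # duplicated column is pruned, not fatal
  gdup <- cbind(g[, 1], g[, 1])
  mvd <- score_multivariate(gdup, endpoint_model("Q1"), fx$pheno)
  expect_equal(mvd$df, 1L)
})

test_that("LASSO score limits bracket the multivariate LRT", {
  fx <- sim_fixture(seed = 32, n = 250, genes = 20)
  ds <- build_analysis_dataset(fx$study, 0.05, include_rare = TRUE)
  idx <- ds$gene_index[[which.max(lengths(ds$gene_index))]]
  g <- ds$geno[, idx, drop = FALSE]

  for (ep in c("Q1", "AFF")) {
    em <- endpoint_model(ep)
    mv <- score_multivariate(g, em, fx$pheno)
    la0 <- score_lasso(g, em, fx$pheno, lambda_override = 0)
    expect_lt(abs(la0$score - mv$score) / mv$score, 1e-6)
    laI <- score_lasso(g, em, fx$pheno, lambda_override = Inf)
    expect_equal(laI$score, 0)
    # covariates unpenalised: at full shrinkage they sit at the null fit
    big <- score_lasso(g, em, fx$pheno, lambda_override = 1e6)
    nullfit <- if (ep == "Q1")
      coef(lm(Q1 ~ Q2 + age + sex + smoking, fx$pheno))
    else
      coef(glm(AFF ~ Q1 + Q2 + Q4 + age + sex + smoking, binomial, fx$pheno))
    got <- big$coefficients[seq_along(nullfit)]
    expect_equal(unname(got), unname(nullfit), tolerance = 1e-6)
  }

  # CV-selected score never exceeds the unpenalised LRT
  em <- endpoint_model("Q1")
  mv_all <- score_all_genes(ds, em, fx$pheno, "MV")
  la_all <- score_all_genes(ds, em, fx$pheno, "LA", seed = 99)
  expect_true(all(la_all$score <= mv_all$score + 1e-8))
})

test_that("gene scan is complete, stable and dataset-aware", {
  fx <- sim_fixture(seed = 33, n = 300, genes = 50)
  dss <- build_all_datasets(fx$study)
  ds <- dss[["CR5%"]]
  em <- endpoint_model("Q1")

  ms <- score_all_genes(ds, em, fx$pheno, "MS")
  expect_equal(nrow(ms), length(ds$gene_index))
  expect_false(any(is.na(ms$score)))

  la1 <- score_all_genes(ds, em, fx$pheno, "LA", seed = 7)
  la2 <- score_all_genes(ds, em, fx$pheno, "LA", seed = 7)
  expect_identical(la1, la2)

  # genes represented only by a supermarker are scored in CR, absent in C
  sm_only <- setdiff(names(dss[["CR5%"]]$gene_index),
                     names(dss[["C5%"]]$gene_index))
  if (length(sm_only)) {
    expect_true(all(sm_only %in% ms$gene_id))
    msc <- score_all_genes(dss[["C5%"]], em, fx$pheno, "MS")
    expect_false(any(sm_only %in% msc$gene_id))
  }
  expect_error(score_all_genes(ds, em, fx$pheno, "XX"))
})

test_that("single-marker genes rank identically under MS, HT and MV", {
  cfg <- exome_config(n_individuals = 400, n_genes = 60,
                      markers_per_gene = 1, rare_fraction = 0.3, seed = 44)
  sim <- simulate_exome(cfg)
  pheno <- simulate_phenotypes(sim$study, sim$truth, cfg)
  ds <- build_analysis_dataset(sim$study, 0.01, include_rare = FALSE)
  em <- endpoint_model("Q1")
  rks <- lapply(c("MS", "HT", "MV"), function(me)
    rank_genes(score_all_genes(ds, em, pheno, me))$rank)
  expect_equal(rks[[1]], rks[[2]])
  expect_equal(rks[[1]], rks[[3]])
})
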