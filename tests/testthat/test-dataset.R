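test_that("compute_maf counts minor alleles and flips when needed", {
  expect_equal(compute_maf(c(0, 1, 2, 0)), list(maf = 3 / 8, mac = 3))
  expect_equal(compute_maf(c(0, 0, 0)), list(maf = 0, mac = 0))
  # coded-allele frequency 7/8: minor allele is the reference
  expect_equal(compute_maf(c(2, 2, 2, 1)), list(maf = 1 / 8, mac = 1))
  expect_error(compute_maf(numeric(0)), "empty")
  expect_error(compute_maf(c(0, 3)), "0, 1, 2")
})

test_that("rare-variant collapsing is the carrier indicator", {
  geno <- cbind(a = c(0L, 1L, 0L), b = c(0L, 0L, 2L))
  mk <- data.frame(marker_id = c("a", "b"), gene_id = "g",
                   class = "nonsynonymous", maf = c(1 / 6, 2 / 6),
                   stringsAsFactors = FALSE)
  sm <- collapse_rare_variants(geno, mk, "g", 0.5)
  expect_equal(as.integer(sm), c(0L, 1L, 1L))
  expect_equal(attr(sm, "variants"), c("a", "b"))

  # single qualifying variant: indicator = min(genotype, 1)
  sm1 <- collapse_rare_variants(geno[, "a", drop = FALSE], mk[1, ], "g", 0.5)
  expect_equal(as.integer(sm1), pmin(geno[, "a"], 1L))

  # disjoint carriers: carrier count is the sum
  n <- 30
  gd <- sapply(1:10, function(j) {
    v <- integer(n); v[j] <- 1L; v
  })
  colnames(gd) <- paste0("v", 1:10)
  mkd <- data.frame(marker_id = colnames(gd), gene_id = "g",
                    class = "nonsynonymous", maf = 1 / (2 * n),
                    stringsAsFactors = FALSE)
  expect_equal(sum(collapse_rare_variants(gd, mkd, "g", 0.05)), 10)

  # no qualifying variant is a signal, not an error
  mk$class <- "synonymous"
  expect_null(collapse_rare_variants(geno, mk, "g", 0.5))
})

test_that("the four analysis datasets carry the CR/C labels and filters", {
  fx <- sim_fixture(seed = 21, n = 400, genes = 50)
  dss <- build_all_datasets(fx$study)
  expect_setequal(names(dss), c("CR1%", "CR5%", "C1%", "C5%"))
  for (ds in dss) {
    mm <- generank:::compute_maf_matrix(ds$geno)
    expect_true(all(mm$mac >= 5))
    nonsm <- ds$markers$class != "supermarker"
    expect_true(all(mm$maf[nonsm] > ds$cutoff))
    if (!ds$includes_rare)
      expect_false(any(ds$markers$class == "supermarker"))
    sm <- ds$geno[, ds$markers$class == "supermarker", drop = FALSE]
    expect_true(all(sm %in% 0:1))
  }
  # CR supset C nesting: common columns coincide
  for (pc in c("1%", "5%")) {
    cr <- dss[[paste0("CR", pc)]]
    cc <- dss[[paste0("C", pc)]]
    common_cr <- cr$markers$marker_id[cr$markers$class != "supermarker"]
    expect_identical(common_cr, cc$markers$marker_id)
    expect_identical(cr$geno[, common_cr], cc$geno)
  }
})

test_that("supermarker carrier frequency is bounded by its contributors", {
  fx <- sim_fixture(seed = 22, n = 500, genes = 40)
  ds <- build_analysis_dataset(fx$study, 0.05, include_rare = TRUE,
                               min_mac = 1)
  sms <- which(ds$markers$class == "supermarker")
  for (i in sms) {
    contrib <- strsplit(ds$markers$variants[i], ",")[[1]]
    cf_sm <- mean(ds$geno[, i] > 0)
    cf_each <- colMeans(fx$study$geno[, contrib, drop = FALSE] > 0)
    expect_gte(cf_sm, max(cf_each))
    expect_lte(cf_sm, sum(cf_each) + 1e-12)
  }
})

test_that("low-count markers are filtered and filtering is idempotent", {
  # one common variant with 4 minor alleles in 40 individuals: filtered out
  g <- matrix(0L, 40, 1, dimnames = list(NULL, "v1"))
  g[1:4, 1] <- 1L
  st <- genotype_study(g, data.frame(marker_id = "v1", gene_id = "g1",
                                     class = "nonsynonymous"))
  ds <- build_analysis_dataset(st, 0.01, include_rare = FALSE)
  expect_equal(ncol(ds$geno), 0)
  expect_length(ds$gene_index, 0)

  # gene with only rare variants is absent from common-only datasets
  fx <- sim_fixture(seed = 23, n = 300, genes = 30)
  only_rare <- tapply(generank:::compute_maf_matrix(fx$study$geno)$maf,
                      fx$study$markers$gene_id, max)
  rare_genes <- names(only_rare)[only_rare <= 0.05]
  ds_c <- build_analysis_dataset(fx$study, 0.05, include_rare = FALSE)
  expect_false(any(rare_genes %in% names(ds_c$gene_index)))

  ds_cr <- build_analysis_dataset(fx$study, 0.05, include_rare = TRUE)
  re <- refilter_dataset(ds_cr)
  expect_identical(re$geno, ds_cr$geno)
  expect_identical(re$markers, ds_cr$markers)

  expect_error(build_analysis_dataset(fx$study, 0.2, FALSE), "cutoff")
  expect_s3_class(build_analysis_dataset(fx$study, 0.2, FALSE,
                                         allow_any_cutoff = TRUE),
                  "analysis_dataset")
})

test_that("supermarker/common LD reports r-squared correctly", {
  set.seed(31)
  n <- 10000
  common <- rbinom(n, 2, 0.3)
  ind <- as.integer(rbinom(n, 1, 0.05))
  geno <- cbind(cv = as.integer(common), cv01 = as.integer(common > 0),
                sm = ind)
  ds <- list(
    geno = geno,
    markers = data.frame(marker_id = colnames(geno), gene_id = "g",
                         class = c("nonsynonymous", "nonsynonymous",
                                   "supermarker"),
                         stringsAsFactors = FALSE),
    gene_index = list(g = 1:3))

  # independent columns: near-zero r2
  expect_lt(ld_supermarker_vs_common(ds)$max_r2, 0.01)

  # supermarker identical to a 0/1 common column: r2 = 1, also when negated
  ds$geno[, "sm"] <- ds$geno[, "cv01"]
  expect_equal(ld_supermarker_vs_common(ds)$max_r2, 1)
  ds$geno[, "sm"] <- 1L - ds$geno[, "cv01"]
  expect_equal(ld_supermarker_vs_common(ds)$max_r2, 1)

  # zero-variance common column: r2 undefined -> missing
  ds$geno[, "cv"] <- 1L
  ds$geno[, "cv01"] <- 0L
  expect_true(is.na(ld_supermarker_vs_common(ds)$max_r2))
})

test_that("study TSV and VCF round-trips preserve genotypes", {
  fx <- sim_fixture(seed = 24, n = 30, genes = 5)
  pre <- file.path(tempdir(), "study_rt")
  write_study_tsv(fx$study, pre)
  st2 <- read_study_tsv(pre)
  expect_equal(unname(st2$geno), unname(fx$study$geno))
  expect_equal(st2$markers$gene_id, fx$study$markers$gene_id)

  vcf <- file.path(tempdir(), "study_rt.vcf")
  write_study_vcf(fx$study, vcf)
  ann <- fx$study$markers[c("marker_id", "gene_id", "class")]
  st3 <- read_study_vcf(vcf, ann)
  expect_equal(unname(st3$geno[, colnames(fx$study$geno)]),
               unname(fx$study$geno))
})
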