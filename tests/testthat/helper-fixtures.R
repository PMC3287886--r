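# Small deterministic fixtures shared across test files.

# Hand-built study: two genes, a mix of common and rare variants with known
# in-sample MAFs over 10 individuals.
toy_study <- function() {
  geno <- cbind(
    c1 = c(0L, 1L, 2L, 0L, 1L, 0L, 1L, 0L, 1L, 1L),  # maf 7/20, common
    c2 = c(2L, 2L, 2L, 1L, 2L, 2L, 2L, 2L, 2L, 2L),  # freq 19/20 -> flipped
    r1 = c(1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),  # maf 1/20 rare nonsyn
    r2 = c(0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),  # rare nonsyn
    s1 = c(0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L),  # rare synonymous
    d1 = c(0L, 1L, 1L, 0L, 1L, 1L, 0L, 1L, 0L, 1L)   # gene B common
  )
  markers <- data.frame(
    marker_id = colnames(geno),
    gene_id = c("gA", "gA", "gA", "gA", "gA", "gB"),
    class = c("synonymous", "nonsynonymous", "nonsynonymous",
              "nonsynonymous", "synonymous", "nonsynonymous"),
    stringsAsFactors = FALSE
  )
  genotype_study(geno, markers)
}

# Simulated study + phenotypes at a scale where every method runs fast.
sim_fixture <- function(seed = 11, n = 300, genes = 40) {
  k <- max(1L, genes %/% 10L)
  cfg <- exome_config(n_individuals = n, n_genes = genes, seed = seed,
                      n_causal_genes = list(Q1 = k, Q2 = k, AFF = k))
  sim <- simulate_exome(cfg)
  pheno <- simulate_phenotypes(sim$study, sim$truth, cfg)
  list(cfg = cfg, study = sim$study, truth = sim$truth, pheno = pheno)
}

# Balanced synthetic scenario-result table with known cell means plus
# replicate and noise effects.
balanced_results <- function(methods = c("MS", "HT", "MV", "LA"),
                             n_rep = 6, seed = 4, noise_sd = 0.3,
                             endpoint = "Q1", top_n = 100) {
  set.seed(seed)
  grid <- expand.grid(method = methods, cutoff = c(0.01, 0.05),
                      includes_rare = c(TRUE, FALSE),
                      replicate = seq_len(n_rep),
                      stringsAsFactors = FALSE)
  method_eff <- stats::setNames(seq_along(methods), methods)
  rep_eff <- stats::rnorm(n_rep, 0, 1)
  grid$endpoint <- endpoint
  grid$top_n <- top_n
  grid$count <- 5 + method_eff[grid$method] +
    2 * (grid$cutoff == 0.01) + 1.5 * grid$includes_rare +
    rep_eff[grid$replicate] + stats::rnorm(nrow(grid), 0, noise_sd)
  grid
}
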