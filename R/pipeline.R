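# simple FNV-1a string hash for config manifests (no external digest dep)
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 2166136261
  for (v in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), v)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Write a table as TSV with '#'-prefixed metadata lines
#'
#' @param x `data.frame`.
#' @param path Output path.
#' @param meta Named character vector written as `# key=value` lines.
#' @return Invisibly, `path`.
#' @export
write_tsv_meta <- function(x, path, meta = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta))
    writeLines(sprintf("# %s=%s", names(meta), meta), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the mini-exome replication study end to end
#'
#' By default mirrors the mini-exome design: one simulated exome with a
#' fixed truth table, and `n_replicates` phenotype replicates drawn on top
#' of it (replicate seeds derived from the master seed). Each replicate is
#' scored with every requested method and endpoint on the four analysis
#' datasets, ranked, and evaluated by top-N causal-gene counts. With
#' `resimulate_genotypes = TRUE` the exome and truth are re-simulated per
#' replicate instead. Writes `scenario_results.tsv`, `causal_ranks.tsv`,
#' `mean_counts.tsv` and a manifest to `out_dir` when given.
#'
#' @param cfg An [exome_config] (its `seed` is the master seed).
#' @param n_replicates Number of phenotype replicates.
#' @param methods Methods to run (subset of MS/HT/MV/LA).
#' @param endpoints Endpoints to analyse (subset of Q1/Q2/AFF).
#' @param top_n Gene-list cutoffs.
#' @param cv_folds Cross-validation folds for the LASSO score.
#' @param resimulate_genotypes Re-draw the exome and truth each replicate.
#' @param out_dir Optional output directory for TSV tables and the manifest.
#' @return List with `results` (long per-replicate top-N counts),
#'   `causal_ranks` (per-replicate ranks of causal genes), `mean_counts`,
#'   and `truth` (the fixed truth table, or `NULL` when re-simulating).
#' @export
run_replication_study <- function(cfg, n_replicates = 2,
                                  methods = c("MS", "HT", "MV", "LA"),
                                  endpoints = c("Q1", "Q2", "AFF"),
                                  top_n = c(10, 20, 50, 100, 200, 500),
                                  cv_folds = 10L,
                                  resimulate_genotypes = FALSE,
                                  out_dir = NULL) {
  results <- list()
  causal_ranks <- list()
  if (!resimulate_genotypes) {
    sim0 <- simulate_exome(cfg)
    datasets0 <- build_all_datasets(sim0$study)
  }
  for (rep_i in seq_len(n_replicates)) {
    rep_cfg <- cfg
    rep_cfg$seed <- derive_seed(cfg$seed, rep_i)
    if (resimulate_genotypes) {
      sim <- simulate_exome(rep_cfg)
      datasets <- build_all_datasets(sim$study)
    } else {
      sim <- sim0
      datasets <- datasets0
    }
    pheno <- simulate_phenotypes(sim$study, sim$truth, rep_cfg)
    for (ep in endpoints) {
      model <- endpoint_model(ep)
      causal <- unique(sim$truth$gene_id[sim$truth$endpoint == ep])
      for (ds in datasets) for (me in methods) {
        sc <- tryCatch(
          score_all_genes(ds, model, pheno, me,
                          seed = derive_seed(rep_cfg$seed, match(me, methods)),
                          cv_folds = cv_folds),
          error = function(e) NULL)
        if (is.null(sc)) next  # replicate cell failed; recorded as absent
        rk <- rank_genes(sc)
        cnt <- count_causal_topn(rk, causal, top_n)
        results[[length(results) + 1L]] <- data.frame(
          method = me, cutoff = ds$cutoff, includes_rare = ds$includes_rare,
          dataset = ds$label, endpoint = ep, replicate = rep_i,
          top_n = top_n, count = as.integer(cnt), stringsAsFactors = FALSE)
        hit <- rk[rk$gene_id %in% causal, , drop = FALSE]
        if (nrow(hit))
          causal_ranks[[length(causal_ranks) + 1L]] <- data.frame(
            gene_id = hit$gene_id, method = me, dataset = ds$label,
            endpoint = ep, replicate = rep_i, rank = hit$rank,
            stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, results)
  causal_ranks <- if (length(causal_ranks)) do.call(rbind, causal_ranks)
    else data.frame()
  means <- average_over_replicates(results)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    meta <- c(config_hash = config_hash(cfg), seed = cfg$seed,
              n_replicates = n_replicates,
              version = as.character(utils::packageVersion("generank")))
    write_tsv_meta(results, file.path(out_dir, "scenario_results.tsv"), meta)
    write_tsv_meta(causal_ranks, file.path(out_dir, "causal_ranks.tsv"), meta)
    write_tsv_meta(means, file.path(out_dir, "mean_counts.tsv"), meta)
    writeLines(yaml::as.yaml(list(config = unclass(cfg),
                                  n_replicates = n_replicates,
                                  methods = methods, endpoints = endpoints,
                                  top_n = top_n,
                                  config_hash = unname(meta["config_hash"]))),
               file.path(out_dir, "manifest.yaml"))
  }
  list(results = results, causal_ranks = causal_ranks, mean_counts = means,
       truth = if (resimulate_genotypes) NULL else sim0$truth)
}

# causal-gene rank per method for one simulated case-control replicate;
# MS and HT share one vectorised marginal pass
cc_replicate_ranks <- function(sc, methods = c("MS", "HT")) {
  sim <- simulate_case_control(sc)
  model <- endpoint_model("status", family = "logistic")
  data <- data.frame(status = sim$status)
  gene_index <- split(seq_len(ncol(sim$study$geno)),
                      sim$study$markers$gene_id)
  geno <- sim$study$geno
  storage.mode(geno) <- "double"  # one coercion shared by all downstream ops
  ds <- list(geno = geno, gene_index = gene_index)
  # covariate-free binary endpoint on 0/1/2 genotypes: take the fast
  # aggregated-Newton path directly (identical to fit_marginals here)
  marg <- fast_logistic_marginals(ds$geno, sim$status)
  tvec <- marg$t
  flg <- marg$flagged
  nind <- nrow(ds$geno)
  mu <- colMeans(ds$geno)
  genes <- names(gene_index)
  out <- numeric(0)
  for (me in methods) {
    scores <- vapply(genes, function(gn) {
      idx <- gene_index[[gn]]
      m <- list(t = tvec[idx], flagged = flg[idx])
      res <- switch(me,
        MS = score_max(m),
        HT = {
          xs <- ds$geno[, idx, drop = FALSE]
          # centred cross-product from raw columns: X'X - n mu mu'
          cp <- crossprod(xs) - nind * tcrossprod(mu[idx])
          score_hotelling(m, xs, cp = cp)
        },
        MV = score_multivariate(ds$geno[, idx, drop = FALSE], model, data),
        stop("unsupported crossover method: ", me))
      if (is.na(res$score)) NA_real_ else res$score
    }, numeric(1))
    rk <- rank_genes(data.frame(gene_id = genes, score = scores))
    out[me] <- rk$rank[rk$gene_id == "gene_causal"]
  }
  out
}

#' Default case-control crossover grid
#'
#' Representative sub-grid of the full scenario design used by the
#' desk-scale crossover study: markers per gene 2/3/5/7, causal allele
#' frequency 5% and 20%, odds ratio 1.3 and 1.7, and 1-3 causal markers
#' (never exceeding the gene's marker count).
#'
#' @param n_cases Cases (= controls) per replicate.
#' @return `data.frame` of grid cells.
#' @export
crossover_grid <- function(n_cases = 1000) {
  g <- expand.grid(markers_per_gene = c(2, 3, 5, 7),
                   n_causal_markers = c(1, 2, 3),
                   causal_maf = c(0.05, 0.20),
                   odds_ratio = c(1.3, 1.7),
                   n_cases = n_cases)
  g[g$n_causal_markers <= g$markers_per_gene, , drop = FALSE]
}

#' Case-control crossover experiment (median ranks per method per cell)
#'
#' Runs every grid cell for `n_replicates` simulated datasets, ranking the
#' causal gene among the null genes with each method, and summarises the
#' per-cell rank distribution: medians and the MS-vs-HT win indicator
#' (whether the MS median rank is at or below HT's).
#'
#' @param grid `data.frame` of scenario cells (see [crossover_grid]).
#' @param n_replicates Causal-gene replicates per cell.
#' @param n_null_genes Null genes per dataset.
#' @param methods Methods to compare (MS/HT/MV).
#' @param baseline_prevalence Penetrance at genotype 0.
#' @param seed Master seed.
#' @param out_dir Optional output directory.
#' @return `data.frame`: grid columns plus per-method `median_<method>`,
#'   plus `ms_beats_ht` and `ms_win_rate` (share of replicates where MS
#'   ranks the causal gene at least as well as HT).
#' @export
run_crossover_experiment <- function(grid = crossover_grid(),
                                     n_replicates = 100,
                                     n_null_genes = 200,
                                     methods = c("MS", "HT"),
                                     baseline_prevalence = 0.01,
                                     seed = 1L, out_dir = NULL) {
  rows <- vector("list", nrow(grid))
  for (ci in seq_len(nrow(grid))) {
    cell <- grid[ci, ]
    ranks <- matrix(NA_real_, n_replicates, length(methods),
                    dimnames = list(NULL, methods))
    for (r in seq_len(n_replicates)) {
      sc <- cc_scenario(
        n_null_genes = n_null_genes,
        markers_per_gene = cell$markers_per_gene,
        n_causal_markers = cell$n_causal_markers,
        causal_maf = cell$causal_maf,
        odds_ratio = cell$odds_ratio,
        n_cases = cell$n_cases,
        baseline_prevalence = baseline_prevalence,
        seed = derive_seed(seed, ci * 100000 + r))
      ranks[r, ] <- cc_replicate_ranks(sc, methods)
    }
    med <- apply(ranks, 2, stats::median, na.rm = TRUE)
    row <- cbind(cell,
                 as.data.frame(as.list(stats::setNames(
                   med, paste0("median_", methods)))))
    if (all(c("MS", "HT") %in% methods)) {
      row$ms_beats_ht <- med["MS"] <= med["HT"]
      row$ms_win_rate <- mean(ranks[, "MS"] <= ranks[, "HT"], na.rm = TRUE)
    }
    rows[[ci]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_meta(out, file.path(out_dir, "crossover_summary.tsv"),
                   c(seed = seed, n_replicates = n_replicates,
                     n_null_genes = n_null_genes))
  }
  out
}

#' Read / write a run configuration as YAML
#'
#' @param cfg An [exome_config] (for writing).
#' @param path File path.
#' @return `read_run_config` returns an [exome_config].
#' @export
write_run_config <- function(cfg, path) {
  writeLines(yaml::as.yaml(unclass(cfg)), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  do.call(exome_config, yaml::read_yaml(path))
}
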