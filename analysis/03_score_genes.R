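#!/usr/bin/env Rscript
# Score every gene of every analysis dataset with the four gene-wise
# methods (MS = maximum |t|, HT = Hotelling T2 on the marginal statistics,
# MV = multivariate LRT, LA = cross-validated LASSO deviance score) for
# the three endpoints, on the first simulation replicate.

library(generank)

study <- read_study_tsv("results/data/exome")
pheno <- read.table("results/data/phenotypes.tsv", header = TRUE,
                    sep = "\t", comment.char = "#")
out_dir <- "results/scores"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

all_scores <- list()
for (ds in build_all_datasets(study)) {
  for (ep in c("Q1", "Q2", "AFF")) {
    em <- endpoint_model(ep)
    for (me in c("MS", "HT", "MV", "LA")) {
      t0 <- Sys.time()
      sc <- score_all_genes(ds, em, pheno, me, seed = 1, cv_folds = 5)
      sc$dataset <- ds$label
      all_scores[[paste(ds$label, ep, me)]] <- sc
      cat(sprintf("%-5s %-3s %-2s: %3d genes, %d missing, %.1fs\n",
                  ds$label, ep, me, nrow(sc), sum(is.na(sc$score)),
                  as.numeric(Sys.time() - t0, units = "secs")))
    }
  }
}
scores <- do.call(rbind, all_scores)
write_tsv_meta(scores, file.path(out_dir, "gene_scores.tsv"),
               c(replicate = 1))
cat("wrote", nrow(scores), "gene scores\n")
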