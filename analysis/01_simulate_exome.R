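#!/usr/bin/env Rscript
# Simulate the mini-exome study the rest of the analysis consumes: a
# GAW17-like design (unrelated individuals, many genes, rare-variant-heavy
# MAF spectrum, causal nonsynonymous variants behind Q1/Q2/AFF plus age,
# sex and smoking covariates), written as TSV under results/data/.

library(generank)

out_dir <- "results/data"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- exome_config(
  n_individuals = 697,       # mini-exome cohort size
  n_genes = 400,             # desk-scale gene panel
  markers_per_gene = 1:15,
  rare_fraction = 0.75,
  nonsyn_fraction = 0.5,
  n_causal_genes = list(Q1 = 9, Q2 = 13, AFF = 15),
  prevalence = 0.3,
  seed = 20260922
)
write_run_config(cfg, file.path(out_dir, "exome_config.yaml"))

sim <- simulate_exome(cfg)
pheno <- simulate_phenotypes(sim$study, sim$truth, cfg)

print(sim$study)
cat(sprintf("causal genes: Q1=%d Q2=%d AFF=%d\n",
            length(unique(sim$truth$gene_id[sim$truth$endpoint == "Q1"])),
            length(unique(sim$truth$gene_id[sim$truth$endpoint == "Q2"])),
            length(unique(sim$truth$gene_id[sim$truth$endpoint == "AFF"]))))
cat(sprintf("observed prevalence: %.3f (target %.2f)\n",
            mean(pheno$AFF), cfg$prevalence))
maf <- generank:::compute_maf_matrix(sim$study$geno)$maf
cat(sprintf("rare variants (MAF <= 1%%): %.1f%%\n",
            100 * mean(maf <= 0.01)))

write_study_tsv(sim$study, file.path(out_dir, "exome"))
write_tsv_meta(sim$truth, file.path(out_dir, "truth.tsv"),
               c(seed = cfg$seed))
write_tsv_meta(pheno, file.path(out_dir, "phenotypes.tsv"),
               c(seed = cfg$seed))
write_study_vcf(sim$study, file.path(out_dir, "exome.vcf"))
cat("wrote", out_dir, "\n")
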