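#' Configuration for the synthetic mini-exome generator
#'
#' Describes a GAW17-like mini-exome: many genes, a marker-count distribution
#' per gene, a minor-allele-frequency (MAF) spectrum dominated by rare
#' variants, a minority of causal nonsynonymous variants acting on the
#' quantitative endpoints Q1 and Q2 and on the liability behind the binary
#' affection status AFF, plus the covariates age, sex and smoking.
#'
#' @param n_individuals Number of unrelated individuals.
#' @param n_genes Number of genes.
#' @param markers_per_gene Integer vector of possible marker counts per gene;
#'   each gene draws its count uniformly from this set. A single integer
#'   gives every gene that many markers.
#' @param rare_fraction Proportion of variants whose true MAF is drawn from
#'   `maf_rare_range` rather than `maf_common_range`.
#' @param maf_rare_range Length-2 interval within (0, 0.01] for rare MAFs.
#' @param maf_common_range Length-2 interval within (0.01, 0.5] for common
#'   MAFs. Must lie strictly above `maf_rare_range`.
#' @param nonsyn_fraction Proportion of variants annotated nonsynonymous.
#' @param n_causal_genes Named list or vector with elements `Q1`, `Q2`, `AFF`:
#'   number of causal genes per endpoint.
#' @param max_causal_per_gene Upper bound on the number of causal markers
#'   drawn per causal gene (at most the gene's nonsynonymous marker count).
#' @param causal_beta_range Length-2 interval of per-allele effect sizes
#'   (trait units per minor allele; liability units for AFF).
#' @param trait_noise_sd Residual standard deviation of Q1, Q2 and Q4.
#' @param prevalence Target proportion affected, in (0, 1).
#' @param smoking_prob Bernoulli probability of the smoking covariate.
#' @param seed Integer seed; the generator is bit-reproducible given the
#'   full configuration.
#'
#' @return An object of class `exome_config`.
#' @export
exome_config <- function(n_individuals = 697,
                         n_genes = 200,
                         markers_per_gene = 1:15,
                         rare_fraction = 0.75,
                         maf_rare_range = c(0.001, 0.01),
                         maf_common_range = c(0.01, 0.5),
                         nonsyn_fraction = 0.5,
                         n_causal_genes = list(Q1 = 9, Q2 = 13, AFF = 15),
                         max_causal_per_gene = 4,
                         causal_beta_range = c(0.3, 0.8),
                         trait_noise_sd = 1,
                         prevalence = 0.3,
                         smoking_prob = 0.3,
                         seed = 1L) {
  stopifnot(
    n_individuals >= 2, n_genes >= 1,
    is.numeric(markers_per_gene), all(markers_per_gene >= 1),
    rare_fraction >= 0, rare_fraction <= 1,
    nonsyn_fraction >= 0, nonsyn_fraction <= 1,
    prevalence > 0, prevalence < 1,
    smoking_prob >= 0, smoking_prob <= 1,
    trait_noise_sd > 0,
    length(maf_rare_range) == 2, length(maf_common_range) == 2,
    length(causal_beta_range) == 2
  )
  if (!(maf_rare_range[1] > 0 && maf_rare_range[2] <= 0.01))
    stop("maf_rare_range must lie within (0, 0.01]")
  if (!(maf_common_range[1] >= 0.01 && maf_common_range[2] <= 0.5))
    stop("maf_common_range must lie within [0.01, 0.5]")
  if (maf_rare_range[2] > maf_common_range[1])
    stop("MAF ranges must be disjoint and ordered (rare below common)")
  n_causal_genes <- as.list(n_causal_genes)
  for (ep in c("Q1", "Q2", "AFF")) {
    if (is.null(n_causal_genes[[ep]])) n_causal_genes[[ep]] <- 0L
    if (n_causal_genes[[ep]] > n_genes)
      stop("n_causal_genes[", ep, "] exceeds n_genes")
  }
  structure(
    list(
      n_individuals = as.integer(n_individuals),
      n_genes = as.integer(n_genes),
      markers_per_gene = as.integer(markers_per_gene),
      rare_fraction = rare_fraction,
      maf_rare_range = maf_rare_range,
      maf_common_range = maf_common_range,
      nonsyn_fraction = nonsyn_fraction,
      n_causal_genes = lapply(n_causal_genes, as.integer),
      max_causal_per_gene = as.integer(max_causal_per_gene),
      causal_beta_range = causal_beta_range,
      trait_noise_sd = trait_noise_sd,
      prevalence = prevalence,
      smoking_prob = smoking_prob,
      seed = as.integer(seed)
    ),
    class = "exome_config"
  )
}

#' Single-cell case-control power scenario
#'
#' One cell of the case-control scenario grid: a panel of null genes with a
#' fixed number of independent markers each (allele frequencies uniform),
#' plus one causal gene in which a subset of markers carries a per-allele
#' odds ratio on disease status. Cases and controls are sampled
#' retrospectively from a logistic penetrance model.
#'
#' @param n_null_genes Number of genes without genetic effect.
#' @param markers_per_gene Markers per gene (applies to the causal gene too);
#'   one of 2, 3, 5 or 7 in the reference grid.
#' @param n_causal_markers Number of causal markers in the causal gene
#'   (1, 2 or 3); must not exceed `markers_per_gene`.
#' @param causal_maf Allele frequency of each causal marker.
#' @param odds_ratio Per-allele odds ratio of each causal marker (> 1, or
#'   exactly 1 for a null control cell).
#' @param n_cases,n_controls Numbers of case and control subjects.
#' @param baseline_prevalence Penetrance at genotype 0, in (0, 1).
#' @param null_maf_range Interval from which null-marker minor-allele
#'   frequencies are drawn uniformly.
#' @param seed Integer seed.
#'
#' @return An object of class `cc_scenario`.
#' @export
cc_scenario <- function(n_null_genes = 2000,
                        markers_per_gene = 5,
                        n_causal_markers = 1,
                        causal_maf = 0.1,
                        odds_ratio = 1.5,
                        n_cases = 1000,
                        n_controls = n_cases,
                        baseline_prevalence = 0.01,
                        null_maf_range = c(0.01, 0.5),
                        seed = 1L) {
  stopifnot(
    n_null_genes >= 1, markers_per_gene >= 1,
    n_causal_markers >= 1,
    causal_maf > 0, causal_maf < 1,
    odds_ratio >= 1,
    n_cases >= 1, n_controls >= 1,
    baseline_prevalence > 0, baseline_prevalence < 1,
    length(null_maf_range) == 2, null_maf_range[1] > 0,
    null_maf_range[2] <= 0.5
  )
  if (n_causal_markers > markers_per_gene)
    stop("n_causal_markers must not exceed markers_per_gene")
  structure(
    list(
      n_null_genes = as.integer(n_null_genes),
      markers_per_gene = as.integer(markers_per_gene),
      n_causal_markers = as.integer(n_causal_markers),
      causal_maf = causal_maf,
      odds_ratio = odds_ratio,
      n_cases = as.integer(n_cases),
      n_controls = as.integer(n_controls),
      baseline_prevalence = baseline_prevalence,
      null_maf_range = null_maf_range,
      seed = as.integer(seed)
    ),
    class = "cc_scenario"
  )
}

#' Derive a reproducible child seed
#'
#' Linear-congruential mix of a master seed and a stream index, kept inside
#' the 32-bit signed-integer range so it is always a valid [set.seed] input.
#'
#' @param master Master seed (integer).
#' @param index Stream index (integer, e.g. replicate number).
#' @return A single non-negative integer below 2^31.
#' @export
derive_seed <- function(master, index) {
  m <- 2^31 - 1
  x <- (as.numeric(master) %% m) * 48271 %% m
  x <- (x + as.numeric(index) * 69621) %% m
  as.integer((x * 16807 + 12345) %% m)
}
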