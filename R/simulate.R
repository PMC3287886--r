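#' Simulate a GAW17-like mini-exome
#'
#' Draws per-marker minor-allele frequencies from a rare/common mixture,
#' genotypes under Hardy-Weinberg equilibrium, annotates markers as
#' nonsynonymous or synonymous, and assigns causal genes and per-variant
#' effect coefficients for each endpoint. Causal markers are always
#' nonsynonymous; effects are drawn from `cfg$causal_beta_range` and are
#' positive (deleterious), mirroring mini-exome practice.
#'
#' @param cfg An [exome_config].
#' @return A list with elements `study` (a [genotype_study], with true MAFs
#'   in `markers$maf`) and `truth` (data.frame `endpoint`, `gene_id`,
#'   `marker_id`, `beta`).
#' @export
simulate_exome <- function(cfg) {
  stopifnot(inherits(cfg, "exome_config"))
  set.seed(cfg$seed)
  n <- cfg$n_individuals
  m_per_gene <- if (length(cfg$markers_per_gene) == 1L)
    rep(cfg$markers_per_gene, cfg$n_genes)
  else
    sample(cfg$markers_per_gene, cfg$n_genes, replace = TRUE)
  m <- sum(m_per_gene)
  gene_id <- rep(sprintf("gene%04d", seq_len(cfg$n_genes)), m_per_gene)
  marker_id <- sprintf("snp%05d", seq_len(m))

  is_rare <- stats::runif(m) < cfg$rare_fraction
  maf <- ifelse(is_rare,
                stats::runif(m, cfg$maf_rare_range[1], cfg$maf_rare_range[2]),
                stats::runif(m, cfg$maf_common_range[1], cfg$maf_common_range[2]))
  cls <- ifelse(stats::runif(m) < cfg$nonsyn_fraction,
                "nonsynonymous", "synonymous")

  geno <- sim_hwe_genotypes(n, maf)
  colnames(geno) <- marker_id
  markers <- data.frame(marker_id = marker_id, gene_id = gene_id,
                        class = cls, maf = maf, stringsAsFactors = FALSE)
  study <- genotype_study(geno, markers)

  # causal assignment: per endpoint, genes with >=1 nonsynonymous marker
  eligible <- unique(gene_id[cls == "nonsynonymous"])
  truth <- list()
  for (ep in c("Q1", "Q2", "AFF")) {
    k <- cfg$n_causal_genes[[ep]]
    if (k == 0L) next
    if (k > length(eligible))
      stop("not enough genes with nonsynonymous markers for endpoint ", ep)
    genes <- sample(eligible, k)
    for (gn in genes) {
      idx <- which(gene_id == gn & cls == "nonsynonymous")
      n_causal <- sample(seq_len(min(length(idx), cfg$max_causal_per_gene)), 1)
      picked <- if (length(idx) == 1L) idx else sample(idx, n_causal)
      truth[[length(truth) + 1L]] <- data.frame(
        endpoint = ep, gene_id = gn, marker_id = marker_id[picked],
        beta = stats::runif(length(picked), cfg$causal_beta_range[1],
                            cfg$causal_beta_range[2]),
        stringsAsFactors = FALSE
      )
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(endpoint = character(), gene_id = character(),
               marker_id = character(), beta = numeric())
  list(study = study, truth = truth)
}

# genotypes under HWE: dosage ~ Binomial(2, maf), drawn column-wise
sim_hwe_genotypes <- function(n, maf) {
  m <- length(maf)
  g <- matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), nrow = n)
  storage.mode(g) <- "integer"
  g
}

#' Simulate phenotypes on top of a mini-exome
#'
#' Q1 and Q2 are additive linear traits (sum of beta * genotype over their
#' causal markers, plus covariate effects and Gaussian noise). Q4 is a
#' nuisance trait driven by covariates and noise only. AFF is produced by a
#' liability threshold on a latent score combining standardised Q1 and Q2,
#' the AFF causal markers and Gaussian noise; the threshold is the empirical
#' quantile matching the configured prevalence. Covariates: age uniform on
#' 20..70, sex Bernoulli(0.5), smoking Bernoulli(`cfg$smoking_prob`).
#'
#' @param study A [genotype_study].
#' @param truth Truth table as returned by [simulate_exome].
#' @param cfg The [exome_config] used for the study.
#' @return `data.frame` with columns Q1, Q2, Q4, AFF, age, sex, smoking.
#' @export
simulate_phenotypes <- function(study, truth, cfg) {
  stopifnot(inherits(study, "genotype_study"))
  if (nrow(truth) && !all(truth$marker_id %in% colnames(study$geno)))
    stop("truth references markers absent from the study")
  set.seed(cfg$seed + 1L)
  n <- nrow(study$geno)
  age <- sample(20:70, n, replace = TRUE)
  sex <- stats::rbinom(n, 1, 0.5)
  smoking <- stats::rbinom(n, 1, cfg$smoking_prob)

  genetic_part <- function(ep) {
    tt <- truth[truth$endpoint == ep, , drop = FALSE]
    if (!nrow(tt)) return(numeric(n))
    as.vector(study$geno[, tt$marker_id, drop = FALSE] %*% tt$beta)
  }
  sd0 <- cfg$trait_noise_sd
  q1 <- genetic_part("Q1") + 0.01 * age + 0.2 * sex + 0.3 * smoking +
    stats::rnorm(n, 0, sd0)
  q2 <- genetic_part("Q2") + 0.01 * age + 0.2 * sex + 0.1 * smoking +
    stats::rnorm(n, 0, sd0)
  q4 <- 0.015 * age + 0.25 * sex + stats::rnorm(n, 0, sd0)
  liab <- 0.5 * as.vector(scale(q1)) + 0.5 * as.vector(scale(q2)) +
    genetic_part("AFF") + stats::rnorm(n, 0, 1)
  thr <- stats::quantile(liab, 1 - cfg$prevalence, names = FALSE)
  data.frame(Q1 = q1, Q2 = q2, Q4 = q4, AFF = as.integer(liab > thr),
             age = age, sex = sex, smoking = smoking)
}

#' Genotype distribution given case/control status
#'
#' Exact Bayes enumeration over g in {0, 1, 2} under HWE allele frequency
#' `maf` and logistic penetrance
#' `logit P(D = 1 | g) = logit(p0) + g * log(or)`.
#'
#' @param maf Allele frequency of the risk allele.
#' @param or Per-allele odds ratio.
#' @param p0 Baseline prevalence (penetrance at g = 0).
#' @return List with probability vectors `case` and `control` over g = 0..2.
#' @export
genotype_given_status <- function(maf, or, p0) {
  g <- 0:2
  pg <- stats::dbinom(g, 2, maf)
  pen <- stats::plogis(stats::qlogis(p0) + g * log(or))
  case <- pg * pen
  ctrl <- pg * (1 - pen)
  list(case = case / sum(case), control = ctrl / sum(ctrl))
}

#' Simulate one case-control scenario
#'
#' Null-gene genotypes are independent of disease status (HWE draws at
#' uniform allele frequencies). The causal gene's causal markers are drawn
#' from the genotype-given-status distributions of [genotype_given_status]
#' (retrospective sampling), mutually independently given status; its
#' remaining markers are null. Cases come first in the returned matrix.
#'
#' @param sc A [cc_scenario].
#' @return List with `study` (a [genotype_study]; causal gene id
#'   `"gene_causal"`), `status` (integer vector, 1 = case) and `truth`
#'   (data.frame as in [simulate_exome], betas = log odds ratios).
#' @export
simulate_case_control <- function(sc) {
  stopifnot(inherits(sc, "cc_scenario"))
  set.seed(sc$seed)
  n <- sc$n_cases + sc$n_controls
  status <- rep(c(1L, 0L), c(sc$n_cases, sc$n_controls))

  m_null_total <- sc$n_null_genes * sc$markers_per_gene
  maf_null <- stats::runif(m_null_total, sc$null_maf_range[1],
                           sc$null_maf_range[2])
  g_null <- sim_hwe_genotypes(n, maf_null)

  # causal gene: causal markers drawn given status, rest null
  n_extra <- sc$markers_per_gene - sc$n_causal_markers
  dist <- genotype_given_status(sc$causal_maf, sc$odds_ratio,
                                sc$baseline_prevalence)
  g_causal <- matrix(0L, n, sc$n_causal_markers)
  for (j in seq_len(sc$n_causal_markers)) {
    g_causal[status == 1L, j] <- sample(0:2, sc$n_cases, replace = TRUE,
                                        prob = dist$case)
    g_causal[status == 0L, j] <- sample(0:2, sc$n_controls, replace = TRUE,
                                        prob = dist$control)
  }
  maf_extra <- if (n_extra > 0)
    stats::runif(n_extra, sc$null_maf_range[1], sc$null_maf_range[2])
  else numeric(0)
  g_extra <- if (n_extra > 0) sim_hwe_genotypes(n, maf_extra)
  else matrix(0L, n, 0)

  geno <- cbind(g_null, g_causal, g_extra)
  gene_id <- c(rep(sprintf("gene%04d", seq_len(sc$n_null_genes)),
                   each = sc$markers_per_gene),
               rep("gene_causal", sc$markers_per_gene))
  marker_id <- sprintf("m%05d", seq_len(ncol(geno)))
  colnames(geno) <- marker_id
  markers <- data.frame(marker_id = marker_id, gene_id = gene_id,
                        class = "nonsynonymous",
                        maf = c(maf_null,
                                rep(sc$causal_maf, sc$n_causal_markers),
                                maf_extra),
                        stringsAsFactors = FALSE)
  causal_ids <- marker_id[m_null_total + seq_len(sc$n_causal_markers)]
  truth <- data.frame(endpoint = "status", gene_id = "gene_causal",
                      marker_id = causal_ids,
                      beta = rep(log(sc$odds_ratio), sc$n_causal_markers),
                      stringsAsFactors = FALSE)
  list(study = genotype_study(geno, markers), status = status, truth = truth)
}
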