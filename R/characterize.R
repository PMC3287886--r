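#' Median causal-gene ranks per gene, method and dataset
#'
#' @param ranks Long `data.frame` with columns `gene_id`, `method`,
#'   `dataset`, `replicate`, `rank`; missing ranks are excluded from that
#'   gene's median.
#' @return `data.frame` with `gene_id`, `method`, `dataset`, `median_rank`,
#'   `n_replicates`.
#' @export
median_rank_table <- function(ranks) {
  ok <- !is.na(ranks$rank)
  d <- ranks[ok, , drop = FALSE]
  med <- stats::aggregate(rank ~ gene_id + method + dataset, data = d,
                          FUN = stats::median)
  names(med)[names(med) == "rank"] <- "median_rank"
  nrep <- stats::aggregate(rank ~ gene_id + method + dataset, data = d,
                           FUN = length)
  med$n_replicates <- nrep$rank
  med
}

#' Classify which method a gene prefers from its median ranks
#'
#' Ratio = `median_a / median_b` (smaller rank is better). Ratio below
#' `ratio_low` means method A detected the gene better; above `ratio_high`,
#' method B; in between, neither. A gene counts as undetectable unless at
#' least one method achieves a median rank at or below `detect_threshold`.
#'
#' @param median_a,median_b Median ranks under methods A and B (>= 1).
#' @param detect_threshold Detectability bound on the better median rank.
#' @param ratio_low,ratio_high Classification band.
#' @return One of `"A_better"`, `"B_better"`, `"neither"`, `"undetectable"`.
#' @export
classify_method_preference <- function(median_a, median_b,
                                       detect_threshold = 1000,
                                       ratio_low = 0.9, ratio_high = 1.1) {
  if (!is.finite(median_a) || !is.finite(median_b) ||
      median_a < 1 || median_b < 1)
    stop("median ranks must be finite and >= 1")
  if (min(median_a, median_b) > detect_threshold) return("undetectable")
  ratio <- median_a / median_b
  if (ratio < ratio_low) "A_better"
  else if (ratio > ratio_high) "B_better"
  else "neither"
}

#' Characteristics of a gene's causal content in an analysis dataset
#'
#' Tabulates, for one gene of an analysis dataset, the marker count, the
#' number and percentage of causal markers (a supermarker is causal when it
#' collapses at least one causal variant), and the frequency-adjusted
#' effect sizes `|beta| * sd(genotype)`: for additive markers
#' `sqrt(2 f (1 - f))` under HWE with the marker's in-sample MAF, for
#' supermarkers the empirical SD of the 0/1 column. The supermarker beta is
#' the mean beta of its causal contributing variants.
#'
#' @param gene Gene id.
#' @param truth Truth table (`endpoint`, `gene_id`, `marker_id`, `beta`).
#' @param ds An `analysis_dataset` containing the gene.
#' @param endpoint Endpoint whose truth rows apply.
#' @return One-row `data.frame` with `gene_id`, `markers_per_gene`,
#'   `causal_marker_count`, `causal_marker_pct`, `strongest_effect`,
#'   `strongest_freq`, `second_relative_effect_pct`.
#' @export
gene_characteristics <- function(gene, truth, ds, endpoint) {
  idx <- ds$gene_index[[gene]]
  if (is.null(idx)) stop("gene '", gene, "' not in dataset")
  mk <- ds$markers[idx, , drop = FALSE]
  tt <- truth[truth$endpoint == endpoint & truth$gene_id == gene, ,
              drop = FALSE]

  eff <- freq <- rep(NA_real_, nrow(mk))
  causal <- logical(nrow(mk))
  for (i in seq_len(nrow(mk))) {
    if (mk$class[i] == "supermarker") {
      contrib <- strsplit(mk$variants[i], ",")[[1]]
      bb <- tt$beta[tt$marker_id %in% contrib]
      if (length(bb)) {
        causal[i] <- TRUE
        eff[i] <- abs(mean(bb)) * stats::sd(ds$geno[, idx[i]])
        freq[i] <- mk$maf[i]
      }
    } else {
      b <- tt$beta[tt$marker_id == mk$marker_id[i]]
      if (length(b)) {
        causal[i] <- TRUE
        f <- mk$maf[i]
        eff[i] <- abs(b[1]) * sqrt(2 * f * (1 - f))
        freq[i] <- f
      }
    }
  }
  nc <- sum(causal)
  if (nc == 0) {
    return(data.frame(gene_id = gene, markers_per_gene = nrow(mk),
                      causal_marker_count = 0L, causal_marker_pct = 0,
                      strongest_effect = NA_real_, strongest_freq = NA_real_,
                      second_relative_effect_pct = NA_real_,
                      stringsAsFactors = FALSE))
  }
  ord <- order(eff, decreasing = TRUE, na.last = TRUE)
  strongest <- ord[1]
  second_rel <- if (nc >= 2) 100 * eff[ord[2]] / eff[strongest] else NA_real_
  data.frame(gene_id = gene, markers_per_gene = nrow(mk),
             causal_marker_count = as.integer(nc),
             causal_marker_pct = 100 * nc / nrow(mk),
             strongest_effect = eff[strongest],
             strongest_freq = freq[strongest],
             second_relative_effect_pct = second_rel,
             stringsAsFactors = FALSE)
}

#' Compare gene characteristics between method-preference groups
#'
#' For each characteristic, reports group means (SD; `NA` for singleton
#' groups) and a two-sided Mann-Whitney (Wilcoxon rank-sum) p-value, exact
#' for small untied samples. Groups of fewer than 2 genes get the summary
#' but no p-value.
#'
#' @param chars `data.frame` of [gene_characteristics] rows.
#' @param labels Preference label per row (e.g. from
#'   [classify_method_preference]).
#' @param group_a,group_b The two labels to compare.
#' @param characteristics Columns to compare, in output order.
#' @return `data.frame`: `characteristic`, `mean_a`, `sd_a`, `n_a`,
#'   `mean_b`, `sd_b`, `n_b`, `p`.
#' @export
compare_groups <- function(chars, labels,
                           group_a = "A_better", group_b = "B_better",
                           characteristics = c(
                             "markers_per_gene", "causal_marker_count",
                             "causal_marker_pct", "strongest_effect",
                             "strongest_freq",
                             "second_relative_effect_pct")) {
  a <- chars[labels == group_a, , drop = FALSE]
  b <- chars[labels == group_b, , drop = FALSE]
  rows <- lapply(characteristics, function(ch) {
    xa <- a[[ch]][!is.na(a[[ch]])]
    xb <- b[[ch]][!is.na(b[[ch]])]
    p <- if (length(xa) >= 2 && length(xb) >= 2)
      suppressWarnings(stats::wilcox.test(xa, xb)$p.value)
    else NA_real_
    data.frame(characteristic = ch,
               mean_a = if (length(xa)) mean(xa) else NA_real_,
               sd_a = if (length(xa) >= 2) stats::sd(xa) else NA_real_,
               n_a = length(xa),
               mean_b = if (length(xb)) mean(xb) else NA_real_,
               sd_b = if (length(xb) >= 2) stats::sd(xb) else NA_real_,
               n_b = length(xb),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
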