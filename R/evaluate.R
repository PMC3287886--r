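#' Rank genes by score
#'
#' Rank 1 is the largest score; ties receive the average rank; missing
#' scores are ranked last (sharing the average of the tail positions) and
#' flagged.
#'
#' @param scores `data.frame` with columns `gene_id` and `score` (e.g. from
#'   [score_all_genes]).
#' @return `data.frame` with `gene_id`, `score`, `rank`, `missing`.
#' @export
rank_genes <- function(scores) {
  s <- scores$score
  if (all(is.na(s))) stop("all gene scores are missing")
  g <- length(s)
  rk <- rep(NA_real_, g)
  ok <- !is.na(s)
  rk[ok] <- rank(-s[ok], ties.method = "average")
  n_ok <- sum(ok)
  if (n_ok < g) rk[!ok] <- mean(seq(n_ok + 1, g))
  data.frame(gene_id = scores$gene_id, score = s, rank = rk,
             missing = !ok, stringsAsFactors = FALSE)
}

#' Count causal genes among the N best-ranked genes
#'
#' A causal gene is counted at cutoff N when its rank value is below
#' N + 0.5 (so an average-rank tie straddling N counts only if it lands
#' under the cutoff).
#'
#' @param ranked Output of [rank_genes].
#' @param causal_genes Character vector of causal gene ids for the endpoint.
#' @param cutoffs Integer vector of list sizes.
#' @return Named integer vector of counts, one per cutoff.
#' @export
count_causal_topn <- function(ranked, causal_genes,
                              cutoffs = c(10, 20, 50, 100, 200, 500)) {
  if (!length(causal_genes)) {
    warning("empty causal gene set; all counts are 0")
    return(stats::setNames(integer(length(cutoffs)), cutoffs))
  }
  rk <- ranked$rank[ranked$gene_id %in% causal_genes]
  stats::setNames(vapply(cutoffs, function(n) sum(rk < n + 0.5), integer(1)),
                  cutoffs)
}

#' Average per-scenario causal counts over replicates
#'
#' @param results Long `data.frame` with columns `method`, `cutoff`,
#'   `includes_rare`, `endpoint`, `replicate`, `top_n`, `count`.
#' @return `data.frame` of means per (method, cutoff, includes_rare,
#'   endpoint, top_n) with the replicate count.
#' @export
average_over_replicates <- function(results) {
  agg <- stats::aggregate(
    count ~ method + cutoff + includes_rare + endpoint + top_n,
    data = results, FUN = mean)
  names(agg)[names(agg) == "count"] <- "mean_count"
  nrep <- stats::aggregate(
    count ~ method + cutoff + includes_rare + endpoint + top_n,
    data = results, FUN = length)
  agg$n_replicates <- nrep$count
  agg
}

#' Mixed-model comparison of analysis scenarios
#'
#' For each endpoint and top-N cutoff, fits a linear mixed model of the
#' causal-gene count on the fixed factors method, allele-frequency cutoff,
#' rare-variant use and the cutoff-by-use interaction, with a random
#' intercept per simulation replicate (REML). Emits the pairwise method
#' contrasts, the cutoff contrast (1% - 5%), the rare-use contrast
#' (common-only - with-rare) and the interaction
#' (difference-in-differences for the AF = 1%, common-only cell), each with
#' SE and a Wald normal p-value.
#'
#' @param results Long `data.frame` as in [average_over_replicates]; must be
#'   a complete balanced factorial over the present levels with >= 2
#'   replicates.
#' @return `data.frame`: `endpoint`, `top_n`, `term`, `estimate`, `se`, `p`.
#' @export
compare_scenarios_mixed_model <- function(results) {
  req <- c("method", "cutoff", "includes_rare", "endpoint", "replicate",
           "top_n", "count")
  if (!all(req %in% names(results)))
    stop("results must have columns: ", paste(req, collapse = ", "))
  if (length(unique(results$replicate)) < 2)
    stop("need >= 2 replicates")
  check_balance(results)

  out <- list()
  for (ep in unique(results$endpoint)) for (nn in unique(results$top_n)) {
    d <- results[results$endpoint == ep & results$top_n == nn, , drop = FALSE]
    canon <- c("MS", "HT", "MV", "LA")
    lev <- c(intersect(canon, unique(d$method)),
             setdiff(unique(d$method), canon))
    d$method <- factor(d$method, levels = lev)
    d$af <- factor(ifelse(d$cutoff == 0.01, "1%", "5%"), c("1%", "5%"))
    d$use <- factor(ifelse(d$includes_rare, "RV", "CV"), c("CV", "RV"))
    d$replicate <- factor(d$replicate)
    two_af <- nlevels(d$af) > 1
    two_use <- nlevels(d$use) > 1
    form <- stats::as.formula(paste(
      "count ~ method",
      if (two_af) "+ af" else "",
      if (two_use) "+ use" else "",
      if (two_af && two_use) "+ af:use" else "",
      "+ (1 | replicate)"))
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(form, data = d, REML = TRUE)))
    beta <- lme4::fixef(fit)
    # degenerate fits (zero variance everywhere) have no usable vcov
    vc <- tryCatch(as.matrix(stats::vcov(fit)),
                   error = function(e) matrix(0, length(beta), length(beta)))

    # model-implied cell means over the full factorial grid
    grid <- expand.grid(method = levels(d$method), af = levels(d$af),
                        use = levels(d$use))
    xg <- stats::model.matrix(stats::formula(fit, fixed.only = TRUE)[-2],
                              grid)
    xg <- xg[, names(beta), drop = FALSE]

    cell_contrast <- function(w) {
      cvec <- as.vector(crossprod(xg, w))
      est <- sum(cvec * beta)
      se <- sqrt(as.numeric(t(cvec) %*% vc %*% cvec))
      z <- est / se
      c(est, se, 2 * stats::pnorm(-abs(z)))
    }
    wt_for <- function(cond) {
      w <- as.numeric(cond)
      w / sum(w)
    }

    meths <- levels(d$method)
    rows <- list()
    if (length(meths) > 1) {
      for (i in seq_along(meths)) for (j in seq_along(meths)) {
        if (j <= i) next
        w <- wt_for(grid$method == meths[i]) - wt_for(grid$method == meths[j])
        rows[[paste0(meths[i], "_vs_", meths[j])]] <- cell_contrast(w)
      }
    }
    if (two_af)
      rows[["AF1_vs_AF5"]] <-
        cell_contrast(wt_for(grid$af == "1%") - wt_for(grid$af == "5%"))
    if (two_use)
      rows[["CV_vs_RV"]] <-
        cell_contrast(wt_for(grid$use == "CV") - wt_for(grid$use == "RV"))
    if (two_af && two_use) {
      w <- wt_for(grid$af == "1%" & grid$use == "CV") -
        wt_for(grid$af == "1%" & grid$use == "RV") -
        wt_for(grid$af == "5%" & grid$use == "CV") +
        wt_for(grid$af == "5%" & grid$use == "RV")
      rows[["IA_AF1_CV"]] <- cell_contrast(w)
    }
    est <- do.call(rbind, rows)
    out[[length(out) + 1L]] <- data.frame(
      endpoint = ep, top_n = nn, term = rownames(est),
      estimate = est[, 1], se = est[, 2], p = est[, 3],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# error when the (method, cutoff, use, replicate) factorial is incomplete
check_balance <- function(results) {
  cells <- with(results, table(method, cutoff, includes_rare, replicate,
                               endpoint, top_n))
  if (any(cells == 0)) {
    miss <- which(cells == 0, arr.ind = TRUE)
    lab <- apply(miss[seq_len(min(5, nrow(miss))), , drop = FALSE], 1,
                 function(i) paste(mapply(function(d, k) dimnames(cells)[[d]][k],
                                          seq_along(i), i), collapse = "/"))
    stop("unbalanced design; missing cells: ", paste(lab, collapse = "; "))
  }
  invisible(TRUE)
}

#' Permutation p-values for gene scores
#'
#' Permutes the phenotype table rows (endpoint and covariates jointly, so
#' phenotype-covariate structure is preserved while genotype links break)
#' B times, rescoring every gene against each permuted table with a single
#' shared permutation stream. Empirical p uses the add-one convention
#' `p = (1 + #\{permuted >= observed\}) / (B + 1)`.
#'
#' @param ds An `analysis_dataset`.
#' @param model An [endpoint_model].
#' @param data Phenotype/covariate `data.frame`.
#' @param method Scoring method (see [score_all_genes]).
#' @param B Number of permutations (>= 19).
#' @param seed Integer seed.
#' @return `data.frame`: `gene_id`, `score`, `perm_p`.
#' @export
permutation_pvalues <- function(ds, model, data, method = "MS", B = 99L,
                                seed = 1L) {
  if (B < 19) stop("B must be >= 19")
  obs <- score_all_genes(ds, model, data, method, seed = seed)
  cnt <- numeric(nrow(obs))
  # ties are counted with a small relative slack so exact ties are not
  # split by floating-point noise
  thr <- obs$score - 1e-8 * (1 + abs(obs$score))
  set.seed(seed)
  perms <- replicate(B, sample(nrow(data)), simplify = FALSE)
  for (b in seq_len(B)) {
    sc <- score_all_genes(ds, model, data[perms[[b]], , drop = FALSE],
                          method, seed = derive_seed(seed, b))
    cnt <- cnt + as.numeric(!is.na(sc$score) & !is.na(obs$score) &
                              sc$score >= thr)
  }
  data.frame(gene_id = obs$gene_id, score = obs$score,
             perm_p = (1 + cnt) / (B + 1), stringsAsFactors = FALSE)
}
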