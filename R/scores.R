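#' Moore-Penrose pseudo-inverse of a symmetric matrix
#'
#' Eigendecomposition-based; eigenvalues below `tol * max(abs(eigenvalue))`
#' are treated as zero.
#'
#' @param x Symmetric numeric matrix.
#' @param tol Relative tolerance for rank determination.
#' @return List with `inv` (pseudo-inverse) and `rank`.
#' @keywords internal
pinv_sym <- function(x, tol = 1e-10) {
  e <- eigen(x, symmetric = TRUE)
  keep <- abs(e$values) > tol * max(abs(e$values), tol)
  r <- sum(keep)
  if (r == 0)
    return(list(inv = matrix(0, nrow(x), ncol(x)), rank = 0L))
  v <- e$vectors[, keep, drop = FALSE]
  list(inv = v %*% (t(v) / e$values[keep]), rank = as.integer(r))
}

#' Maximum-statistic gene score
#'
#' Score = maximum of the absolute (default) or signed marginal Wald
#' statistics over the gene's markers, supermarker included. No adjustment
#' for the number of markers.
#'
#' @param marginals `data.frame` from [fit_marginals] for the gene's markers.
#' @param signed Use the signed maximum instead of max |t|.
#' @return List with `score`, `df` (`NA`), `p` (`NA`), `argmax` (index of
#'   the first maximising marker); `score` is `NA` when every marginal is
#'   flagged.
#' @export
score_max <- function(marginals, signed = FALSE) {
  t_ok <- marginals$t[!marginals$flagged]
  idx_ok <- which(!marginals$flagged)
  if (!length(t_ok)) return(list(score = NA_real_, df = NA_integer_,
                                 p = NA_real_, argmax = NA_integer_))
  val <- if (signed) t_ok else abs(t_ok)
  i <- which.max(val)  # ties: first by marker order
  list(score = val[i], df = NA_integer_, p = NA_real_, argmax = idx_ok[i])
}

#' Hotelling's T2 gene score from marginal statistics
#'
#' Quadratic form `t' R^- t`, where `t` stacks the usable marginal Wald
#' statistics and `R^-` is the Moore-Penrose pseudo-inverse of the pairwise
#' Pearson correlation matrix of the corresponding genotype columns.
#' Degrees of freedom = rank(R); p from the chi-square reference.
#'
#' @param marginals `data.frame` from [fit_marginals].
#' @param geno Genotype submatrix of the same markers (columns aligned with
#'   `marginals` rows).
#' @param cp Optional precomputed cross-product of the centered genotype
#'   columns (as from `crossprod(scale(geno, scale = FALSE))`); saves the
#'   centering when scoring many genes of one dataset.
#' @return List with `score`, `df`, `p`.
#' @export
score_hotelling <- function(marginals, geno, cp = NULL) {
  if (is.null(cp)) {
    n <- nrow(geno)
    gc <- geno - rep(colMeans(geno), each = n)
    cp <- crossprod(gc)
  }
  use <- !marginals$flagged & diag(cp) > 0
  if (!any(use)) return(list(score = NA_real_, df = NA_integer_,
                             p = NA_real_))
  tvec <- marginals$t[use]
  cpu <- cp[use, use, drop = FALSE]
  d <- sqrt(diag(cpu))
  r <- cpu / tcrossprod(d)  # pairwise Pearson correlation
  pi <- pinv_sym(r)
  score <- as.numeric(tvec %*% pi$inv %*% tvec)
  list(score = score, df = pi$rank,
       p = stats::pchisq(score, pi$rank, lower.tail = FALSE))
}

# drop, in marker order, genetic columns (nearly) collinear with the
# covariates and earlier genetic columns; returns retained column indices
prune_collinear <- function(geno, qrx, tol = 1e-10) {
  basis <- qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
  kept <- integer(0)
  for (j in seq_len(ncol(geno))) {
    g <- geno[, j]
    res <- g - basis %*% crossprod(basis, g)
    if (sum(res^2) <= tol * max(sum(g^2), 1)) next
    kept <- c(kept, j)
    q <- res / sqrt(sum(res^2))
    basis <- cbind(basis, q)
  }
  kept
}

#' Multivariate likelihood-ratio gene score
#'
#' Likelihood-ratio test of the joint model with all of the gene's markers
#' against the covariates-only null: `2 * (loglik_full - loglik_null)`
#' (for linear endpoints, `n * log(RSS_null / RSS_full)` under the normal
#' likelihood). Genetic columns collinear with the covariates or with
#' earlier markers are pruned deterministically in marker order; df is the
#' retained count.
#'
#' @param geno Genotype submatrix of the gene's markers.
#' @param model An [endpoint_model].
#' @param data Phenotype/covariate `data.frame`.
#' @return List with `score`, `df`, `p` (chi-square on `df`).
#' @export
score_multivariate <- function(geno, model, data) {
  mf <- model_frame(model, data)
  kept <- prune_collinear(geno, mf$qrx)
  if (!length(kept))
    return(list(score = 0, df = 0L, p = NA_real_))
  x_full <- cbind(mf$xc, geno[, kept, drop = FALSE])
  n <- length(mf$y)
  if (model$family == "linear") {
    rss0 <- sum(qr.resid(mf$qrx, mf$y)^2)
    rss1 <- sum(qr.resid(qr(x_full), mf$y)^2)
    score <- n * log(rss0 / rss1)
  } else {
    fit0 <- suppressWarnings(stats::glm.fit(mf$xc, mf$y,
                                            family = stats::binomial()))
    fit1 <- tryCatch(
      suppressWarnings(stats::glm.fit(x_full, mf$y,
                                      family = stats::binomial())),
      error = function(e) NULL)
    if (is.null(fit1) || !fit1$converged)
      return(list(score = NA_real_, df = NA_integer_, p = NA_real_))
    score <- fit0$deviance - fit1$deviance
  }
  score <- max(score, 0)
  df <- length(kept)
  list(score = score, df = as.integer(df),
       p = stats::pchisq(score, df, lower.tail = FALSE))
}

# deviance on the scale used by score_multivariate
model_deviance <- function(y, mu, family, n) {
  if (family == "linear") sum((y - mu)^2)
  else {
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
  }
}

#' L1-penalised (LASSO) gene score
#'
#' Fits the endpoint on covariates plus the gene's markers with an L1
#' penalty on the genetic coefficients only (covariates and intercept
#' unpenalised, via `glmnet` penalty factors). The penalty is chosen by
#' K-fold cross-validated deviance (`lambda.min`), with fold assignment
#' seeded. Score = deviance(null) - deviance(penalised fit), on the same
#' scale as [score_multivariate]; non-negative by construction (clamped at
#' numerical zero).
#'
#' @param geno Genotype submatrix of the gene's markers.
#' @param model An [endpoint_model].
#' @param data Phenotype/covariate `data.frame`.
#' @param cv_folds Number of cross-validation folds (>= 3).
#' @param seed Integer seed for the fold assignment.
#' @param lambda_override Optional fixed penalty: `0` gives the unpenalised
#'   fit, `Inf` the fully shrunk (null) genetic model.
#' @return List with `score`, `df` (nonzero genetic coefficients), `p`
#'   (`NA`; the score is a ranking statistic), `lambda`, and `coefficients`
#'   of the penalised fit (intercept, covariates, genetic columns).
#' @export
score_lasso <- function(geno, model, data, cv_folds = 10L, seed = 1L,
                        lambda_override = NULL) {
  if (is.null(lambda_override) && cv_folds < 3)
    stop("cv_folds must be >= 3")
  mf <- model_frame(model, data)
  n <- length(mf$y)
  kept <- which(apply(geno, 2, stats::var) > 0)
  if (!length(kept))
    return(list(score = 0, df = 0L, p = NA_real_, lambda = NA_real_))
  xg <- geno[, kept, drop = FALSE]
  xc <- mf$xc[, -1, drop = FALSE]  # glmnet supplies the intercept
  x <- cbind(xc, xg)
  pf <- c(rep(0, ncol(xc)), rep(1, ncol(xg)))
  fam <- if (model$family == "linear") "gaussian" else "binomial"
  if (ncol(x) < 2) {  # glmnet needs >= 2 columns; pad with an inert column
    x <- cbind(x, pad = 0)
    pf <- c(pf, 1)
  }

  dev0 <- model_deviance(mf$y, null_mu(mf, model), model$family, n)

  if (!is.null(lambda_override) && is.infinite(lambda_override)) {
    coefs_g <- rep(0, ncol(xg))
    cf <- c(null_coefficients(mf, model), coefs_g,
            if (ncol(x) > ncol(xc) + ncol(xg)) 0)
    dev <- dev0
    lam <- Inf
  } else if (!is.null(lambda_override)) {
    # a short decreasing path ending at the override avoids glmnet's
    # single-lambda warm-start inaccuracy
    fit <- glmnet::glmnet(x, mf$y, family = fam, penalty.factor = pf,
                          lambda = exp(seq(log(1 + lambda_override + 1e-3),
                                           log(lambda_override + 1e-12),
                                           length.out = 20)),
                          thresh = 1e-14, maxit = 1e7)
    mu <- stats::predict(fit, newx = x, s = min(fit$lambda),
                         type = "response")
    cf <- as.vector(stats::coef(fit, s = min(fit$lambda)))
    coefs_g <- cf[1 + ncol(xc) + seq_len(ncol(xg))]
    dev <- model_deviance(mf$y, as.vector(mu), model$family, n)
    lam <- lambda_override
  } else {
    set.seed(seed)
    foldid <- sample(rep_len(seq_len(cv_folds), n))
    cv <- glmnet::cv.glmnet(x, mf$y, family = fam, penalty.factor = pf,
                            foldid = foldid)
    lam <- cv$lambda.min
    mu <- stats::predict(cv$glmnet.fit, newx = x, s = lam,
                         type = "response")
    cf <- as.vector(stats::coef(cv$glmnet.fit, s = lam))
    coefs_g <- cf[1 + ncol(xc) + seq_len(ncol(xg))]
    dev <- model_deviance(mf$y, as.vector(mu), model$family, n)
  }
  score <- if (model$family == "linear") n * log(dev0 / dev) else dev0 - dev
  score <- max(score, 0)
  gnames <- if (is.null(colnames(xg))) paste0("g", seq_len(ncol(xg)))
            else colnames(xg)
  names(cf) <- c("(Intercept)", colnames(xc), gnames,
                 if (length(cf) > 1 + ncol(xc) + ncol(xg)) "pad")
  list(score = score, df = sum(abs(coefs_g) > 0), p = NA_real_,
       lambda = lam, coefficients = cf)
}

# fitted values of the covariates-only null model
null_mu <- function(mf, model) {
  if (model$family == "linear") qr.fitted(mf$qrx, mf$y)
  else suppressWarnings(
    stats::glm.fit(mf$xc, mf$y, family = stats::binomial()))$fitted.values
}

# coefficients (intercept + covariates) of the covariates-only null model
null_coefficients <- function(mf, model) {
  if (model$family == "linear") qr.coef(mf$qrx, mf$y)
  else suppressWarnings(
    stats::glm.fit(mf$xc, mf$y, family = stats::binomial()))$coefficients
}

#' Score every gene of an analysis dataset
#'
#' Computes one gene score per gene with the requested method. Marginal
#' statistics are fitted once for the whole dataset and reused across MS
#' and HT genes; per-gene failures are downgraded to missing scores.
#'
#' @param ds An `analysis_dataset` (or any list with `geno`, `gene_index`).
#' @param model An [endpoint_model].
#' @param data Phenotype/covariate `data.frame`.
#' @param method One of `"MS"`, `"HT"`, `"MV"`, `"LA"`.
#' @param seed Seed for the LASSO fold assignment (per-gene seeds derived).
#' @param cv_folds Cross-validation folds for `"LA"`.
#' @return `data.frame`: `gene_id`, `method`, `endpoint`, `score`, `df`,
#'   `p`, `n_markers`.
#' @export
score_all_genes <- function(ds, model, data, method = c("MS", "HT", "MV", "LA"),
                            seed = 1L, cv_folds = 10L) {
  method <- match.arg(method)
  genes <- names(ds$gene_index)
  marg <- if (method %in% c("MS", "HT"))
    fit_marginals(ds$geno, model, data) else NULL

  rows <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    idx <- ds$gene_index[[genes[i]]]
    res <- tryCatch({
      switch(method,
        MS = score_max(marg[idx, , drop = FALSE]),
        HT = score_hotelling(marg[idx, , drop = FALSE],
                             ds$geno[, idx, drop = FALSE]),
        MV = score_multivariate(ds$geno[, idx, drop = FALSE], model, data),
        LA = score_lasso(ds$geno[, idx, drop = FALSE], model, data,
                         cv_folds = cv_folds,
                         seed = derive_seed(seed, i)))
    }, error = function(e) list(score = NA_real_, df = NA_integer_,
                                p = NA_real_))
    rows[[i]] <- data.frame(gene_id = genes[i], method = method,
                            endpoint = model$endpoint,
                            score = res$score,
                            df = if (is.null(res$df)) NA_integer_ else res$df,
                            p = if (is.null(res$p)) NA_real_ else res$p,
                            n_markers = length(idx),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
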