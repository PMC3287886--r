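#' Marginal single-marker regression
#'
#' Fits the endpoint on one additive-coded marker plus the model's
#' covariates and intercept: ordinary least squares for linear endpoints,
#' maximum-likelihood logistic regression for binary ones. The reported
#' statistic is the Wald t (or z) of the genotype coefficient.
#'
#' @param g Genotype column.
#' @param model An [endpoint_model].
#' @param data Phenotype/covariate `data.frame`.
#' @return List with `beta`, `se`, `t`, `p`, `flagged` (TRUE when the fit is
#'   unusable: constant marker, collinearity, separation/non-convergence).
#' @export
fit_marginal <- function(g, model, data) {
  res <- fit_marginals(matrix(g, ncol = 1), model, data)
  as.list(res[1, c("beta", "se", "t", "p", "flagged")])
}

#' Marginal regressions for a set of markers
#'
#' Vectorised marginal fits sharing one covariate projection. Linear
#' endpoints use the Frisch-Waugh-Lovell residualisation, which reproduces
#' per-marker OLS exactly; covariate-free logistic endpoints use an
#' aggregated-count Newton solver ([fast_logistic_marginals]); logistic
#' endpoints with covariates fall back to one `glm` per marker.
#' Constant or covariate-collinear markers and non-converged or separated
#' logistic fits come back flagged with `NA` statistics.
#'
#' @param geno Genotype matrix (individuals x markers).
#' @param model An [endpoint_model].
#' @param data Phenotype/covariate `data.frame`.
#' @return `data.frame` with one row per marker: `beta`, `se`, `t`, `p`,
#'   `flagged`.
#' @export
fit_marginals <- function(geno, model, data) {
  mf <- model_frame(model, data)
  n <- length(mf$y)
  if (nrow(geno) != n) stop("genotype rows must match phenotype rows")
  m <- ncol(geno)

  if (model$family == "linear") {
    yr <- qr.resid(mf$qrx, mf$y)
    gr <- qr.resid(mf$qrx, geno)
    sxx <- colSums(gr^2)
    usable <- sxx > n * 1e-12
    beta <- se <- tval <- p <- rep(NA_real_, m)
    df <- n - ncol(mf$xc) - 1L
    sxy <- as.vector(crossprod(gr, yr))
    syy <- sum(yr^2)
    b <- sxy / sxx
    rss <- syy - b^2 * sxx
    s2 <- pmax(rss, 0) / df
    beta[usable] <- b[usable]
    se[usable] <- sqrt(s2 / sxx)[usable]
    tval <- beta / se
    p <- 2 * stats::pt(-abs(tval), df)
    return(data.frame(beta = beta, se = se, t = tval, p = p,
                      flagged = !usable))
  }

  # logistic
  if (length(model$covariates) == 0 &&
      (is.integer(geno) || all(geno == as.integer(geno))) &&
      min(geno) >= 0 && max(geno) <= 2)
    return(fast_logistic_marginals(geno, mf$y))

  out <- data.frame(beta = rep(NA_real_, m), se = NA_real_, t = NA_real_,
                    p = NA_real_, flagged = TRUE)
  for (j in seq_len(m)) {
    g <- geno[, j]
    if (stats::var(g) == 0) next
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(cbind(mf$xc, g = g), mf$y,
                                      family = stats::binomial())),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    k <- ncol(mf$xc) + 1L
    b <- fit$coefficients[k]
    if (!is.finite(b) || abs(b) > 15) next  # separation guard
    w <- fit$weights
    x <- cbind(mf$xc, g = g)
    vc <- tryCatch(solve(crossprod(x * sqrt(w))), error = function(e) NULL)
    if (is.null(vc)) next
    s <- sqrt(vc[k, k])
    out[j, ] <- list(b, s, b / s, 2 * stats::pnorm(-abs(b / s)), FALSE)
  }
  out
}

#' Fast covariate-free marginal logistic fits
#'
#' Maximum-likelihood logistic regression of a binary response on one
#' additive marker (intercept + slope), fitted simultaneously for all
#' markers via Newton iterations on the aggregated 3 x 2 genotype-by-status
#' tables. Exactly the per-marker `glm` solution (same likelihood), at a
#' fraction of the cost. Used as the fast path in the case-control
#' crossover study.
#'
#' @param geno Genotype matrix with entries in \{0, 1, 2\}.
#' @param y Binary response (0/1).
#' @param max_iter,tol Newton iteration controls.
#' @return `data.frame` as in [fit_marginals].
#' @export
fast_logistic_marginals <- function(geno, y, max_iter = 40L, tol = 1e-10) {
  n <- length(y)
  m <- ncol(geno)
  y <- as.numeric(y)
  # per-marker counts of g = 1, 2 overall and among y = 1, recovered from
  # the sums of g and g^2 (g in {0,1,2}): n2 = (q - s)/2, n1 = s - 2 n2
  if (!is.double(geno)) storage.mode(geno) <- "double"
  gsq <- geno * geno
  s <- colSums(geno)
  q <- colSums(gsq)
  s1 <- as.vector(crossprod(geno, y))
  q1 <- as.vector(crossprod(gsq, y))
  n2 <- (q - s) / 2
  n1 <- s - 2 * n2
  k2 <- (q1 - s1) / 2
  k1 <- s1 - 2 * k2
  n0 <- n - n1 - n2
  k0 <- sum(y) - k1 - k2
  tot <- cbind(n0, n1, n2)      # m x 3 totals per genotype value
  cas <- cbind(k0, k1, k2)      # m x 3 case counts
  gval <- c(0, 1, 2)

  usable <- (n1 + n2) > 0 & (n0 + n1) > 0  # polymorphic
  a <- rep(stats::qlogis(pmin(pmax(sum(y) / n, 1e-6), 1 - 1e-6)), m)
  b <- numeric(m)
  active <- usable
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    eta0 <- a[active]
    eta <- cbind(eta0, eta0 + b[active], eta0 + 2 * b[active])
    pr <- stats::plogis(eta)
    w <- tot[active, , drop = FALSE] * pr * (1 - pr)
    resid <- cas[active, , drop = FALSE] -
      tot[active, , drop = FALSE] * pr
    u1 <- rowSums(resid)
    u2 <- as.vector(resid %*% gval)
    i11 <- rowSums(w)
    i12 <- as.vector(w %*% gval)
    i22 <- as.vector(w %*% gval^2)
    det <- i11 * i22 - i12^2
    ok <- is.finite(det) & det > 1e-12
    da <- db <- numeric(sum(active))
    da[ok] <- (i22[ok] * u1[ok] - i12[ok] * u2[ok]) / det[ok]
    db[ok] <- (i11[ok] * u2[ok] - i12[ok] * u1[ok]) / det[ok]
    # dampen huge steps (separation drift)
    da <- pmin(pmax(da, -5), 5)
    db <- pmin(pmax(db, -5), 5)
    idx <- which(active)
    a[idx] <- a[idx] + da
    b[idx] <- b[idx] + db
    conv <- pmax(abs(da), abs(db)) < tol
    active[idx[conv]] <- FALSE
  }
  unconverged <- active
  # Wald SE from observed (= expected) information at the MLE
  eta <- cbind(a, a + b, a + 2 * b)
  pr <- stats::plogis(eta)
  w <- tot * pr * (1 - pr)
  i11 <- rowSums(w)
  i12 <- as.vector(w %*% gval)
  i22 <- as.vector(w %*% gval^2)
  det <- i11 * i22 - i12^2
  se <- sqrt(ifelse(det > 0, i11 / det, NA_real_))
  flagged <- !usable | unconverged | !is.finite(se) | abs(b) > 15
  beta <- ifelse(flagged, NA_real_, b)
  se <- ifelse(flagged, NA_real_, se)
  tval <- beta / se
  data.frame(beta = beta, se = se, t = tval,
             p = 2 * stats::pnorm(-abs(tval)), flagged = flagged)
}
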