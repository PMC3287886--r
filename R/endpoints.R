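#' Endpoint regression model specification
#'
#' The three study endpoints carry fixed covariate-adjustment sets: Q1 is
#' linear adjusted for Q2, age, sex and smoking; Q2 is linear adjusted for
#' Q1, age, sex and smoking; AFF is logistic adjusted for Q1, Q2, Q4, age,
#' sex and smoking. Custom endpoints (e.g. the case-control scenarios'
#' `status`) must state family and covariates explicitly.
#'
#' @param endpoint Endpoint name; column of the phenotype table.
#' @param family `"linear"` or `"logistic"`; filled in automatically for
#'   Q1/Q2/AFF.
#' @param covariates Character vector of adjustment columns; automatic for
#'   Q1/Q2/AFF, default none otherwise.
#' @return An object of class `endpoint_model`.
#' @export
endpoint_model <- function(endpoint, family = NULL, covariates = NULL) {
  defaults <- list(
    Q1  = list(family = "linear",
               covariates = c("Q2", "age", "sex", "smoking")),
    Q2  = list(family = "linear",
               covariates = c("Q1", "age", "sex", "smoking")),
    AFF = list(family = "logistic",
               covariates = c("Q1", "Q2", "Q4", "age", "sex", "smoking"))
  )
  if (endpoint %in% names(defaults)) {
    d <- defaults[[endpoint]]
    if (is.null(family)) family <- d$family
    if (is.null(covariates)) covariates <- d$covariates
  }
  if (is.null(family))
    stop("family must be given for custom endpoint '", endpoint, "'")
  if (is.null(covariates)) covariates <- character(0)
  family <- match.arg(family, c("linear", "logistic"))
  structure(list(endpoint = endpoint, family = family,
                 covariates = covariates),
            class = "endpoint_model")
}

# response vector and covariate design matrix (with intercept) from a model
model_frame <- function(model, data) {
  y <- data[[model$endpoint]]
  if (is.null(y)) stop("endpoint '", model$endpoint, "' not in data")
  missing_cov <- setdiff(model$covariates, names(data))
  if (length(missing_cov))
    stop("covariates not in data: ", paste(missing_cov, collapse = ", "))
  xc <- cbind(`(Intercept)` = 1,
              as.matrix(data[model$covariates]))
  qrx <- qr(xc)
  if (qrx$rank < ncol(xc))
    stop("rank-deficient covariate design; collinear columns: ",
         paste(colnames(xc)[qrx$pivot[-seq_len(qrx$rank)]], collapse = ", "))
  list(y = as.numeric(y), xc = xc, qrx = qrx)
}
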