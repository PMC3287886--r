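#' Minor-allele frequency and count of a genotype column
#'
#' The coded-allele frequency is `sum(g) / (2n)`. If it exceeds 0.5 the
#' minor allele is the reference allele and the frequency and count are
#' flipped. Supermarker (0/1) columns go through the same formula.
#'
#' @param g Genotype vector with entries in \{0, 1, 2\}.
#' @return List with `maf` and `mac` (minor-allele count).
#' @export
compute_maf <- function(g) {
  if (length(g) == 0) stop("empty genotype column")
  if (anyNA(g) || !all(g %in% 0:2))
    stop("genotype entries must be in {0, 1, 2}")
  n2 <- 2 * length(g)
  ac <- sum(g)
  if (ac / n2 > 0.5) list(maf = 1 - ac / n2, mac = n2 - ac)
  else list(maf = ac / n2, mac = ac)
}

# vectorised over columns of a genotype matrix
compute_maf_matrix <- function(geno) {
  n2 <- 2 * nrow(geno)
  ac <- colSums(geno)
  flip <- ac / n2 > 0.5
  data.frame(maf = ifelse(flip, 1 - ac / n2, ac / n2),
             mac = ifelse(flip, n2 - ac, ac),
             flipped = flip)
}

#' Collapse a gene's rare nonsynonymous variants into a supermarker
#'
#' Indicator collapsing: the supermarker is 1 for individuals carrying at
#' least one minor allele across the gene's qualifying variants
#' (nonsynonymous, 0 < MAF <= cutoff), else 0.
#'
#' @param geno Genotype matrix (individuals x markers) for the whole study.
#' @param markers Marker metadata with in-sample `maf` and `flipped`.
#' @param gene Gene id to collapse.
#' @param cutoff Rare-variant MAF cutoff (0.01 or 0.05).
#' @return Integer 0/1 vector with attribute `variants` (contributing
#'   marker ids), or `NULL` when the gene has no qualifying rare variant.
#' @export
collapse_rare_variants <- function(geno, markers, gene, cutoff) {
  sel <- markers$gene_id == gene & markers$class == "nonsynonymous" &
    markers$maf > 0 & markers$maf <= cutoff
  if (!any(sel)) return(NULL)
  g <- geno[, markers$marker_id[sel], drop = FALSE]
  flips <- markers$flipped[sel]
  if (any(flips))  # minor allele is reference: carrier iff dosage < 2
    g[, flips] <- 2L - g[, flips, drop = FALSE]
  sm <- as.integer(rowSums(g > 0) > 0)
  attr(sm, "variants") <- markers$marker_id[sel]
  sm
}

#' Build one of the four analysis datasets
#'
#' Keeps common variants (in-sample MAF strictly above `cutoff`, synonymous
#' and nonsynonymous alike); when `include_rare = TRUE`, appends one
#' supermarker per gene collapsing its rare (0 < MAF <= cutoff)
#' nonsynonymous variants; then removes every marker — supermarkers
#' included — with fewer than `min_mac` minor alleles, and drops genes left
#' without markers. Labels follow the CR1%/CR5%/C1%/C5% scheme.
#'
#' @param study A [genotype_study].
#' @param cutoff Rare-variant MAF cutoff, 0.01 or 0.05 (other values need
#'   `allow_any_cutoff = TRUE`).
#' @param include_rare Append rare-variant supermarkers?
#' @param min_mac Minimum minor-allele count for a marker to be retained.
#' @param allow_any_cutoff Permit non-standard cutoffs.
#' @return An object of class `analysis_dataset`: list with `label`,
#'   `cutoff`, `includes_rare`, `geno`, `markers` (with in-sample `maf`,
#'   `mac`, and `variants` for supermarkers) and `gene_index` (gene id ->
#'   column indices).
#' @export
build_analysis_dataset <- function(study, cutoff, include_rare,
                                   min_mac = 5L, allow_any_cutoff = FALSE) {
  stopifnot(inherits(study, "genotype_study"))
  if (!allow_any_cutoff && !cutoff %in% c(0.01, 0.05))
    stop("cutoff must be 0.01 or 0.05 (set allow_any_cutoff to override)")
  mm <- compute_maf_matrix(study$geno)
  info <- cbind(study$markers[c("marker_id", "gene_id", "class")], mm)

  common <- which(info$maf > cutoff)
  geno <- study$geno[, common, drop = FALSE]
  markers <- info[common, , drop = FALSE]
  markers$variants <- NA_character_

  if (include_rare) {
    genes_with_rare <- unique(info$gene_id[
      info$class == "nonsynonymous" & info$maf > 0 & info$maf <= cutoff])
    sm_cols <- list()
    sm_rows <- list()
    for (gn in genes_with_rare) {
      sm <- collapse_rare_variants(study$geno, info, gn, cutoff)
      if (is.null(sm)) next
      id <- paste0(gn, "_SM")
      sm_cols[[id]] <- sm
      sm_rows[[id]] <- data.frame(
        marker_id = id, gene_id = gn, class = "supermarker",
        maf = NA_real_, mac = NA_real_, flipped = FALSE,
        variants = paste(attr(sm, "variants"), collapse = ","),
        stringsAsFactors = FALSE)
    }
    if (length(sm_cols)) {
      smg <- do.call(cbind, sm_cols)
      smm <- compute_maf_matrix(smg)
      smr <- do.call(rbind, sm_rows)
      smr$maf <- smm$maf
      smr$mac <- smm$mac
      geno <- cbind(geno, smg)
      markers <- rbind(markers, smr)
    }
  }

  keep <- markers$mac >= min_mac
  geno <- geno[, keep, drop = FALSE]
  markers <- markers[keep, , drop = FALSE]
  rownames(markers) <- NULL
  colnames(geno) <- markers$marker_id

  label <- paste0(if (include_rare) "CR" else "C",
                  if (cutoff == 0.01) "1%"
                  else if (cutoff == 0.05) "5%"
                  else paste0(100 * cutoff, "%"))
  structure(
    list(label = label, cutoff = cutoff, includes_rare = include_rare,
         geno = geno, markers = markers,
         gene_index = split(seq_len(ncol(geno)), markers$gene_id)),
    class = "analysis_dataset")
}

#' @export
print.analysis_dataset <- function(x, ...) {
  cat("analysis_dataset", x$label, ":", ncol(x$geno), "markers (",
      sum(x$markers$class == "supermarker"), "supermarkers ) in",
      length(x$gene_index), "genes,", nrow(x$geno), "individuals\n")
  invisible(x)
}

#' Build all four analysis datasets (CR1%, CR5%, C1%, C5%)
#'
#' @inheritParams build_analysis_dataset
#' @return Named list of four `analysis_dataset` objects.
#' @export
build_all_datasets <- function(study, min_mac = 5L) {
  out <- list()
  for (cutoff in c(0.01, 0.05)) for (rare in c(TRUE, FALSE)) {
    ds <- build_analysis_dataset(study, cutoff, rare, min_mac = min_mac)
    out[[ds$label]] <- ds
  }
  out
}

#' Re-apply the dataset filters to an already built dataset
#'
#' Used to check filtering idempotence: recomputes MAF/MAC on the dataset's
#' own columns and re-applies the cutoff and minimum-count rules.
#'
#' @param ds An `analysis_dataset`.
#' @param min_mac Minimum minor-allele count.
#' @return The filtered `analysis_dataset`.
#' @export
refilter_dataset <- function(ds, min_mac = 5L) {
  mm <- compute_maf_matrix(ds$geno)
  keep <- mm$mac >= min_mac &
    (ds$markers$class == "supermarker" | mm$maf > ds$cutoff)
  geno <- ds$geno[, keep, drop = FALSE]
  markers <- ds$markers[keep, , drop = FALSE]
  rownames(markers) <- NULL
  structure(
    list(label = ds$label, cutoff = ds$cutoff,
         includes_rare = ds$includes_rare, geno = geno, markers = markers,
         gene_index = split(seq_len(ncol(geno)), markers$gene_id)),
    class = "analysis_dataset")
}

#' Maximum LD (r^2) between each gene's supermarker and its common variants
#'
#' @param ds An `analysis_dataset` containing supermarkers.
#' @return `data.frame` with `gene_id` and `max_r2` (squared Pearson
#'   correlation; `NA` when a column has zero variance). Genes lacking
#'   either a supermarker or a common variant are omitted.
#' @export
ld_supermarker_vs_common <- function(ds) {
  out <- list()
  for (gn in names(ds$gene_index)) {
    idx <- ds$gene_index[[gn]]
    cls <- ds$markers$class[idx]
    sm <- idx[cls == "supermarker"]
    cm <- idx[cls != "supermarker"]
    if (!length(sm) || !length(cm)) next
    s <- ds$geno[, sm[1]]
    r2 <- vapply(cm, function(j) {
      g <- ds$geno[, j]
      if (stats::var(g) == 0 || stats::var(s) == 0) return(NA_real_)
      stats::cor(s, g)^2
    }, numeric(1))
    out[[gn]] <- data.frame(gene_id = gn,
                            max_r2 = if (all(is.na(r2))) NA_real_
                                     else max(r2, na.rm = TRUE))
  }
  if (!length(out))
    return(data.frame(gene_id = character(), max_r2 = numeric()))
  rr <- do.call(rbind, out)
  rownames(rr) <- NULL
  rr
}

#' Write an analysis dataset as TSV with a label header line
#'
#' @param ds An `analysis_dataset`.
#' @param prefix Output path prefix.
#' @return Invisibly, the file paths.
#' @export
write_dataset_tsv <- function(ds, prefix) {
  gpath <- paste0(prefix, "_genotypes.tsv")
  mpath <- paste0(prefix, "_markers.tsv")
  for (p in c(gpath, mpath))
    writeLines(sprintf("# dataset=%s cutoff=%g includes_rare=%s",
                       ds$label, ds$cutoff, ds$includes_rare), p)
  suppressWarnings({
    utils::write.table(ds$geno, gpath, sep = "\t", quote = FALSE,
                       row.names = FALSE, append = TRUE)
    utils::write.table(ds$markers, mpath, sep = "\t", quote = FALSE,
                       row.names = FALSE, append = TRUE)
  })
  invisible(c(genotypes = gpath, markers = mpath))
}
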