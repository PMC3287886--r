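#' Construct a genotype study container
#'
#' Bundles an individuals-by-markers additive genotype matrix (0/1/2 dosage
#' of the coded allele; 0/1 for collapsed supermarkers) with per-marker
#' metadata.
#'
#' @param geno Integer matrix, individuals in rows, markers in columns;
#'   column names are marker ids.
#' @param markers `data.frame` with one row per genotype column, columns
#'   `marker_id`, `gene_id`, `class` (one of `"nonsynonymous"`,
#'   `"synonymous"`, `"supermarker"`) and optionally `maf` (true simulated
#'   MAF, where known).
#' @return An object of class `genotype_study`.
#' @export
genotype_study <- function(geno, markers) {
  geno <- as.matrix(geno)
  if (ncol(geno) != nrow(markers))
    stop("markers must have one row per genotype column")
  if (is.null(colnames(geno))) colnames(geno) <- markers$marker_id
  if (!identical(colnames(geno), as.character(markers$marker_id)))
    stop("genotype column names must match markers$marker_id")
  ok <- c("nonsynonymous", "synonymous", "supermarker")
  if (!all(markers$class %in% ok))
    stop("marker class must be one of: ", paste(ok, collapse = ", "))
  structure(list(geno = geno, markers = markers), class = "genotype_study")
}

#' @export
print.genotype_study <- function(x, ...) {
  cat("genotype_study:", nrow(x$geno), "individuals x",
      ncol(x$geno), "markers in", length(unique(x$markers$gene_id)),
      "genes\n")
  invisible(x)
}

#' Number of individuals in a study or dataset
#' @param x A `genotype_study` or `analysis_dataset`.
#' @return Integer count.
#' @export
n_individuals <- function(x) nrow(x$geno)

#' Write a genotype study to TSV files
#'
#' Writes `<prefix>_genotypes.tsv` (rows = individuals, header row of marker
#' ids) and `<prefix>_markers.tsv` (marker metadata).
#'
#' @param study A `genotype_study`.
#' @param prefix Path prefix for the two output files.
#' @return Invisibly, the two file paths.
#' @export
write_study_tsv <- function(study, prefix) {
  gpath <- paste0(prefix, "_genotypes.tsv")
  mpath <- paste0(prefix, "_markers.tsv")
  utils::write.table(study$geno, gpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$markers, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(genotypes = gpath, markers = mpath))
}

#' Read a genotype study from TSV files written by [write_study_tsv]
#'
#' @param prefix Path prefix used when writing.
#' @return A `genotype_study`.
#' @export
read_study_tsv <- function(prefix) {
  geno <- as.matrix(utils::read.table(paste0(prefix, "_genotypes.tsv"),
                                      header = TRUE, sep = "\t",
                                      check.names = FALSE))
  markers <- utils::read.table(paste0(prefix, "_markers.tsv"),
                               header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  storage.mode(geno) <- "integer"
  genotype_study(geno, markers)
}

#' Export simulated genotypes as a minimal VCF
#'
#' One synthetic contig; positions are marker indices; diploid unphased GT
#' with allele dosage equal to the stored additive coding. Intended for
#' interoperability checks, not as a faithful variant-call record.
#'
#' @param study A `genotype_study`.
#' @param path Output file path (plain text `.vcf`).
#' @return Invisibly, `path`.
#' @export
write_study_vcf <- function(study, path) {
  g <- study$geno
  n <- nrow(g)
  ids <- colnames(g)
  gt <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrS,length=1000000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", paste0("ind", seq_len(n))), collapse = "\t")
  ), con)
  for (j in seq_len(ncol(g))) {
    row <- c("chrS", j, ids[j], "A", "T", ".", "PASS", ".", "GT",
             gt[g[, j] + 1L])
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(path)
}

#' Import a biallelic VCF plus annotation TSV as a genotype study
#'
#' Gene assignment and functional class are taken from an annotation table
#' keyed by variant id. Missing genotypes are not imputed: any missing GT
#' aborts with an error.
#'
#' @param vcf_path Path to a VCF with diploid GT entries.
#' @param annotation `data.frame` with columns `marker_id`, `gene_id`,
#'   `class`.
#' @return A `genotype_study`.
#' @export
read_study_vcf <- function(vcf_path, annotation) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF import requires the 'vcfR' package")
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(is.na(gt)) || any(grepl("\\.", gt)))
    stop("missing genotypes in VCF; refusing to impute")
  dose <- matrix(
    vapply(strsplit(gsub("\\|", "/", gt), "/"),
           function(a) sum(as.integer(a) > 0), integer(1)),
    nrow = nrow(gt), dimnames = dimnames(gt)
  )
  dose <- t(dose)  # individuals x markers
  ids <- colnames(dose)
  ann <- annotation[match(ids, annotation$marker_id), , drop = FALSE]
  if (anyNA(ann$gene_id))
    stop("annotation missing for variants: ",
         paste(utils::head(ids[is.na(ann$gene_id)]), collapse = ", "))
  storage.mode(dose) <- "integer"
  genotype_study(dose, data.frame(marker_id = ids, gene_id = ann$gene_id,
                                  class = ann$class,
                                  stringsAsFactors = FALSE))
}
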