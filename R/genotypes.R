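#' Construct a genotype matrix object
#'
#' Wraps an n x m matrix of additive minor-allele counts (0/1/2) together
#' with sample and variant identifiers and per-variant sample minor-allele
#' frequencies. This is the common container for both candidate variants
#' and the background genomic markers used for ancestry inference.
#'
#' @param values integer matrix, individuals in rows, variants in columns;
#'   every entry must be 0, 1 or 2 (resolve missingness first, see
#'   [impute_genotypes()]).
#' @param sample_ids optional character vector of row identifiers.
#' @param variant_ids optional character vector of column identifiers.
#' @return An object of class `genotype_matrix` with fields `values`,
#'   `sample_ids`, `variant_ids` and `maf` (folded sample frequency,
#'   always <= 0.5).
#' @examples
#' g <- genotype_matrix(matrix(c(0L, 1L, 2L, 0L), 2, 2))
#' g$maf
#' @export
genotype_matrix <- function(values, sample_ids = NULL, variant_ids = NULL) {
  values <- as.matrix(values)
  if (anyNA(values)) {
    stop("genotype matrix contains missing values; impute first (impute_genotypes)")
  }
  if (!all(values %in% c(0, 1, 2))) {
    stop("genotype values must be additive minor-allele counts in {0, 1, 2}")
  }
  storage.mode(values) <- "integer"
  n <- nrow(values)
  m <- ncol(values)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  if (is.null(variant_ids)) variant_ids <- paste0("V", seq_len(m))
  stopifnot(length(sample_ids) == n, length(variant_ids) == m)
  af <- colSums(values) / (2 * n)
  structure(
    list(values = values, sample_ids = as.character(sample_ids),
         variant_ids = as.character(variant_ids), maf = pmin(af, 1 - af)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  MAF range: %.4g - %.4g\n",
              min(x$maf), max(x$maf)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' Mean-impute missing genotype calls
#'
#' Replaces NA entries of a raw dosage matrix by the column mean (rounded to
#' the nearest integer dosage so the result stays in 0/1/2).
#'
#' @param values numeric matrix with possible NAs.
#' @return integer matrix without NAs.
#' @export
impute_genotypes <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values)) {
    cm <- colMeans(values, na.rm = TRUE)
    cm[is.nan(cm)] <- 0
    idx <- which(is.na(values), arr.ind = TRUE)
    values[idx] <- round(cm[idx[, 2]])
  }
  storage.mode(values) <- "integer"
  values
}

#' Read a genotype matrix from a delimited text file
#'
#' Expects a header row of variant identifiers and a first column of sample
#' identifiers; remaining cells are additive genotype codes (0/1/2, NA
#' allowed and mean-imputed).
#'
#' @param path file path (tab- or whitespace-delimited).
#' @return a [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path) {
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           row.names = 1)
  values <- impute_genotypes(as.matrix(tab))
  genotype_matrix(values, sample_ids = rownames(tab),
                  variant_ids = colnames(tab))
}

#' Read biallelic genotypes from a VCF file
#'
#' Converts GT fields of biallelic records to additive alternate-allele
#' counts, then folds to minor-allele counts per variant. Multi-allelic
#' records are dropped with a message. Requires the `vcfR` package.
#'
#' @param path path to an (optionally gzipped) VCF.
#' @return a [genotype_matrix()].
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  biallelic <- !grepl(",", vcfR::getALT(v), fixed = TRUE)
  if (!all(biallelic)) {
    message(sum(!biallelic), " multi-allelic record(s) dropped")
    v <- v[biallelic, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(g) {
    ifelse(is.na(g), NA_integer_,
           vapply(strsplit(g, "[/|]"), function(a) sum(a == "1"), 0L))
  }
  dos <- apply(gt, 2, count_alt)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1, dimnames = dimnames(gt))
  dos <- t(dos)  # samples x variants
  dos <- impute_genotypes(dos)
  # fold columns where the alternate allele is the major allele
  af <- colMeans(dos) / 2
  flip <- af > 0.5
  dos[, flip] <- 2L - dos[, flip]
  ids <- vcfR::getID(v)
  if (all(is.na(ids))) {
    ids <- paste0(vcfR::getCHROM(v), ":", vcfR::getPOS(v))
  }
  genotype_matrix(dos, sample_ids = rownames(dos), variant_ids = ids)
}
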