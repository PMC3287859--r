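#' Construct a genotype matrix object
#'
#' Bundles an `n x p` allele-count (dosage) matrix with per-SNP annotation.
#' Dosages count copies of one allele per individual, so each entry is 0, 1
#' or 2. No coding direction (minor vs. major allele) is assumed: minor
#' allele frequencies are computed downstream by folding at 0.5, so flipping
#' a column's coding changes nothing in the analysis.
#'
#' @param dosages Numeric matrix of 0/1/2 dosages, individuals in rows.
#'   Row names are sample ids, column names SNP ids (both required).
#' @param info Optional tibble of per-SNP annotation with columns `snp_id`
#'   and any of `chromosome`, `gene`, `maf_declared`. Missing annotation is
#'   filled with empty strings / `NA`.
#' @return An object of class `genotype_matrix`.
#' @export
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, 1), 2, 2,
#'   dimnames = list(c("s1", "s2"), c("snpA", "snpB"))))
#' g
genotype_matrix <- function(dosages, info = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(rownames(dosages)) ||
      (ncol(dosages) > 0L && is.null(colnames(dosages)))) {
    abort("dosage matrix needs sample ids as row names and SNP ids as column names")
  }
  if (anyNA(dosages)) abort("dosage matrix contains missing values; impute at load time")
  if (!all(dosages %in% c(0, 1, 2))) {
    abort("dosages must be allele counts in {0, 1, 2}")
  }
  if (anyDuplicated(rownames(dosages))) abort("duplicate sample ids")
  if (anyDuplicated(colnames(dosages))) abort("duplicate SNP ids")
  if (any(!nzchar(colnames(dosages)))) abort("empty SNP id")

  p <- ncol(dosages)
  base_info <- tibble::tibble(
    snp_id = colnames(dosages) %||% character(0),
    chromosome = NA_character_,
    gene = "",
    maf_declared = NA_real_
  )
  if (!is.null(info)) {
    info <- tibble::as_tibble(info)
    if (!"snp_id" %in% names(info)) abort("`info` needs a snp_id column")
    keep <- intersect(c("chromosome", "gene", "maf_declared"), names(info))
    idx <- match(base_info$snp_id, info$snp_id)
    for (col in keep) {
      vals <- info[[col]][idx]
      base_info[[col]][!is.na(idx)] <- vals[!is.na(idx)]
    }
    md <- base_info$maf_declared
    if (any(!is.na(md) & (md < 0 | md > 0.5))) {
      abort("maf_declared must lie in [0, 0.5]")
    }
  }
  structure(list(dosages = dosages, info = base_info),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$dosages), " individuals x ",
      ncol(x$dosages), " SNPs\n", sep = "")
  ann <- sum(!is.na(x$info$chromosome))
  cat("  annotated SNPs: ", ann, "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Sample ids of a genotype matrix or phenotype table
#' @param x A `genotype_matrix` or `phenotype_tbl`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(x) UseMethod("sample_ids")

#' @export
sample_ids.genotype_matrix <- function(x) rownames(x$dosages)

#' @export
sample_ids.phenotype_tbl <- function(x) x$sample_id

#' SNP ids of a genotype matrix
#' @param g A `genotype_matrix`.
#' @return Character vector of SNP ids.
#' @export
snp_ids <- function(g) colnames(g$dosages) %||% character(0)

#' @describeIn genotype_matrix Per-SNP annotation plus realized MAF, one row
#'   per SNP, as a tibble.
#' @param x A `genotype_matrix`.
#' @param ... Unused.
#' @export
tidy.genotype_matrix <- function(x, ...) {
  dplyr::mutate(x$info, maf = snp_mafs(x)$maf)
}

subset_snps <- function(g, keep) {
  genotype_matrix(g$dosages[, keep, drop = FALSE], g$info)
}

subset_samples <- function(g, keep) {
  genotype_matrix(g$dosages[keep, , drop = FALSE], g$info)
}

# ---- phenotype replicates ---------------------------------------------------

covariate_names <- c("Sex", "Age", "Smoke")

#' Construct a phenotype-replicates table
#'
#' A tibble holding one row per individual: a `sample_id` column, the three
#' non-SNP covariates `Sex`, `Age` and `Smoke`, and one numeric column per
#' quantitative-trait replicate. All replicates share the same individuals
#' (and, after [align_samples()], the same genotype rows); only the residual
#' noise differs between replicates.
#'
#' @param df A data frame with columns `sample_id`, `Sex`, `Age`, `Smoke`,
#'   and at least one trait column.
#' @return A tibble of class `phenotype_tbl`.
#' @export
phenotype_replicates <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("sample_id", covariate_names)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    abort(paste0("phenotype table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(df$sample_id)) abort("duplicate sample ids in phenotype table")
  traits <- setdiff(names(df), need)
  if (length(traits) == 0L) abort("phenotype table has no trait column")
  if (anyDuplicated(traits)) abort("duplicate trait replicate ids")
  for (tr in traits) {
    v <- df[[tr]]
    if (!is.numeric(v) || !all(is.finite(v))) {
      abort(paste0("trait column `", tr, "` must be finite numeric"))
    }
  }
  for (cv in covariate_names) {
    if (!is.numeric(df[[cv]])) abort(paste0("covariate `", cv, "` must be numeric"))
  }
  class(df) <- c("phenotype_tbl", class(df))
  df
}

#' Trait replicate ids of a phenotype table
#' @param p A `phenotype_tbl`.
#' @return Character vector of trait column names.
#' @export
trait_ids <- function(p) {
  setdiff(names(p), c("sample_id", covariate_names))
}

# ---- readers / writers ------------------------------------------------------

#' Read a genotype dosage file
#'
#' Two dialects are supported. `"delimited"`: header row of SNP ids, first
#' column the sample id, tab- or comma-separated dosages. `"plink_raw"`: the
#' PLINK `--recode A` layout (`FID IID PAT MAT SEX PHENOTYPE` then one
#' `snp_allele` column per SNP), with `NA` tokens allowed. Missing dosages
#' are imputed to the per-SNP mode (ties broken toward the smaller dosage)
#' and the imputation count is reported via a message and the
#' `n_imputed` attribute.
#'
#' @param path Path to the genotype file.
#' @param dialect `"delimited"` or `"plink_raw"`.
#' @param info Optional SNP annotation tibble passed to [genotype_matrix()].
#' @return A `genotype_matrix`.
#' @export
read_genotypes <- function(path, dialect = c("delimited", "plink_raw"),
                           info = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (dialect == "delimited") {
    df <- readr::read_delim(path, delim = guess_delim(path),
                            show_col_types = FALSE, progress = FALSE)
    sample_col <- names(df)[1L]
    samples <- as.character(df[[sample_col]])
    dos <- as.matrix(df[, -1L, drop = FALSE])
  } else {
    df <- readr::read_table(path, show_col_types = FALSE, progress = FALSE,
                            na = c("NA", "-9"))
    fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    miss <- setdiff(fixed, names(df))
    if (length(miss) > 0L) {
      abort(paste0("not a PLINK .raw file; missing column(s): ",
                   paste(miss, collapse = ", ")))
    }
    samples <- as.character(df$IID)
    dos <- as.matrix(df[, setdiff(names(df), fixed), drop = FALSE])
    # strip the _allele suffix PLINK appends to SNP ids
    colnames(dos) <- sub("_[^_]*$", "", colnames(dos))
  }
  storage.mode(dos) <- "double"
  bad <- !(is.na(dos) | dos %in% c(0, 1, 2))
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1L, ]
    abort(paste0("dosage outside {0,1,2,NA} at data row ", ij[1L],
                 ", SNP `", colnames(dos)[ij[2L]], "`"))
  }
  n_imp <- 0L
  if (anyNA(dos)) {
    for (j in which(colSums(is.na(dos)) > 0L)) {
      x <- dos[, j]
      miss <- is.na(x)
      tab <- table(factor(x[!miss], levels = c(0, 1, 2)))
      mode_val <- as.numeric(names(tab)[which.max(tab)]) # ties -> smaller
      dos[miss, j] <- mode_val
      n_imp <- n_imp + sum(miss)
    }
    inform(paste0("imputed ", n_imp, " missing dosage(s) to per-SNP mode"))
  }
  rownames(dos) <- samples
  g <- genotype_matrix(dos, info = info)
  attr(g, "n_imputed") <- n_imp
  g
}

guess_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Write a genotype matrix to disk
#'
#' Inverse of [read_genotypes()]; `read_genotypes(write_genotypes(g, f))`
#' reproduces `g` exactly.
#'
#' @param g A `genotype_matrix`.
#' @param path Output path.
#' @param dialect `"delimited"` (tab-separated) or `"plink_raw"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, dialect = c("delimited", "plink_raw")) {
  dialect <- match.arg(dialect)
  dos <- g$dosages
  if (dialect == "delimited") {
    df <- tibble::as_tibble(dos)
    df <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(dos)), df)
    readr::write_tsv(df, path, progress = FALSE)
  } else {
    df <- tibble::as_tibble(dos)
    names(df) <- paste0(names(df), "_A")
    df <- dplyr::bind_cols(
      tibble::tibble(FID = rownames(dos), IID = rownames(dos),
                     PAT = 0L, MAT = 0L, SEX = 0L, PHENOTYPE = -9L),
      df
    )
    readr::write_delim(df, path, delim = " ", progress = FALSE)
  }
  invisible(path)
}

#' Read a phenotype table
#'
#' Delimited text with columns `sample_id`, `Sex`, `Age`, `Smoke`, then one
#' column per quantitative-trait replicate.
#'
#' @param path Path to the phenotype file.
#' @return A `phenotype_tbl`.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  df <- readr::read_delim(path, delim = guess_delim(path),
                          show_col_types = FALSE, progress = FALSE)
  df$sample_id <- as.character(df$sample_id)
  phenotype_replicates(df)
}

#' Write a phenotype table to disk (tab-separated)
#' @param p A `phenotype_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(p, path) {
  readr::write_tsv(tibble::as_tibble(p), path, progress = FALSE)
  invisible(path)
}

# ---- alignment --------------------------------------------------------------

#' Align genotype and phenotype objects on shared samples
#'
#' Restricts both objects to the intersection of their sample ids, in the
#' genotype file's order (genotypes are the larger, fixed object). A warning
#' reports any dropped ids; an empty intersection is an error.
#'
#' @param g A `genotype_matrix`.
#' @param p A `phenotype_tbl`.
#' @return A list with elements `genotypes` and `phenotypes`, row-aligned.
#' @export
align_samples <- function(g, p) {
  gs <- sample_ids(g)
  ps <- sample_ids(p)
  common <- gs[gs %in% ps]
  if (length(common) == 0L) abort("genotype and phenotype sample ids are disjoint")
  dropped <- (length(gs) - length(common)) + (length(ps) - length(common))
  if (dropped > 0L) {
    warn(paste0("align_samples: dropped ", length(gs) - length(common),
                " genotype and ", length(ps) - length(common),
                " phenotype sample(s) outside the intersection"))
  }
  g2 <- subset_samples(g, match(common, gs))
  p2 <- p[match(common, ps), , drop = FALSE]
  class(p2) <- class(p)
  list(genotypes = g2, phenotypes = p2)
}
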