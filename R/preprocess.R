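#' Minor allele frequency of a dosage vector
#'
#' The allele frequency `f = sum(dosages) / (2n)` folded at 0.5:
#' `min(f, 1 - f)`. Folding makes the result invariant to the coding
#' direction of the dosage column.
#'
#' @param x Dosage vector with entries in `{0, 1, 2}`.
#' @return MAF in `[0, 0.5]`.
#' @export
#' @examples
#' compute_maf(c(0, 1, 2, 1)) # 0.5
compute_maf <- function(x) {
  if (length(x) == 0L) abort("empty dosage vector")
  if (anyNA(x) || !all(x %in% c(0, 1, 2))) abort("dosages must be in {0, 1, 2}")
  f <- sum(x) / (2 * length(x))
  min(f, 1 - f)
}

#' Realized MAF of every SNP in a genotype matrix
#'
#' @param g A `genotype_matrix`.
#' @return Tibble with columns `snp_id`, `maf`.
#' @export
snp_mafs <- function(g) {
  f <- colMeans(g$dosages) / 2
  tibble::tibble(snp_id = snp_ids(g), maf = pmin(f, 1 - f))
}

#' Filter SNPs by minor allele frequency
#'
#' Retains SNPs with realized MAF at or above `threshold` (default 0.01, the
#' common-variant boundary). The removed count is reported via a message and
#' the `n_removed` attribute.
#'
#' @param g A `genotype_matrix`.
#' @param threshold MAF cutoff; SNPs with `maf < threshold` are removed.
#' @return Filtered `genotype_matrix`.
#' @export
filter_by_maf <- function(g, threshold = 0.01) {
  maf <- snp_mafs(g)$maf
  keep <- maf >= threshold
  if (!any(keep)) inform("filter_by_maf: no SNP passes the threshold")
  inform(paste0("filter_by_maf: removed ", sum(!keep), " of ", length(keep),
                " SNP(s) with MAF < ", threshold))
  out <- subset_snps(g, keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Collapse groups of identical SNPs
#'
#' SNPs whose dosage columns are bit-identical are grouped; the first member
#' in input order is retained as the group's representative. The returned
#' mapping lets downstream reports re-expand a representative to all of its
#' duplicates. Only exact identity is collapsed (flipped-coding copies with
#' `r^2 = 1` are kept).
#'
#' @param g A `genotype_matrix`.
#' @return A list with `genotypes` (deduplicated) and `groups`, a tibble
#'   with columns `representative`, `member` covering every input SNP.
#' @export
collapse_duplicates <- function(g) {
  dos <- g$dosages
  key <- vapply(seq_len(ncol(dos)),
                function(j) rawToChar(as.raw(dos[, j] + 49)), character(1))
  rep_idx <- match(key, key) # first occurrence of each column pattern
  ids <- snp_ids(g)
  groups <- tibble::tibble(representative = ids[rep_idx], member = ids)
  keep <- which(rep_idx == seq_along(rep_idx))
  n_dropped <- length(ids) - length(keep)
  if (n_dropped > 0L) {
    inform(paste0("collapse_duplicates: removed ", n_dropped,
                  " duplicate SNP(s), ", length(keep), " retained"))
  }
  list(genotypes = subset_snps(g, keep), groups = groups)
}

#' Build a standardized regression design
#'
#' Centers and scales every SNP column (penalized block `X`) and covariate
#' column (unpenalized block `Z`) to mean 0 and unit variance under the
#' `1/n` convention, and centers the response. Column centers and scales are
#' retained so coefficients can be mapped back to the raw scale. The `1/n`
#' variance convention matches the penalized-regression objective, so
#' penalty values are on the conventional scale.
#'
#' @param g A `genotype_matrix`.
#' @param p A `phenotype_tbl` row-aligned with `g` (see [align_samples()]).
#' @param trait_id Name of the trait column to use as response.
#' @param covariates Covariate columns for the unpenalized block; default
#'   `Sex`, `Age`, `Smoke`.
#' @return An object of class `standardized_design` with elements `X`, `Z`,
#'   `y`, centers/scales, and id bookkeeping.
#' @export
standardize_design <- function(g, p, trait_id,
                               covariates = c("Sex", "Age", "Smoke")) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!identical(sample_ids(g), sample_ids(p))) {
    abort("genotypes and phenotypes are not row-aligned; run align_samples() first")
  }
  if (!trait_id %in% trait_ids(p)) {
    abort(paste0("no trait column `", trait_id, "`"))
  }
  xs <- std_columns(g$dosages, "SNP column")
  Z <- NULL; z_center <- numeric(0); z_scale <- numeric(0)
  if (length(covariates) > 0L) {
    zm <- as.matrix(tibble::as_tibble(p)[, covariates, drop = FALSE])
    zs <- std_columns(zm, "covariate")
    Z <- zs$x; z_center <- zs$center; z_scale <- zs$scale
  }
  y_raw <- p[[trait_id]]
  structure(
    list(X = xs$x, Z = Z, y = y_raw - mean(y_raw),
         x_center = xs$center, x_scale = xs$scale,
         z_center = z_center, z_scale = z_scale,
         y_center = mean(y_raw),
         snp_ids = snp_ids(g), covariates = covariates,
         trait_id = trait_id, n = nrow(xs$x)),
    class = "standardized_design")
}

#' @export
print.standardized_design <- function(x, ...) {
  cat("<standardized_design> n = ", x$n, ", ", ncol(x$X),
      " penalized SNP column(s), ",
      if (is.null(x$Z)) 0L else ncol(x$Z),
      " unpenalized covariate(s), trait `", x$trait_id, "`\n", sep = "")
  invisible(x)
}

#' Center and scale matrix columns to unit 1/n-variance
#'
#' The elementary standardization used throughout: each column gets mean 0
#' and `mean(x^2) = 1`. Idempotent up to floating point. Errors on
#' zero-variance columns.
#'
#' @param m Numeric matrix.
#' @return Matrix of the same shape with attributes `center` and `scale`.
#' @export
standardize_columns <- function(m) {
  s <- std_columns(as.matrix(m))
  out <- s$x
  attr(out, "center") <- s$center
  attr(out, "scale") <- s$scale
  out
}

#' Map standardized-scale coefficients back to the raw scale
#'
#' @param d A `standardized_design`.
#' @param beta Named coefficients of the SNP block on the standardized scale.
#' @param gamma Named coefficients of the covariate block on the
#'   standardized scale (may be `NULL`).
#' @return Tibble with columns `term`, `estimate` on the raw scale,
#'   including the intercept.
#' @export
backtransform_coefs <- function(d, beta, gamma = NULL) {
  b_raw <- beta / d$x_scale[names(beta)]
  g_raw <- if (length(gamma) > 0L) gamma / d$z_scale[names(gamma)] else numeric(0)
  icpt <- d$y_center -
    sum(b_raw * d$x_center[names(beta)]) -
    (if (length(g_raw) > 0L) sum(g_raw * d$z_center[names(gamma)]) else 0)
  tibble::tibble(term = c("(Intercept)", names(beta), names(gamma)),
                 estimate = c(icpt, unname(b_raw), unname(g_raw)))
}

#' Squared Pearson correlation between two dosage vectors
#'
#' The standard LD measure `r^2` on allele counts; invariant to flipping
#' either column's coding (`d -> 2 - d`).
#'
#' @param a,b Dosage vectors of equal length, neither constant.
#' @return `r^2` in `[0, 1]`.
#' @export
pairwise_r2 <- function(a, b) {
  if (length(a) != length(b)) abort("vectors differ in length")
  if (var(a) == 0 || var(b) == 0) abort("constant dosage vector")
  cor(a, b)^2
}

#' Screen focal SNPs for their strongest LD partner
#'
#' For each focal SNP, finds the maximum pairwise `r^2` against every other
#' SNP in the panel and the partner attaining it — the check used to judge
#' whether a selected SNP might be standing in for a causal one.
#'
#' @param g A `genotype_matrix`.
#' @param focal SNP ids to screen.
#' @param threshold `r^2` above which the focal SNP is flagged as in LD
#'   (default 0.1).
#' @return Tibble with columns `snp_id`, `partner`, `r2`, `in_ld`.
#' @export
ld_screen <- function(g, focal, threshold = 0.1) {
  ids <- snp_ids(g)
  missing <- setdiff(focal, ids)
  if (length(missing) > 0L) {
    abort(paste0("focal SNP(s) not in panel: ", paste(missing, collapse = ", ")))
  }
  if (length(ids) < 2L) abort("need at least two SNPs to screen LD")
  r <- cor(g$dosages[, focal, drop = FALSE], g$dosages)^2
  purrr::map_dfr(seq_along(focal), function(k) {
    row <- r[k, ]
    row[focal[k]] <- -Inf # exclude self
    best <- which.max(row)
    tibble::tibble(snp_id = focal[k], partner = ids[best],
                   r2 = unname(row[best]), in_ld = unname(row[best]) >= threshold)
  })
}
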