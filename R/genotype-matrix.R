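#' Construct a genotype matrix object
#'
#' The central genotype container: an `n_samples x n_loci` matrix of diploid
#' alternate-allele dosages (0, 1, 2, with `NA` for missing calls) together
#' with a locus registry and a sample-metadata table.
#'
#' @param dosage integer matrix, samples in rows, loci in columns; entries
#'   0/1/2 or `NA` for a missing call.
#' @param loci data.frame with columns `chrom`, `pos` (1-based, as in VCF),
#'   `ref`, `alt`; one row per column of `dosage`.
#' @param samples data.frame of sample metadata with columns `sample_id`,
#'   `sex` (`male`/`female`/`unknown`), `locality`, `cohort`
#'   (`contemporary`/`historic`/`captive`); one row per row of `dosage`.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, loci, samples) {
  dosage <- as.matrix(dosage)
  stopifnot(nrow(dosage) == nrow(samples), ncol(dosage) == nrow(loci))
  ok <- dosage %in% c(0L, 1L, 2L) | is.na(dosage)
  if (!all(ok)) stop("dosage entries must be 0, 1, 2 or NA")
  samples <- validate_sample_meta(samples)
  loci <- as.data.frame(loci)
  req <- c("chrom", "pos", "ref", "alt")
  if (!all(req %in% names(loci))) {
    stop("loci registry needs columns: ", paste(req, collapse = ", "))
  }
  rownames(dosage) <- samples$sample_id
  colnames(dosage) <- paste0(loci$chrom, ":", loci$pos)
  structure(
    list(dosage = dosage, loci = loci, samples = samples),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$dosage))
  cat(sprintf(
    "genotype_matrix: %d samples x %d loci (%.1f%% missing)\n",
    n_samples(x), n_loci(x), 100 * miss
  ))
  tab <- table(x$samples$cohort)
  cat("  cohorts:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples / loci in a genotype matrix
#' @param G a `genotype_matrix`
#' @return integer count
#' @export
n_samples <- function(G) nrow(G$dosage)

#' @rdname n_samples
#' @export
n_loci <- function(G) ncol(G$dosage)

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`
#' @param i sample index (logical, integer or sample ids)
#' @param j locus index (logical or integer)
#' @param ... unused
#' @return a `genotype_matrix`
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_samples(x))
  if (missing(j)) j <- seq_len(n_loci(x))
  if (is.character(i)) i <- match(i, x$samples$sample_id)
  genotype_matrix(
    x$dosage[i, j, drop = FALSE],
    x$loci[j, , drop = FALSE],
    x$samples[i, , drop = FALSE]
  )
}

#' Per-sample missingness and per-locus summaries
#'
#' `sample_missingness()` returns the fraction of missing calls per sample;
#' `locus_call_rate()` the fraction of non-missing calls per locus;
#' `locus_maf()` the minor-allele frequency per locus computed on
#' non-missing calls only.
#'
#' @param G a `genotype_matrix`
#' @return named numeric vector
#' @export
sample_missingness <- function(G) {
  rowMeans(is.na(G$dosage))
}

#' @rdname sample_missingness
#' @export
locus_call_rate <- function(G) {
  colMeans(!is.na(G$dosage))
}

#' @rdname sample_missingness
#' @export
locus_maf <- function(G) {
  p <- colMeans(G$dosage, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

validate_sample_meta <- function(samples) {
  samples <- as.data.frame(samples)
  req <- c("sample_id", "sex", "locality", "cohort")
  miss <- setdiff(req, names(samples))
  if (length(miss)) {
    stop("sample metadata missing columns: ", paste(miss, collapse = ", "))
  }
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicated sample_id in metadata: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  }
  bad_sex <- setdiff(unique(samples$sex), c("male", "female", "unknown"))
  if (length(bad_sex)) stop("invalid sex value(s): ", paste(bad_sex, collapse = ", "))
  bad_cohort <- setdiff(unique(samples$cohort), c("contemporary", "historic", "captive"))
  if (length(bad_cohort)) {
    stop("invalid cohort value(s): ", paste(bad_cohort, collapse = ", "))
  }
  rownames(samples) <- NULL
  samples
}
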