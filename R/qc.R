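#' Locus-level quality filters
#'
#' Retains loci with call rate at least `presence_min` (fraction of samples
#' with a non-missing call) and minor-allele frequency at least `maf_min`
#' (computed on non-missing calls).  Locus order is preserved.  Upstream
#' per-genotype depth/quality filters (MinDepth, MinMapQ, MinQ) apply to
#' variant calling and are not re-applied to hard GT input.
#'
#' @param G a `genotype_matrix`
#' @param presence_min minimum call-rate fraction (e.g. 0.90 or 0.95)
#' @param maf_min minimum minor-allele frequency (e.g. 0.01 or 0.05)
#' @return filtered `genotype_matrix`, with a `"qc"` attribute recording
#'   loci in/out per criterion
#' @export
filter_loci <- function(G, presence_min = 0.90, maf_min = 0.01) {
  stopifnot(inherits(G, "genotype_matrix"), n_loci(G) > 0)
  cr <- locus_call_rate(G)
  maf <- locus_maf(G)
  maf[is.nan(maf)] <- 0   # loci with zero calls
  keep <- cr >= presence_min & maf >= maf_min
  if (!any(keep)) {
    stop("all loci removed by presence/MAF filters; review thresholds ",
         "(presence_min=", presence_min, ", maf_min=", maf_min, ")")
  }
  out <- G[, keep]
  attr(out, "qc") <- list(
    stage = "filter_loci", loci_in = n_loci(G), loci_out = sum(keep),
    removed_presence = sum(cr < presence_min),
    removed_maf = sum(cr >= presence_min & maf < maf_min)
  )
  out
}

#' Sample-level missingness filter
#'
#' Removes samples whose fraction of missing calls is strictly greater than
#' `missing_max` (the "more than 15% missing" rule; a sample at exactly the
#' threshold is retained).
#'
#' @param G a `genotype_matrix` (locus filtering already applied)
#' @param missing_max maximum tolerated missing fraction (default 0.15)
#' @return filtered `genotype_matrix` with a `"qc"` attribute listing the
#'   excluded samples and their missingness
#' @export
filter_samples <- function(G, missing_max = 0.15) {
  stopifnot(inherits(G, "genotype_matrix"))
  miss <- sample_missingness(G)
  keep <- miss <= missing_max
  if (!any(keep)) stop("all samples removed by missingness filter")
  out <- G[keep, ]
  attr(out, "qc") <- list(
    stage = "filter_samples", samples_in = n_samples(G),
    samples_out = sum(keep),
    excluded = data.frame(sample_id = G$samples$sample_id[!keep],
                          missing_fraction = unname(miss[!keep]),
                          stringsAsFactors = FALSE)
  )
  out
}

#' Windowed linkage-disequilibrium pruning
#'
#' Sliding-window LD pruning in the PLINK `--indep-pairwise` style: within
#' each window of `window` loci, advanced by `step` loci along each
#' chromosome, every remaining pair whose squared Pearson correlation of
#' dosages exceeds `r2_max` loses its later-position member; the scan
#' repeats within the window until no surviving pair exceeds the threshold.
#' Pairwise r-squared uses samples non-missing at both loci; pairs with
#' fewer than two complete observations or a zero-variance member are left
#' untouched.  Windows never span chromosomes.
#'
#' @param G a `genotype_matrix`; loci are sorted by (chrom, pos) internally.
#' @param window window size in loci (default 25)
#' @param step step size in loci (default 10)
#' @param r2_max prune threshold on squared correlation (default 0.5)
#' @return pruned `genotype_matrix` with a `"qc"` attribute
#' @export
ld_prune <- function(G, window = 25L, step = 10L, r2_max = 0.5) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (window < 2) stop("window must be at least 2 loci")
  if (step < 1 || step > window) stop("step must be in [1, window]")
  ord <- order(G$loci$chrom, G$loci$pos)
  G <- G[, ord]
  L <- n_loci(G)
  keep <- rep(TRUE, L)
  for (chrom in unique(G$loci$chrom)) {
    idx <- which(G$loci$chrom == chrom)
    starts <- seq(1L, length(idx), by = step)
    for (s in starts) {
      win <- idx[s:min(s + window - 1L, length(idx))]
      if (length(win) < 2) next
      # repeated greedy scan: killing only ever removes loci, so one pass
      # over ordered pairs with liveness checks reaches the fixed point
      for (a in seq_along(win)) {
        ia <- win[a]
        if (!keep[ia]) next
        for (b in seq_along(win)) {
          if (b <= a) next
          ib <- win[b]
          if (!keep[ib]) next
          r2 <- pair_r2(G$dosage[, ia], G$dosage[, ib])
          if (!is.na(r2) && r2 > r2_max) keep[ib] <- FALSE
        }
      }
    }
  }
  out <- G[, keep]
  attr(out, "qc") <- list(stage = "ld_prune", loci_in = L,
                          loci_out = sum(keep), removed_ld = sum(!keep))
  out
}

pair_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (var(x) == 0 || var(y) == 0) return(NA_real_)
  cor(x, y)^2
}

#' Run the full genotype QC stage
#'
#' Convenience wrapper applying [filter_loci()], [filter_samples()] and
#' [ld_prune()] with the thresholds in a [run_config()], and computing
#' [kinship_ml()] on the pruned matrix.  Flagged close kin are reported but
#' retained by default; `drop_kin = TRUE` removes one member (the second id)
#' of each first-degree pair for sensitivity re-runs.
#'
#' @param G a `genotype_matrix`
#' @param cfg a [run_config()]
#' @param drop_kin drop one member of each first-degree pair?
#' @param kinship compute the (quadratic-cost) kinship screen?
#' @return list with `genotypes` (QC'd matrix), `kinship` (pair table or
#'   `NULL`), and `report` (per-stage counts)
#' @export
qc_genotypes <- function(G, cfg = run_config(), drop_kin = FALSE,
                         kinship = TRUE) {
  g1 <- filter_loci(G, cfg$locus_presence_min, cfg$maf_min)
  r1 <- attr(g1, "qc")
  g2 <- filter_samples(g1, cfg$sample_missing_max)
  r2 <- attr(g2, "qc")
  g3 <- ld_prune(g2, cfg$ld_window, cfg$ld_step, cfg$ld_r2_max)
  r3 <- attr(g3, "qc")
  kin <- NULL
  if (kinship) {
    kin <- kinship_ml(g3)
    if (drop_kin) {
      first_deg <- kin[kin$relationship == "first_degree", , drop = FALSE]
      drop <- unique(first_deg$id_b)
      if (length(drop)) g3 <- g3[!g3$samples$sample_id %in% drop, ]
    }
  }
  list(genotypes = g3, kinship = kin,
       report = list(filter_loci = r1, filter_samples = r2, ld_prune = r3))
}
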