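#' Run the full introgression-assessment pipeline
#'
#' Convenience wrapper chaining the stages: genotype QC ([qc_genotypes()]),
#' genotype PCA ([run_pca()]), admixture fitting ([fit_admixture()]) and
#' genomic classification ([classify_genomic()]), morphology scoring
#' ([score_table()]), the morphology-genomics regressions
#' ([regress_morphology()]), per-sex trait PCA contributions and AIC subset
#' selection ([trait_pca_contributions()], [aic_model_search()]), and the
#' threshold report ([threshold_report()]).
#'
#' @param genotypes a `genotype_matrix`
#' @param traits list of `trait_record`s
#' @param cfg a [run_config()]
#' @param anchors anchor sample ids (default: the historic cohort)
#' @param n_replicates admixture restarts (default 10)
#' @param kinship run the kinship screen? (quadratic in samples)
#' @return list with components `qc`, `pca`, `admixture`, `genomic_labels`,
#'   `scores`, `regression_pc1`, `regression_q`, `contributions` (per sex),
#'   `selection` (per sex), `threshold`
#' @export
run_pipeline <- function(genotypes, traits, cfg = run_config(),
                         anchors = NULL, n_replicates = 10L,
                         kinship = TRUE) {
  qc <- qc_genotypes(genotypes, cfg, kinship = kinship)
  G <- qc$genotypes
  if (is.null(anchors)) {
    anchors <- G$samples$sample_id[G$samples$cohort == "historic"]
  }
  anchors <- intersect(anchors, G$samples$sample_id)
  pca <- run_pca(G, anchors = anchors)
  adm <- fit_admixture(G, K = cfg$K, seed = cfg$seed,
                       n_replicates = n_replicates, anchors = anchors)
  labels <- classify_genomic(adm, cfg$q_wild_min)
  scores <- score_table(traits, meta = G$samples)

  pc1 <- setNames(pca$scores[, 1], rownames(pca$scores))
  qw <- setNames(adm$Q[, "wild"], rownames(adm$Q))
  reg_pc1 <- regress_morphology(scores, pc1, "pc1_scores")
  reg_q <- regress_morphology(scores, qw, "q_scores")

  contributions <- list(); selection <- list()
  for (sx in c("male", "female")) {
    n_sex <- sum(vapply(traits, function(r) r$sex == sx && r$scorable, TRUE))
    if (n_sex >= 4) {
      ctr <- trait_pca_contributions(traits, sx)
      contributions[[sx]] <- ctr
      cand <- ctr$trait[ctr$above_average]
      forced <- if (sx == "female") "TarC" else character(0)
      if (length(union(cand, forced)) >= 1) {
        selection[[sx]] <- aic_model_search(pc1, traits, cand,
                                            forced_traits = forced, sex = sx)
      }
    }
  }
  thr <- threshold_report(scores, labels, cfg, meta = G$samples)
  list(qc = qc, pca = pca, admixture = adm, genomic_labels = labels,
       scores = scores, regression_pc1 = reg_pc1, regression_q = reg_q,
       contributions = contributions, selection = selection, threshold = thr)
}

#' Reference morphology score table
#'
#' The field-collected morphology scores of 62 adult individuals (54
#' free-roaming birds across Singapore plus 8 captive farm birds) published
#' with the original junglefowl introgression study and shipped with the
#' package as a plain-text file.  These scores are the empirical basis of
#' the 75/25 management cutoffs: the captive (known-domestic) maximum is
#' 18.75, motivating the conservative domestic cutoff of 25.
#'
#' @return data.frame with columns `sample_id`, `locality`, `score_pct`
#' @export
reference_scores <- function() {
  path <- system.file("extdata", "singapore_scores.csv", package = "wildmix",
                      mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
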