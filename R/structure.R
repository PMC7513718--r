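#' Genotype principal component analysis with anchor orientation
#'
#' Missing dosages are mean-imputed per locus; columns are centred and
#' scaled by `sqrt(p(1-p))` with `p` the sample allele frequency (Patterson
#' scaling), so each SNP contributes on the drift scale.  Eigenvalues are
#' those of the sample covariance of the standardised matrix.  Monomorphic
#' loci (zero variance after imputation) are dropped.
#'
#' Because a principal component's sign is arbitrary, PC1 is oriented so
#' that the anchor samples — the historic cohort, or a designated proxy set
#' of wild-representative individuals — sit on the positive side: after
#' orientation the anchor mean PC1 exceeds the captive-cohort mean (or the
#' overall mean when no captive samples are present).
#'
#' @param G a `genotype_matrix` (post-QC)
#' @param anchors character vector of anchor sample ids; defaults to the
#'   historic cohort in `G`.
#' @return object of class `wm_pca`: `eigenvalues`, `scores` (samples x
#'   components), `pct_variance`, `orientation` (anchor ids and whether PC1
#'   was flipped), `n_loci_used`.
#' @export
run_pca <- function(G, anchors = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (n_samples(G) < 2 || n_loci(G) < 2) stop("need at least 2 samples and 2 loci")
  if (is.null(anchors)) anchors <- G$samples$sample_id[G$samples$cohort == "historic"]
  missing_anchors <- setdiff(anchors, G$samples$sample_id)
  if (length(missing_anchors)) {
    stop("anchor sample(s) absent from genotype matrix: ",
         paste(missing_anchors, collapse = ", "))
  }
  X <- G$dosage
  cm <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X))
  if (length(idx)) X[idx] <- cm[((idx - 1) %/% nrow(X)) + 1]
  p_hat <- colMeans(X) / 2
  sdv <- sqrt(p_hat * (1 - p_hat))
  keep <- sdv > 0 & apply(X, 2, var) > 0
  if (!any(keep)) stop("degenerate input: no polymorphic loci (zero variance)")
  X <- X[, keep, drop = FALSE]
  X <- scale(X, center = TRUE, scale = sdv[keep])
  sv <- svd(X)
  n <- nrow(X)
  eig <- sv$d^2 / (n - 1)
  scores <- sv$u %*% diag(sv$d, length(sv$d))
  rownames(scores) <- G$samples$sample_id
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))

  flipped <- FALSE
  if (length(anchors)) {
    anchor_mean <- mean(scores[anchors, 1])
    capt <- G$samples$sample_id[G$samples$cohort == "captive"]
    ref_mean <- if (length(capt)) mean(scores[capt, 1]) else mean(scores[, 1])
    if (anchor_mean < ref_mean) {
      scores[, 1] <- -scores[, 1]
      flipped <- TRUE
    }
  }
  structure(
    list(eigenvalues = eig, scores = scores,
         pct_variance = 100 * sv$d^2 / sum(sv$d^2),
         orientation = list(anchors = anchors, pc1_flipped = flipped),
         n_loci_used = sum(keep)),
    class = "wm_pca"
  )
}

#' @export
print.wm_pca <- function(x, ...) {
  cat(sprintf("wm_pca: %d samples, %d loci; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), x$n_loci_used, x$pct_variance[1],
              x$pct_variance[2]))
  invisible(x)
}

#' Maximum-likelihood admixture model
#'
#' Fits the K-component admixture model by block-relaxation EM: the
#' log-likelihood `sum_il [ g_il log(pi_il) + (2 - g_il) log(1 - pi_il) ]`
#' with `pi_il = sum_k Q_ik P_kl` is maximised over per-sample ancestry
#' fractions Q (rows on the simplex) and per-component allele frequencies
#' P.  Missing genotypes are skipped in the likelihood (not imputed).
#' Updates alternate Q and P until the relative log-likelihood change drops
#' below `tol` or `max_iter` iterations; the best of `n_replicates` random
#' initialisations is returned.  P is clamped to `[1e-6, 1 - 1e-6]` to keep
#' the log-likelihood finite.
#'
#' Cluster labels are arbitrary under the likelihood, so components are
#' relabelled after fitting: component 1 ("wild") is the component with the
#' highest mean membership over the anchor samples (historic cohort by
#' default, or a designated wild-representative proxy set).
#'
#' @param G a `genotype_matrix` (post-QC)
#' @param K number of ancestry components (default 2)
#' @param seed integer seed for the random initialisations
#' @param n_replicates number of random restarts (default 10)
#' @param anchors anchor sample ids for the wild-component relabelling;
#'   defaults to the historic cohort.
#' @param max_iter,tol EM stopping rule (default 2000 iterations, relative
#'   tolerance 1e-6)
#' @return object of class `wm_admixture`: `K`, `Q` (samples x K, column
#'   "wild" first when anchors are available), `P` (K x loci),
#'   `loglik`, `loglik_trace` (best replicate), `traces` (all replicates),
#'   `converged`, `best_replicate`, `seed`.
#' @export
fit_admixture <- function(G, K = 2L, seed = 1L, n_replicates = 10L,
                          anchors = NULL, max_iter = 2000L, tol = 1e-6) {
  stopifnot(inherits(G, "genotype_matrix"))
  n <- n_samples(G); L <- n_loci(G)
  if (K < 1) stop("K must be at least 1")
  if (K > n) stop("K exceeds the number of samples")
  if (is.null(anchors)) anchors <- G$samples$sample_id[G$samples$cohort == "historic"]

  Gm <- G$dosage
  M <- !is.na(Gm)
  G0 <- ifelse(M, Gm, 0)
  G2 <- ifelse(M, 2 - Gm, 0)
  Li2 <- 2 * rowSums(M)

  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  fits <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(rep_seeds[r])
    Q <- matrix(rgamma(n * K, 1), n, K)
    Q <- Q / rowSums(Q)
    P <- matrix(runif(K * L, 0.05, 0.95), K, L)
    trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      Pi <- Q %*% P
      Pi <- pmin(pmax(Pi, 1e-12), 1 - 1e-12)
      ll <- sum(G0 * log(Pi) + G2 * log1p(-Pi))
      trace <- c(trace, ll)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll_old)) {
        converged <- TRUE
        break
      }
      ll_old <- ll
      R1 <- G0 / Pi          # zero where missing
      R0 <- G2 / (1 - Pi)
      A <- R1 %*% t(P)       # n x K
      B <- R0 %*% t(1 - P)
      Qn <- Q * (A + B) / Li2
      Qn <- Qn / rowSums(Qn)
      num <- P * (t(Q) %*% R1)   # K x L
      den <- num + (1 - P) * (t(Q) %*% R0)
      P <- num / den
      P <- pmin(pmax(P, 1e-6), 1 - 1e-6)
      Q <- Qn
    }
    fits[[r]] <- list(Q = Q, P = P, loglik = trace[length(trace)],
                      trace = trace, converged = converged)
  }
  lls <- vapply(fits, `[[`, 0, "loglik")
  best <- which.max(lls)
  fit <- fits[[best]]
  if (!fit$converged) {
    warning("admixture EM did not converge within ", max_iter, " iterations")
  }

  Q <- fit$Q; P <- fit$P
  rownames(Q) <- G$samples$sample_id
  colnames(Q) <- paste0("pop", seq_len(K))
  if (length(anchors) && K > 1) {
    missing_anchors <- setdiff(anchors, G$samples$sample_id)
    if (length(missing_anchors)) {
      stop("anchor sample(s) absent from genotype matrix: ",
           paste(missing_anchors, collapse = ", "))
    }
    wild_k <- which.max(colMeans(Q[anchors, , drop = FALSE]))
    ord <- c(wild_k, setdiff(seq_len(K), wild_k))
    Q <- Q[, ord, drop = FALSE]
    P <- P[ord, , drop = FALSE]
    colnames(Q) <- c("wild", paste0("pop", seq_len(K))[-1])
  } else if (K == 1) {
    colnames(Q) <- "wild"
  }
  structure(
    list(K = as.integer(K), Q = Q, P = P, loglik = fit$loglik,
         loglik_trace = fit$trace,
         traces = lapply(fits, `[[`, "trace"),
         converged = fit$converged, best_replicate = best,
         anchors = anchors, seed = as.integer(seed)),
    class = "wm_admixture"
  )
}

#' @export
print.wm_admixture <- function(x, ...) {
  cat(sprintf(
    "wm_admixture: K=%d, %d samples, %d loci; loglik %.2f (replicate %d%s)\n",
    x$K, nrow(x$Q), ncol(x$P), x$loglik, x$best_replicate,
    if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Genomic wild-type classification from membership coefficients
#'
#' Labels each individual `"wild-type"` when its wild-component membership
#' coefficient q is at least `q_wild_min` (inclusive threshold, q >= 0.9 by
#' default), else `"admixed"`.  Higher q indicates less domestic ancestry.
#'
#' @param fit a `wm_admixture` with the wild component resolved (column
#'   "wild")
#' @param q_wild_min inclusive wild-type threshold (default 0.9)
#' @return data.frame `sample_id`, `q_wild`, `label`, with attribute
#'   `"pct_wild"` giving the percentage of wild-type individuals.
#' @export
classify_genomic <- function(fit, q_wild_min = 0.9) {
  stopifnot(inherits(fit, "wm_admixture"))
  if (!"wild" %in% colnames(fit$Q)) {
    stop("fit has no resolved wild component; provide anchors to fit_admixture")
  }
  qw <- fit$Q[, "wild"]
  out <- data.frame(
    sample_id = rownames(fit$Q), q_wild = unname(qw),
    label = ifelse(qw >= q_wild_min, "wild-type", "admixed"),
    stringsAsFactors = FALSE
  )
  attr(out, "pct_wild") <- 100 * mean(out$label == "wild-type")
  out
}
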