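#' Maximum-likelihood kinship estimation
#'
#' For every sample pair, maximises the genotype-pair likelihood over the
#' IBD-sharing probabilities (k0, k1, k2) on the 2-simplex, assuming
#' Hardy-Weinberg proportions at each locus, independent loci, and allele
#' frequencies estimated from the sample.  The kinship coefficient is
#' `phi = k2/2 + k1/4`.  Pairs with `phi >= 0.177` (the midpoint between
#' the first- and second-degree expectations on the standard
#' 2^(-k - 3/2) relationship ladder) are flagged first-degree (siblings or
#' parent-offspring); such pairs are reported, not removed, by default.
#'
#' The constrained maximisation is performed by EM on the three-component
#' IBD mixture (the component densities are fixed given the allele
#' frequencies, so the mixing weights have closed-form monotone updates),
#' with three starting points to avoid boundary local optima and a 1e-8
#' log-likelihood convergence tolerance.
#'
#' @param G a `genotype_matrix` (locus-filtered)
#' @param min_loci minimum informative (both-called) loci for a pair; below
#'   this the pair is reported with `relationship = "insufficient_data"`
#'   and no estimate (default 50).
#' @param first_degree_phi kinship threshold for the first-degree flag.
#' @return data.frame with one row per pair: `id_a`, `id_b`, `n_loci`,
#'   `k0`, `k1`, `k2`, `phi`, `loglik`, `relationship`.
#' @export
kinship_ml <- function(G, min_loci = 50L, first_degree_phi = 0.177) {
  stopifnot(inherits(G, "genotype_matrix"))
  n <- n_samples(G)
  if (n < 2) stop("need at least 2 samples for kinship")
  p <- colMeans(G$dosage, na.rm = TRUE) / 2
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  ids <- G$samples$sample_id
  pairs <- combn(n, 2)
  out <- vector("list", ncol(pairs))
  for (pp in seq_len(ncol(pairs))) {
    i <- pairs[1, pp]; j <- pairs[2, pp]
    gi <- G$dosage[i, ]; gj <- G$dosage[j, ]
    ok <- !is.na(gi) & !is.na(gj)
    row <- data.frame(id_a = ids[i], id_b = ids[j], n_loci = sum(ok),
                      k0 = NA_real_, k1 = NA_real_, k2 = NA_real_,
                      phi = NA_real_, loglik = NA_real_,
                      relationship = "insufficient_data",
                      stringsAsFactors = FALSE)
    if (sum(ok) >= min_loci) {
      fit <- kinship_pair_mle(gi[ok], gj[ok], p[ok])
      row$k0 <- fit$k[1]; row$k1 <- fit$k[2]; row$k2 <- fit$k[3]
      row$phi <- fit$k[3] / 2 + fit$k[2] / 4
      row$loglik <- fit$loglik
      row$relationship <- if (row$phi >= first_degree_phi) "first_degree" else "unrelated"
    }
    out[[pp]] <- row
  }
  do.call(rbind, out)
}

# Per-locus genotype-pair probabilities conditional on IBD state (0/1/2),
# as functions of the reference-pool alternate-allele frequency p under HWE.
# Columns: c0 = independent (HWE x HWE), c1 = one allele shared IBD,
# c2 = both shared (identical genotypes).
ibd_component_probs <- function(g1, g2, p) {
  q <- 1 - p
  hw <- function(g) ifelse(g == 0, q^2, ifelse(g == 1, 2 * p * q, p^2))
  c0 <- hw(g1) * hw(g2)
  # joint under IBD=1 (one shared allele, the other drawn from the pool)
  c1 <- numeric(length(p))
  s <- g1 * 10 + g2
  c1[s == 0]  <- q[s == 0]^3
  c1[s == 1 | s == 10] <- p[s == 1 | s == 10] * q[s == 1 | s == 10]^2
  c1[s == 11] <- p[s == 11] * q[s == 11]
  c1[s == 12 | s == 21] <- p[s == 12 | s == 21]^2 * q[s == 12 | s == 21]
  c1[s == 22] <- p[s == 22]^3
  # s == 2 or 20 (opposite homozygotes) impossible with a shared allele: 0
  c2 <- ifelse(g1 == g2, hw(g1), 0)
  cbind(c0, c1, c2)
}

kinship_pair_mle <- function(g1, g2, p, tol = 1e-8, max_iter = 1000L) {
  C <- ibd_component_probs(g1, g2, p)
  starts <- list(c(0.98, 0.01, 0.01), c(0.25, 0.5, 0.25), c(0.01, 0.01, 0.98))
  best <- NULL
  for (k in starts) {
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      mix <- C %*% k                      # per-locus likelihood
      ll <- sum(log(mix))
      if (is.finite(ll_old) && ll - ll_old < tol * abs(ll_old)) break
      ll_old <- ll
      resp <- sweep(C, 1, mix, "/") %*% diag(k)
      k <- colSums(resp) / nrow(C)
      k <- k / sum(k)
    }
    ll <- sum(log(C %*% k))
    if (is.null(best) || ll > best$loglik) best <- list(k = as.numeric(k), loglik = ll)
  }
  # EM approaches simplex vertices only geometrically; evaluate the exact
  # vertex solutions (unrelated, parent-offspring, duplicate) so the MLE
  # never falls below them
  for (k in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    mix <- C %*% k
    if (any(mix <= 0)) next   # vertex incompatible with some genotype pair
    ll <- sum(log(mix))
    if (ll > best$loglik) best <- list(k = k, loglik = ll)
  }
  best
}
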