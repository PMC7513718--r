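test_that("locus filters implement the stated call-rate and MAF rules", {
  # 8/10 called at presence_min 0.90 -> removed
  d <- matrix(1L, 10, 2)
  d[1:2, 1] <- NA
  d[1, 2] <- 2L   # keep locus 2 polymorphic
  G <- toy_gm(d)
  out <- filter_loci(G, presence_min = 0.90, maf_min = 0)
  expect_equal(n_loci(out), 1L)
  expect_equal(out$loci$pos, G$loci$pos[2])

  # dosages (0,0,0,0,1) over 5 samples: MAF 0.1 >= 0.05 -> kept
  G2 <- toy_gm(matrix(c(0L, 0L, 0L, 0L, 1L), 5, 1))
  expect_equal(n_loci(filter_loci(G2, 0, 0.05)), 1L)
  # ... but removed at maf_min 0.15
  expect_error(filter_loci(G2, 0, 0.15), "all loci removed")
})

test_that("locus filtering matches a brute-force per-locus oracle and is idempotent", {
  set.seed(404)
  d <- matrix(rbinom(12 * 20, 2, 0.15), 12, 20)
  d[matrix(runif(12 * 20) < 0.12, 12, 20)] <- NA
  G <- toy_gm(d)
  keep <- oracle_locus_filter(d, presence_min = 0.9, maf_min = 0.05)
  out <- filter_loci(G, 0.9, 0.05)
  expect_equal(out$loci$pos, G$loci$pos[keep])
  # idempotence
  out2 <- filter_loci(out, 0.9, 0.05)
  expect_identical(out2$dosage, out$dosage)
})

test_that("sample missingness uses a strict > threshold", {
  d <- matrix(0L, 3, 20)
  d[, 1] <- c(0L, 1L, 2L)          # keep loci estimable
  d[1, 1:4] <- NA                  # 20% missing -> removed
  d[2, 1:3] <- NA                  # exactly 15% -> retained
  G <- toy_gm(d)
  out <- filter_samples(G, missing_max = 0.15)
  expect_equal(out$samples$sample_id, G$samples$sample_id[2:3])
  expect_equal(attr(out, "qc")$excluded$sample_id, G$samples$sample_id[1])
})

test_that("LD pruning drops the later member of perfectly correlated pairs", {
  set.seed(7)
  base <- rbinom(20, 2, 0.5)
  d <- cbind(base, base, rbinom(20, 2, 0.5))
  G <- toy_gm(d)
  out <- ld_prune(G, window = 3, step = 1, r2_max = 0.5)
  expect_equal(n_loci(out), 2L)
  expect_true(G$loci$pos[1] %in% out$loci$pos)   # earlier member survives
  expect_false(G$loci$pos[2] %in% out$loci$pos)
})

test_that("LD pruning leaves independent loci untouched", {
  G <- random_gm(40, 15, seed = 21)
  out <- ld_prune(G, window = 5, step = 2, r2_max = 0.5)
  expect_equal(n_loci(out), 15L)
})

test_that("windowed pruning matches an independent fixed-point oracle", {
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    d <- matrix(rbinom(25 * 30, 2, 0.5), 25, 30)
    # plant three highly correlated pairs at varying separations
    d[, 5] <- d[, 4]
    d[, 12] <- ifelse(runif(25) < 0.9, d[, 10], rbinom(25, 2, 0.5))
    d[, 25] <- d[, 24]
    G <- toy_gm(d)
    out <- ld_prune(G, window = 8, step = 3, r2_max = 0.5)
    alive <- oracle_ld_prune(d, G$loci$pos, window = 8, step = 3, r2_max = 0.5)
    expect_equal(out$loci$pos, G$loci$pos[alive])
    # post-condition: no surviving within-window pair exceeds the threshold
    ids <- which(alive)
    for (s in seq(1, 30, by = 3)) {
      win <- intersect(s:(s + 7), ids)
      if (length(win) < 2) next
      prs <- combn(win, 2)
      r2s <- apply(prs, 2, function(pp) oracle_r2(d[, pp[1]], d[, pp[2]]))
      expect_true(all(is.na(r2s) | r2s <= 0.5))
    }
  }
})

test_that("pruning respects chromosome boundaries and rejects bad windows", {
  set.seed(9)
  base <- rbinom(30, 2, 0.5)
  d <- cbind(base, base)
  loci <- data.frame(chrom = c("1", "2"), pos = c(100L, 100L),
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  G <- genotype_matrix(d, loci, toy_meta(30))
  out <- ld_prune(G, window = 25, step = 10, r2_max = 0.5)
  expect_equal(n_loci(out), 2L)   # identical loci on different chromosomes
  expect_error(ld_prune(G, window = 1, step = 1), "window")
})

test_that("kinship MLE recovers duplicates, parent-offspring and unrelated pairs", {
  set.seed(1234)
  L <- 2000
  p <- runif(L, 0.1, 0.9)
  bg <- matrix(rbinom(10 * L, 2, rep(p, each = 10)), 10, L)
  po <- simulate_parent_offspring(p, seed = 99)
  a <- rbinom(L, 2, p)                       # unrelated to everything
  d <- rbind(bg, a, a, po$parent, po$child)  # rows 11,12 duplicates; 13,14 PO
  G <- toy_gm(d)
  kin <- kinship_ml(G)
  ids <- G$samples$sample_id
  pick <- function(i, j) kin[kin$id_a == ids[i] & kin$id_b == ids[j], ]

  dup <- pick(11, 12)
  expect_equal(dup$phi, 0.5, tolerance = 0.02)
  expect_equal(dup$k2, 1, tolerance = 0.04)
  expect_equal(dup$relationship, "first_degree")

  parent_child <- pick(13, 14)
  expect_equal(parent_child$phi, 0.25, tolerance = 0.03)
  expect_gt(parent_child$k1, 0.85)
  expect_equal(parent_child$relationship, "first_degree")

  unrel <- pick(1, 11)
  expect_lt(unrel$phi, 0.05)
  expect_equal(unrel$relationship, "unrelated")

  # simplex and likelihood-dominance invariants over all pairs
  expect_true(all(abs(kin$k0 + kin$k1 + kin$k2 - 1) < 1e-9))
  expect_true(all(kin$phi >= 0 & kin$phi <= 0.5 + 1e-9))
  # the MLE can never fall below the unrelated (k = (1,0,0)) likelihood
  phat <- pmin(pmax(colMeans(d, na.rm = TRUE) / 2, 1e-6), 1 - 1e-6)
  hw <- function(g, p) ifelse(g == 0, (1 - p)^2, ifelse(g == 1, 2 * p * (1 - p), p^2))
  ll_unrel <- sum(log(hw(d[1, ], phat)) + log(hw(d[11, ], phat)))
  expect_gte(pick(1, 11)$loglik, ll_unrel - 1e-6)
})

test_that("pairs with too few overlapping loci are flagged, not called", {
  d <- matrix(rbinom(3 * 60, 2, 0.5), 3, 60)
  d[1, 1:40] <- NA
  d[2, 21:60] <- NA   # overlap of pair (1,2) is 0 loci... all < 50
  G <- toy_gm(d)
  kin <- kinship_ml(G, min_loci = 50)
  r12 <- kin[kin$id_a == G$samples$sample_id[1] &
               kin$id_b == G$samples$sample_id[2], ]
  expect_equal(r12$relationship, "insufficient_data")
  expect_true(is.na(r12$phi))
})
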