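test_that("regression recovers perfect collinearity and rejects degenerate input", {
  sc <- data.frame(sample_id = paste0("s", 1:10), score_pct = seq(5, 95, 10))
  axis <- setNames(0.01 * sc$score_pct - 0.3, sc$sample_id)
  fit <- suppressWarnings(regress_morphology(sc, axis, "pc1_scores"))
  expect_equal(fit$r_squared, 1)
  expect_lt(fit$p_value, 1e-12)
  expect_equal(fit$slope, 0.01)
  expect_error(regress_morphology(sc, setNames(rep(1, 10), sc$sample_id)),
               "zero variance")
})

test_that("permuting scores against the axis destroys the association", {
  set.seed(55)
  n <- 30
  sc <- data.frame(sample_id = paste0("s", 1:n),
                   score_pct = runif(n, 0, 100))
  axis <- setNames(sc$score_pct / 100 + rnorm(n, 0, 0.1), sc$sample_id)
  r2s <- replicate(200, {
    perm <- sc
    perm$score_pct <- sample(perm$score_pct)
    regress_morphology(perm, axis)$r_squared
  })
  expect_lt(mean(r2s), 0.1)
  # while the unpermuted pairing is strongly associated
  expect_lt(regress_morphology(sc, axis)$p_value, 1e-6)
})

test_that("ancestry-linked traits produce a significant morphology-axis association", {
  ds <- simulate_dataset(sim_config(n_loci = 10, n_wild = 20, n_feral = 25,
                                    n_captive = 15, n_historic = 0,
                                    trait_slope_range = c(4, 8), seed = 77))
  sc <- score_table(ds$traits)
  q <- setNames(ds$truth$samples$q_true, ds$truth$samples$sample_id)
  fit <- regress_morphology(sc, q, "q_scores")
  expect_lt(fit$p_value, 0.01)
  expect_gt(fit$slope, 0)
})

test_that("trait contributions match a brute-force eigendecomposition", {
  set.seed(66)
  n <- 40
  q <- runif(n)
  vals <- cbind(
    Hack = as.numeric(runif(n) < plogis(6 * (q - 0.5))),
    Body = sample(c(0, 0.5, 1), n, replace = TRUE),
    Tail = as.numeric(runif(n) < plogis(5 * (q - 0.5))),
    BP = as.numeric(runif(n) < 0.5),
    TarC = as.numeric(runif(n) < plogis(4 * (q - 0.5))),
    Pri = as.numeric(runif(n) < 0.5)
  )
  recs <- lapply(1:n, function(i) {
    r <- make_record(paste0("f", i), "female", rep(1, 10))
    r$traits <- vals[i, ]    # six-trait toy schema
    r
  })
  ctr <- trait_pca_contributions(recs, "female")
  ev <- eigen(cor(vals))$vectors[, 1]
  expect_equal(sort(ctr$contribution, decreasing = TRUE),
               sort(100 * ev^2 / sum(ev^2), decreasing = TRUE),
               tolerance = 1e-8)
  expect_equal(sum(ctr$contribution), 100, tolerance = 1e-6)
  expect_equal(ctr$expected_average, rep(100 / 6, 6))

  # permutation equivariance: reordering traits permutes contributions
  perm <- c(3, 1, 2, 6, 5, 4)
  recs_p <- lapply(recs, function(r) { r$traits <- r$traits[perm]; r })
  ctr_p <- trait_pca_contributions(recs_p, "female")
  expect_equal(ctr_p$contribution[match(ctr$trait, ctr_p$trait)],
               ctr$contribution, tolerance = 1e-8)
})

test_that("degenerate contribution cases behave as documented", {
  n <- 20
  varying <- rep(c(0, 1), length.out = n)
  recs <- lapply(1:n, function(i) {
    r <- make_record(paste0("f", i), "female", rep(1, 10))
    r$traits <- c(Hack = varying[i], Body = 1, Tail = 0)
    r
  })
  expect_warning(ctr <- trait_pca_contributions(recs, "female"), "constant")
  expect_equal(ctr$contribution[ctr$trait == "Hack"], 100)
  expect_equal(ctr$contribution[ctr$trait != "Hack"], c(0, 0))

  # exactly two equal-variance traits split the loading evenly: neither is
  # strictly above the expected average
  set.seed(12)
  recs2 <- lapply(1:30, function(i) {
    r <- make_record(paste0("g", i), "female", rep(1, 10))
    r$traits <- c(Hack = as.numeric(runif(1) < 0.5),
                  Tail = as.numeric(runif(1) < 0.5))
    r
  })
  ctr2 <- trait_pca_contributions(recs2, "female")
  expect_equal(ctr2$contribution, c(50, 50), tolerance = 1e-9)
})

test_that("AIC table follows the Gaussian-MLE convention with df = predictors + 2", {
  set.seed(88)
  n <- 25
  q <- runif(n)
  sch <- trait_schema("male")
  recs <- lapply(1:n, function(i) {
    vals <- vapply(sch$levels, function(lv) sample(lv, 1), 0)
    vals[2] <- as.numeric(runif(1) < q[i])   # Body informative
    vals[3] <- as.numeric(runif(1) < q[i])   # Tail informative
    make_record(paste0("m", i), "male", vals)
  })
  axis <- setNames(q + rnorm(n, 0, 0.1), paste0("m", 1:n))
  sel <- aic_model_search(axis, recs, c("Body", "Tail", "Pri"), sex = "male")
  expect_equal(nrow(sel), 7)     # all non-empty subsets of 3 candidates
  expect_equal(sel$df, sel$n_predictors + 2L)
  expect_true(all(diff(sel$aic) >= 0))

  # oracle: AIC = 2 df - 2 [-n/2 (log(2 pi RSS/n) + 1)]
  X <- do.call(rbind, lapply(recs, `[[`, "traits"))
  y <- unname(axis)
  for (r in seq_len(nrow(sel))) {
    preds <- strsplit(sel$predictors[r], "+", fixed = TRUE)[[1]]
    rss <- sum(lm(y ~ X[, preds, drop = FALSE])$residuals^2)
    ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
    expect_equal(sel$aic[r], 2 * sel$df[r] - 2 * ll, tolerance = 1e-8)
  }

  # df bookkeeping matches the published convention: 3 predictors -> 5
  expect_equal(sel$df[sel$predictors == "Body+Tail+Pri"], 5L)
  expect_equal(sel$df[sel$predictors == "Body+Tail"], 4L)
})

test_that("AIC ranking is invariant to affine rescaling of the axis", {
  set.seed(99)
  n <- 30
  q <- runif(n)
  sch <- trait_schema("female")
  recs <- lapply(1:n, function(i) {
    vals <- vapply(sch$levels, function(lv) sample(lv, 1), 0)
    vals[5] <- as.numeric(runif(1) < q[i])
    make_record(paste0("f", i), "female", vals)
  })
  axis <- setNames(q + rnorm(n, 0, 0.2), paste0("f", 1:n))
  s1 <- aic_model_search(axis, recs, c("Hack", "TarC", "Pri"), sex = "female")
  s2 <- aic_model_search(-3.7 * axis + 12, recs, c("Hack", "TarC", "Pri"),
                         sex = "female")
  expect_equal(s1$predictors, s2$predictors)
  # the shift in AIC is the same constant for every model: n log|a|
  expect_equal(diff(range((s2$aic - s1$aic))), 0, tolerance = 1e-8)
  expect_equal(mean(s2$aic - s1$aic), 2 * n * log(3.7), tolerance = 1e-8)
})

test_that("forced traits appear in every fitted model", {
  set.seed(101)
  n <- 20
  sch <- trait_schema("female")
  recs <- lapply(1:n, function(i) {
    make_record(paste0("f", i), "female",
                vapply(sch$levels, function(lv) sample(lv, 1), 0))
  })
  axis <- setNames(rnorm(n), paste0("f", 1:n))
  sel <- aic_model_search(axis, recs, c("Hack", "Pri"),
                          forced_traits = "TarC", sex = "female")
  expect_true(all(grepl("TarC", sel$predictors)))
  expect_true("TarC" %in% sel$predictors)   # the forced-only model is fitted
})

test_that("adding a pure-noise predictor usually worsens AIC rank", {
  set.seed(111)
  worse <- replicate(50, {
    n <- 40
    x1 <- rnorm(n); x2 <- rnorm(n); noise <- rnorm(n)
    y <- x1 + x2 + rnorm(n, 0, 0.5)
    AIC(lm(y ~ x1 + x2 + noise)) > AIC(lm(y ~ x1 + x2))
  })
  expect_gte(mean(worse), 0.8)
})

test_that("morphology thresholds classify with strict inequalities", {
  cfg <- run_config()
  expect_equal(classify_morphology(80, cfg), "wild")
  expect_equal(classify_morphology(18.75, cfg), "domestic")
  expect_equal(classify_morphology(50, cfg), "intermediate")
  expect_equal(classify_morphology(c(75, 25), cfg),
               c("intermediate", "intermediate"))   # boundary values
  expect_error(classify_morphology(101, cfg))
})

test_that("threshold report counts errors and the captive maximum", {
  cfg <- run_config()
  sc <- data.frame(
    sample_id = paste0("s", 1:6),
    score_pct = c(90, 80, 60, 20, 76, 10),
    cohort = c(rep("contemporary", 4), "contemporary", "captive")
  )
  genomic <- data.frame(
    sample_id = paste0("s", 1:6),
    label = c("wild-type", "wild-type", "wild-type", "admixed", "admixed",
              "admixed")
  )
  rep <- threshold_report(sc, genomic, cfg)
  expect_equal(rep$false_positives, 1)   # s5: morphology wild, genome admixed
  expect_equal(rep$false_negatives, 1)   # s3: genomically wild, score 60
  expect_equal(rep$captive_max_score, 10)
  expect_true(all(rep$table$morph_class %in%
                    c("wild", "domestic", "intermediate")))
  # an all-wild cohort has no errors at all
  sc2 <- data.frame(sample_id = c("a", "b"), score_pct = c(100, 100))
  g2 <- data.frame(sample_id = c("a", "b"), label = "wild-type")
  rep2 <- threshold_report(sc2, g2, cfg)
  expect_equal(rep2$false_positives + rep2$false_negatives, 0)
})

test_that("morphology classification is monotone under trait improvement", {
  rank_of <- c(domestic = 1, intermediate = 2, wild = 3)
  set.seed(121)
  sch <- trait_schema("male")
  vals <- vapply(sch$levels, function(lv) sample(lv[-length(lv)], 1), 0)
  cls <- function(v) {
    classify_morphology(score_individual(make_record("x", "male", v))$score_pct)
  }
  base_rank <- rank_of[cls(vals)]
  for (j in seq_along(vals)) {
    up <- vals
    lv <- sch$levels[[j]]
    up[j] <- max(lv)
    expect_gte(rank_of[cls(up)], base_rank)
  }
})
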