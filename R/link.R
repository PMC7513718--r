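#' Regress the genomic axis on morphology scores
#'
#' Ordinary least squares of a per-sample genomic domesticity axis (oriented
#' PC1 scores, or wild membership coefficients q) on the 0-100 morphology
#' score, quantifying how well external appearance predicts genomic
#' ancestry.  The genomic axis is the response (as when eigenvalues are
#' plotted against scores); for a single predictor R-squared is symmetric
#' in the two variables, so the headline statistic does not depend on the
#' direction.
#'
#' @param scores a score-card data.frame from [score_table()] (needs
#'   `sample_id`, `score_pct`)
#' @param genomic_axis named numeric vector of per-sample axis values
#'   (names = sample ids)
#' @param response_kind `"pc1_scores"` or `"q_scores"`, recorded in the fit
#' @return list of class `wm_regression`: `response_kind`, `n`, `slope`,
#'   `intercept`, `r_squared`, `p_value` (two-sided F test), `rss`, `fit`
#'   (the underlying `lm`).
#' @export
regress_morphology <- function(scores, genomic_axis,
                               response_kind = c("pc1_scores", "q_scores")) {
  response_kind <- match.arg(response_kind)
  common <- intersect(scores$sample_id, names(genomic_axis))
  if (length(common) < 3) stop("need at least 3 paired samples")
  x <- scores$score_pct[match(common, scores$sample_id)]
  y <- unname(genomic_axis[common])
  if (var(x) == 0 || var(y) == 0) {
    stop("zero variance in morphology scores or genomic axis")
  }
  fit <- lm(y ~ x)
  sm <- summary(fit)
  pf_ <- sm$fstatistic
  structure(
    list(response_kind = response_kind, n = length(common),
         slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = sm$r.squared,
         p_value = unname(stats::pf(pf_[1], pf_[2], pf_[3], lower.tail = FALSE)),
         rss = sum(fit$residuals^2), fit = fit),
    class = "wm_regression"
  )
}

#' @export
print.wm_regression <- function(x, ...) {
  cat(sprintf(
    "wm_regression (%s ~ morphology score): n=%d, R^2=%.3f, p=%.3g\n",
    x$response_kind, x$n, x$r_squared, x$p_value))
  invisible(x)
}

#' Trait contributions to the morphological PC1
#'
#' Runs a correlation PCA (columns centred and unit-scaled) on the numeric
#' trait matrix of one sex and reports each trait's percentage contribution
#' to PC1: `100 * loading^2 / sum(loadings^2)`.  A trait is an
#' above-average contributor when its contribution strictly exceeds the
#' expected average `100 / p` for the `p` traits entering the PCA — the
#' usual selection rule for retaining variables that shape a component.
#' Constant (zero-variance) trait columns cannot be scaled and are excluded
#' with a warning; they are reported with contribution 0.
#'
#' @param records list of `trait_record`s
#' @param sex which sex's records/schema to use
#' @return data.frame of class `wm_contributions`: `trait`, `contribution`
#'   (percent, summing to 100 over retained traits), `expected_average`,
#'   `above_average`; attributes `"pct_variance"` (per PC) and `"scores"`
#'   (per-sample PC scores).
#' @export
trait_pca_contributions <- function(records, sex = c("male", "female")) {
  sex <- match.arg(sex)
  recs <- Filter(function(r) r$sex == sex && r$scorable, records)
  if (length(recs) < 2) stop("need at least 2 complete records of sex ", sex)
  X <- do.call(rbind, lapply(recs, `[[`, "traits"))
  rownames(X) <- vapply(recs, `[[`, "", "sample_id")
  vr <- apply(X, 2, var)
  if (any(vr == 0)) {
    warning("constant trait column(s) excluded from PCA: ",
            paste(colnames(X)[vr == 0], collapse = ", "))
  }
  keep <- vr > 0
  pc <- stats::prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  load1 <- setNames(pc$rotation[, 1], rownames(pc$rotation))
  contrib_kept <- 100 * load1^2 / sum(load1^2)
  p <- sum(keep)
  contribution <- setNames(rep(0, ncol(X)), colnames(X))
  contribution[names(contrib_kept)] <- contrib_kept
  out <- data.frame(
    trait = colnames(X), contribution = unname(contribution),
    expected_average = 100 / p,
    above_average = unname(contribution) > 100 / p,
    stringsAsFactors = FALSE
  )
  attr(out, "pct_variance") <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  attr(out, "scores") <- pc$x
  class(out) <- c("wm_contributions", "data.frame")
  out
}

#' Best-subset AIC search over trait predictors
#'
#' Fits an OLS model of the genomic axis on every non-empty subset of the
#' candidate traits (each subset unioned with any forced traits) and ranks
#' the models by AIC, `2 df - 2 logLik`, with the Gaussian maximum-
#' likelihood log-likelihood `-n/2 (log(2 pi RSS/n) + 1)` and
#' `df = n_predictors + 2` (slopes + intercept + residual variance) — the
#' convention of `stats::AIC` on an `lm` fit, reproduced exactly.
#' Categorical traits enter as numeric 0/0.5/1.  Subsets with more than
#' `n - 2` predictors are skipped (no residual degrees of freedom) and
#' noted.
#'
#' Forcing a trait (e.g. female tarsus colour, of particular interest as a
#' putatively introgressed trait) adds it to every candidate subset and
#' also fits it alone.
#'
#' @param genomic_axis named numeric vector (names = sample ids)
#' @param records list of `trait_record`s
#' @param candidate_traits character vector of trait abbreviations to
#'   search over
#' @param forced_traits traits included in every model (default none)
#' @param sex which sex's records to model
#' @param top_n number of top models to print/report (default 5)
#' @return data.frame of class `wm_selection`, sorted by ascending AIC:
#'   `model` (formula text), `predictors`, `df`, `aic`, `r_squared`;
#'   attributes `"top_n"`, `"skipped"` (subsets too large to fit).
#' @export
aic_model_search <- function(genomic_axis, records, candidate_traits,
                             forced_traits = character(),
                             sex = c("male", "female"), top_n = 5L) {
  sex <- match.arg(sex)
  recs <- Filter(function(r) r$sex == sex && r$scorable, records)
  ids <- vapply(recs, `[[`, "", "sample_id")
  common <- intersect(ids, names(genomic_axis))
  recs <- recs[match(common, ids)]
  X <- as.data.frame(do.call(rbind, lapply(recs, `[[`, "traits")))
  all_tr <- union(candidate_traits, forced_traits)
  missing_tr <- setdiff(all_tr, colnames(X))
  if (length(missing_tr)) {
    stop("trait(s) not in the ", sex, " schema/records: ",
         paste(missing_tr, collapse = ", "))
  }
  df_all <- cbind(data.frame(.y = unname(genomic_axis[common])), X[all_tr])
  n <- nrow(df_all)
  if (n < 3) stop("need at least 3 paired samples")

  candidate_traits <- setdiff(candidate_traits, forced_traits)
  subsets <- list()
  for (k in seq_along(candidate_traits)) {
    cmb <- combn(candidate_traits, k, simplify = FALSE)
    subsets <- c(subsets, cmb)
  }
  if (length(forced_traits)) subsets <- c(list(character(0)), subsets)
  models <- lapply(subsets, function(s) union(forced_traits, s))
  models <- models[!duplicated(lapply(models, sort))]

  rows <- list(); skipped <- character(0)
  for (preds in models) {
    if (length(preds) > n - 2) {
      skipped <- c(skipped, paste(preds, collapse = "+"))
      next
    }
    fml <- stats::as.formula(paste(".y ~", paste(preds, collapse = " + ")))
    fit <- lm(fml, data = df_all)
    # AIC from the stated convention (equals stats::AIC for full-rank fits;
    # for aliased predictors the nominal-predictor df still counts, so a
    # redundant trait can never improve the ranking)
    rss <- sum(fit$residuals^2)
    ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
    df <- length(preds) + 2L
    rows[[length(rows) + 1]] <- data.frame(
      model = paste("axis ~", paste(preds, collapse = " + ")),
      predictors = paste(preds, collapse = "+"),
      n_predictors = length(preds),
      df = df,
      aic = 2 * df - 2 * ll,
      r_squared = summary(fit)$r.squared,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) stop("no fittable models (all subsets exceed n - 2 predictors)")
  out <- do.call(rbind, rows)
  out <- out[order(out$aic), ]
  rownames(out) <- NULL
  attr(out, "top_n") <- min(top_n, nrow(out))
  attr(out, "skipped") <- skipped
  attr(out, "n") <- n
  class(out) <- c("wm_selection", "data.frame")
  out
}

#' @export
print.wm_selection <- function(x, ...) {
  k <- attr(x, "top_n") %||% 5L
  cat(sprintf("wm_selection: %d models fitted on n=%d; top %d by AIC:\n",
              nrow(x), attr(x, "n"), k))
  print.data.frame(utils::head(x[, c("model", "df", "aic")], k), digits = 6)
  invisible(x)
}

#' Morphology threshold classification
#'
#' Classifies a morphology score on the management thresholds: `"wild"`
#' when the score is strictly greater than `morph_wild_min` (75), a
#' reliable indicator of a wild-type genomic profile; `"domestic"` when
#' strictly below `morph_domestic_max` (25), the conservative cutoff for
#' identifying domestic chickens; `"intermediate"` otherwise.  Scores
#' exactly at a cutoff are intermediate (the rules are strict
#' inequalities).
#'
#' @param score_pct numeric vector of scores in \[0, 100\]
#' @param cfg a [run_config()] carrying the cutoffs
#' @return character vector of classes
#' @export
classify_morphology <- function(score_pct, cfg = run_config()) {
  stopifnot(all(score_pct >= 0 & score_pct <= 100, na.rm = TRUE))
  ifelse(score_pct > cfg$morph_wild_min, "wild",
         ifelse(score_pct < cfg$morph_domestic_max, "domestic", "intermediate"))
}

#' Cross-tabulate morphology classes against genomic labels
#'
#' Builds the management error-rate report: a false positive is an
#' individual whose morphology class is wild (score above the wild cutoff)
#' but whose genomic label is not wild-type; a false negative is a
#' genomically wild-type individual whose score fails to clear the wild
#' cutoff.  Also reports the maximum score among captive-cohort samples
#' when cohort information is available — the empirical basis for the
#' domestic cutoff.
#'
#' @param scores score-card data.frame from [score_table()]
#' @param genomic data.frame from [classify_genomic()] (`sample_id`,
#'   `label`)
#' @param cfg a [run_config()]
#' @param meta optional sample metadata (for the captive maximum; ignored
#'   if `scores` already carries a `cohort` column)
#' @return list of class `wm_threshold_report`: `table` (per-sample),
#'   `confusion` (morphology class x genomic label counts),
#'   `false_positives`, `false_negatives`, `captive_max_score`, `cutoffs`.
#' @export
threshold_report <- function(scores, genomic, cfg = run_config(), meta = NULL) {
  common <- intersect(scores$sample_id, genomic$sample_id)
  s <- scores[match(common, scores$sample_id), ]
  g <- genomic[match(common, genomic$sample_id), ]
  tab <- data.frame(
    sample_id = common,
    score_pct = s$score_pct,
    morph_class = classify_morphology(s$score_pct, cfg),
    genomic_label = g$label,
    stringsAsFactors = FALSE
  )
  tab$false_positive <- tab$morph_class == "wild" & tab$genomic_label != "wild-type"
  tab$false_negative <- tab$genomic_label == "wild-type" & tab$morph_class != "wild"
  cohort <- s$cohort
  if (is.null(cohort) && !is.null(meta)) {
    cohort <- meta$cohort[match(common, meta$sample_id)]
  }
  captive_max <- if (!is.null(cohort) && any(cohort == "captive", na.rm = TRUE)) {
    max(tab$score_pct[cohort == "captive"], na.rm = TRUE)
  } else {
    NA_real_
  }
  structure(
    list(table = tab,
         confusion = table(morphology = tab$morph_class,
                           genomic = tab$genomic_label),
         false_positives = sum(tab$false_positive),
         false_negatives = sum(tab$false_negative),
         captive_max_score = captive_max,
         cutoffs = c(wild = cfg$morph_wild_min,
                     domestic = cfg$morph_domestic_max)),
    class = "wm_threshold_report"
  )
}

#' @export
print.wm_threshold_report <- function(x, ...) {
  cat(sprintf(
    "wm_threshold_report: cutoffs wild > %g, domestic < %g; FP=%d, FN=%d%s\n",
    x$cutoffs["wild"], x$cutoffs["domestic"],
    x$false_positives, x$false_negatives,
    if (is.na(x$captive_max_score)) "" else
      sprintf("; captive max score %.2f", x$captive_max_score)))
  print(x$confusion)
  invisible(x)
}
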