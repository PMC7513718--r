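# Shared fixture builders and independent oracles for the test suite.
# Oracles are deliberately written as naive re-implementations, separate
# from the package's code paths.

# --- genotype fixtures -------------------------------------------------

toy_meta <- function(n, cohort = "contemporary", prefix = "S") {
  data.frame(
    sample_id = sprintf("%s%02d", prefix, seq_len(n)),
    sex = rep(c("male", "female"), length.out = n),
    locality = "toyland",
    cohort = rep(cohort, length.out = n),
    stringsAsFactors = FALSE
  )
}

toy_loci <- function(L, chrom = "1") {
  data.frame(chrom = rep(chrom, length.out = L), pos = seq_len(L) * 100L,
             ref = "A", alt = "G", stringsAsFactors = FALSE)
}

toy_gm <- function(dosage, cohort = "contemporary", chrom = "1") {
  dosage <- as.matrix(dosage)
  genotype_matrix(dosage, toy_loci(ncol(dosage), chrom),
                  toy_meta(nrow(dosage), cohort))
}

# random polymorphic matrix under HWE at uniform frequencies
random_gm <- function(n, L, seed = 1, miss = 0) {
  set.seed(seed)
  p <- runif(L, 0.2, 0.8)
  d <- matrix(rbinom(n * L, 2, rep(p, each = n)), n, L)
  if (miss > 0) d[matrix(runif(n * L), n, L) < miss] <- NA
  toy_gm(d)
}

# --- trait fixtures ----------------------------------------------------

make_record <- function(sample_id, sex, values, age_class = "adult") {
  sch <- trait_schema(sex)
  stopifnot(length(values) == nrow(sch))
  structure(
    list(sample_id = sample_id, sex = sex, age_class = age_class,
         traits = stats::setNames(as.numeric(values), sch$trait),
         scorable = !anyNA(values), reason = if (anyNA(values)) "missing" else NULL),
    class = "trait_record"
  )
}

# record with a given raw score, greedily spending whole then half points
record_with_raw <- function(sample_id, sex, raw) {
  sch <- trait_schema(sex)
  vals <- numeric(nrow(sch))
  left <- raw
  for (i in seq_len(nrow(sch))) {
    lv <- sort(sch$levels[[i]], decreasing = TRUE)
    pick <- lv[lv <= left][1]
    if (is.na(pick)) pick <- 0
    vals[i] <- pick
    left <- left - pick
  }
  stopifnot(abs(sum(vals) - raw) < 1e-9)
  make_record(sample_id, sex, vals)
}

# --- brute-force QC oracles -------------------------------------------

oracle_locus_filter <- function(dosage, presence_min, maf_min) {
  keep <- logical(ncol(dosage))
  for (l in seq_len(ncol(dosage))) {
    g <- dosage[, l]
    called <- g[!is.na(g)]
    cr <- length(called) / length(g)
    if (length(called) == 0) { keep[l] <- FALSE; next }
    p <- sum(called) / (2 * length(called))
    maf <- min(p, 1 - p)
    keep[l] <- (cr >= presence_min) && (maf >= maf_min)
  }
  keep
}

oracle_r2 <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 2) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])^2
}

# naive fixed-point windowed pruning: inside each window repeatedly find
# the first surviving pair above threshold and drop its later member
oracle_ld_prune <- function(dosage, pos, window, step, r2_max) {
  ord <- order(pos)
  stopifnot(identical(ord, seq_along(pos)))   # single-chromosome fixtures
  alive <- rep(TRUE, ncol(dosage))
  starts <- seq(1, ncol(dosage), by = step)
  for (s in starts) {
    win <- s:min(s + window - 1, ncol(dosage))
    repeat {
      offender <- NULL
      ids <- win[alive[win]]
      if (length(ids) >= 2) {
        prs <- utils::combn(ids, 2)
        for (cc in seq_len(ncol(prs))) {
          r2 <- oracle_r2(dosage[, prs[1, cc]], dosage[, prs[2, cc]])
          if (!is.na(r2) && r2 > r2_max) { offender <- prs[, cc]; break }
        }
      }
      if (is.null(offender)) break
      alive[max(offender)] <- FALSE
    }
  }
  alive
}

# --- population-genetics oracles --------------------------------------

# Hudson Fst estimator from two groups of dosage rows
hudson_fst <- function(d1, d2) {
  n1 <- colSums(!is.na(d1)); n2 <- colSums(!is.na(d2))
  p1 <- colMeans(d1, na.rm = TRUE) / 2
  p2 <- colMeans(d2, na.rm = TRUE) / 2
  ok <- n1 > 1 & n2 > 1 & !is.na(p1) & !is.na(p2)
  p1 <- p1[ok]; p2 <- p2[ok]; n1 <- 2 * n1[ok]; n2 <- 2 * n2[ok]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# simulate a (parent, child) dosage pair sharing one allele IBD per locus
simulate_parent_offspring <- function(p, seed = 1) {
  set.seed(seed)
  L <- length(p)
  parent_a1 <- rbinom(L, 1, p)
  parent_a2 <- rbinom(L, 1, p)
  transmitted <- ifelse(runif(L) < 0.5, parent_a1, parent_a2)
  other <- rbinom(L, 1, p)
  list(parent = parent_a1 + parent_a2, child = transmitted + other)
}

write_min_vcf <- function(path, lines) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    lines
  ), path)
  path
}
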