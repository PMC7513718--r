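#' Configuration for the synthetic-data generator
#'
#' The generator emulates the study design the pipeline was built for: two
#' divergent ancestral allele-frequency pools (wild vs domestic) under the
#' Balding-Nichols drift model, individuals spanning an admixture gradient
#' q in \[0, 1\] (captive farm birds near 0, wild birds near 1, feral birds
#' in between), a small set of historic museum anchors with elevated
#' missingness and near-wild ancestry, and sex-specific categorical traits
#' whose wild-state probability increases with q.
#'
#' Defaults mirror the field situation: 2 historic anchors, 9 captive farm
#' birds, a wild cluster and a feral gradient among free-roamers, drift
#' F = 0.2 between pools, 2% baseline missingness vs 12% for degraded
#' historic DNA (elevated sixfold, but below the 15% sample-exclusion
#' threshold: historic anchors must survive QC to orient the continuum,
#' as museum specimens routinely do once loci are presence-filtered).
#'
#' @param n_loci number of unlinked SNP loci.
#' @param n_wild,n_feral,n_captive,n_historic cohort sizes.
#' @param divergence_F Balding-Nichols drift parameter in (0, 1) between the
#'   wild and domestic ancestral pools.
#' @param q_wild_beta,q_captive_beta length-2 Beta shape parameters for the
#'   wild/historic (near 1) and captive (near 0) ancestry draws.
#' @param feral_q_range interval in \[0, 1\] for uniform feral ancestry.
#' @param historic_missing_rate,base_missing_rate per-call missing
#'   probabilities; historic must be at least the base rate.
#' @param trait_slope_range interval for the per-trait logistic slopes b_t
#'   linking q to the wild-state probability.
#' @param seed integer seed; the whole dataset is reproducible from it.
#'
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_loci = 5000L, n_wild = 20L, n_feral = 20L,
                       n_captive = 9L, n_historic = 2L,
                       divergence_F = 0.2,
                       q_wild_beta = c(19, 1), q_captive_beta = c(1, 19),
                       feral_q_range = c(0.05, 0.95),
                       historic_missing_rate = 0.12,
                       base_missing_rate = 0.02,
                       trait_slope_range = c(4, 8), seed = 1L) {
  counts <- c(n_loci, n_wild, n_feral, n_captive, n_historic)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (divergence_F <= 0 || divergence_F >= 1) stop("divergence_F must be in (0, 1)")
  if (any(c(q_wild_beta, q_captive_beta) <= 0)) {
    stop("degenerate Beta parameters: shapes must be positive")
  }
  if (historic_missing_rate < base_missing_rate) {
    stop("historic_missing_rate must be at least base_missing_rate")
  }
  structure(
    list(n_loci = as.integer(n_loci), n_wild = as.integer(n_wild),
         n_feral = as.integer(n_feral), n_captive = as.integer(n_captive),
         n_historic = as.integer(n_historic), divergence_F = divergence_F,
         q_wild_beta = q_wild_beta, q_captive_beta = q_captive_beta,
         feral_q_range = feral_q_range,
         historic_missing_rate = historic_missing_rate,
         base_missing_rate = base_missing_rate,
         trait_slope_range = trait_slope_range, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a genotype + trait dataset with known truth
#'
#' Generative model: common ancestral frequencies `p0 ~ Uniform(0.05, 0.95)`
#' per locus; pool frequencies `p_wild, p_dom ~ Beta(p0 (1-F)/F,
#' (1-p0)(1-F)/F)` drawn independently (Balding-Nichols); individual i with
#' ancestry `q_i` has genotype at locus l `~ Binomial(2, q_i p_wild,l +
#' (1-q_i) p_dom,l)`.  Ancestry draws per cohort: captive
#' `Beta(q_captive_beta)`, wild and historic `Beta(q_wild_beta)`, feral
#' `Uniform(feral_q_range)`.  Genotype calls are masked missing at the base
#' rate (the historic rate for historic samples, emulating degraded museum
#' DNA).  Sexes are Bernoulli(1/2).  Each binary trait's wild-state
#' probability is `plogis(a_t + b_t q_i)` with `a_t = -b_t/2` (so the
#' flip-point sits mid-gradient) and `b_t ~ Uniform(trait_slope_range)`;
#' three-level traits use an ordered logistic with cutpoints at -1 and +1
#' around the same latent scale.  Historic samples are not scored (museum
#' specimens are too degraded for colour traits).
#'
#' @param cfg a [sim_config()]
#' @return list with elements `genotypes` (a `genotype_matrix`), `traits`
#'   (list of `trait_record`s), `meta` (sample metadata), and `truth`
#'   (list: `samples` with `q_true`, `loci` with `p0`/`p_wild`/`p_dom`,
#'   `traits` with per-sex/trait `a`, `b`).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_wild + cfg$n_feral + cfg$n_captive + cfg$n_historic
  if (n < 2 || cfg$n_loci < 1) stop("need at least 2 samples and 1 locus")

  cohort_of <- c(rep("wild", cfg$n_wild), rep("feral", cfg$n_feral),
                 rep("captive", cfg$n_captive), rep("historic", cfg$n_historic))
  q <- numeric(n)
  q[cohort_of == "wild"] <- rbeta(cfg$n_wild, cfg$q_wild_beta[1], cfg$q_wild_beta[2])
  q[cohort_of == "feral"] <- runif(cfg$n_feral, cfg$feral_q_range[1],
                                   cfg$feral_q_range[2])
  q[cohort_of == "captive"] <- rbeta(cfg$n_captive, cfg$q_captive_beta[1],
                                     cfg$q_captive_beta[2])
  q[cohort_of == "historic"] <- rbeta(cfg$n_historic, cfg$q_wild_beta[1],
                                      cfg$q_wild_beta[2])

  # Balding-Nichols pools
  F <- cfg$divergence_F
  p0 <- runif(cfg$n_loci, 0.05, 0.95)
  shape <- (1 - F) / F
  p_wild <- rbeta(cfg$n_loci, p0 * shape, (1 - p0) * shape)
  p_dom <- rbeta(cfg$n_loci, p0 * shape, (1 - p0) * shape)
  p_wild <- pmin(pmax(p_wild, 1e-4), 1 - 1e-4)
  p_dom <- pmin(pmax(p_dom, 1e-4), 1 - 1e-4)

  pi_mat <- outer(q, p_wild) + outer(1 - q, p_dom)   # n x L expected freq
  dosage <- matrix(rbinom(n * cfg$n_loci, 2L, pi_mat), n, cfg$n_loci)

  miss_rate <- ifelse(cohort_of == "historic", cfg$historic_missing_rate,
                      cfg$base_missing_rate)
  mask <- matrix(runif(n * cfg$n_loci), n, cfg$n_loci) < miss_rate
  dosage[mask] <- NA_integer_

  sample_id <- sprintf("%s%02d", c(wild = "W", feral = "FR", captive = "CP",
                                   historic = "H")[cohort_of],
                       unlist(lapply(table(factor(cohort_of,
                         levels = c("wild", "feral", "captive", "historic"))),
                         seq_len)))
  sex <- ifelse(runif(n) < 0.5, "male", "female")
  meta <- data.frame(
    sample_id = sample_id, sex = sex,
    locality = c(wild = "reserve", feral = "urban", captive = "farm",
                 historic = "museum")[cohort_of],
    cohort = c(wild = "contemporary", feral = "contemporary",
               captive = "captive", historic = "historic")[cohort_of],
    stringsAsFactors = FALSE
  )

  loci <- data.frame(
    chrom = "1", pos = seq_len(cfg$n_loci) * 1000L,
    ref = "A", alt = "G", stringsAsFactors = FALSE
  )
  G <- genotype_matrix(dosage, loci, meta)

  # trait parameters per (sex, trait)
  truth_traits <- do.call(rbind, lapply(c("male", "female"), function(sx) {
    sch <- trait_schema(sx)
    b <- runif(nrow(sch), cfg$trait_slope_range[1], cfg$trait_slope_range[2])
    data.frame(sex = sx, trait = sch$trait,
               n_levels = vapply(sch$levels, length, 1L),
               a = -b / 2, b = b, stringsAsFactors = FALSE)
  }))

  scored <- cohort_of != "historic"
  traits <- lapply(which(scored), function(i) {
    sx <- sex[i]
    tt <- truth_traits[truth_traits$sex == sx, ]
    vals <- vapply(seq_len(nrow(tt)), function(j) {
      eta <- tt$a[j] + tt$b[j] * q[i]
      if (tt$n_levels[j] == 2) {
        as.numeric(runif(1) < plogis(eta))
      } else {
        u <- runif(1)
        if (u < plogis(eta - 1)) 1 else if (u < plogis(eta + 1)) 0.5 else 0
      }
    }, numeric(1))
    structure(
      list(sample_id = sample_id[i], sex = sx, age_class = "adult",
           traits = setNames(vals, tt$trait), scorable = TRUE, reason = NULL),
      class = "trait_record"
    )
  })

  truth <- list(
    samples = data.frame(sample_id = sample_id, cohort = meta$cohort,
                         group = cohort_of, q_true = q,
                         stringsAsFactors = FALSE),
    loci = data.frame(chrom = loci$chrom, pos = loci$pos, p0 = p0,
                      p_wild = p_wild, p_dom = p_dom,
                      stringsAsFactors = FALSE),
    traits = truth_traits
  )
  list(genotypes = G, traits = traits, meta = meta, truth = truth)
}

#' Write a simulated dataset to disk as standard files
#'
#' Emits `genotypes.vcf`, `meta.csv`, `traits.csv`, `truth_samples.csv`,
#' `truth_loci.csv` and `truth_traits.csv` under `out_dir`; the VCF and
#' CSVs are consumable by [read_genotypes()] / [read_traits()] unchanged.
#'
#' @param dataset output of [simulate_dataset()]
#' @param out_dir output directory (created if absent)
#' @return named character vector of the files written, invisibly
#' @export
write_fixture <- function(dataset, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  if (file.access(out_dir, mode = 2) != 0) {
    stop("output directory not writable: ", out_dir)
  }
  paths <- c(
    vcf = file.path(out_dir, "genotypes.vcf"),
    meta = file.path(out_dir, "meta.csv"),
    traits = file.path(out_dir, "traits.csv"),
    truth_samples = file.path(out_dir, "truth_samples.csv"),
    truth_loci = file.path(out_dir, "truth_loci.csv"),
    truth_traits = file.path(out_dir, "truth_traits.csv")
  )
  write_genotypes(dataset$genotypes, paths["vcf"])
  write.csv(dataset$meta, paths["meta"], row.names = FALSE)
  write.csv(traits_to_df(dataset$traits), paths["traits"], row.names = FALSE)
  write.csv(dataset$truth$samples, paths["truth_samples"], row.names = FALSE)
  write.csv(dataset$truth$loci, paths["truth_loci"], row.names = FALSE)
  write.csv(dataset$truth$traits, paths["truth_traits"], row.names = FALSE)
  invisible(paths)
}

# wide per-sex trait table; traits absent from a record's sex schema are NA
traits_to_df <- function(records) {
  all_traits <- unique(c(trait_schema("male")$trait, trait_schema("female")$trait))
  rows <- lapply(records, function(r) {
    row <- as.list(setNames(rep(NA_real_, length(all_traits)), all_traits))
    row[names(r$traits)] <- r$traits
    cbind(data.frame(sample_id = r$sample_id, sex = r$sex,
                     age_class = r$age_class, stringsAsFactors = FALSE),
          as.data.frame(row))
  })
  do.call(rbind, rows)
}
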