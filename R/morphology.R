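#' Sex-specific categorical trait schema
#'
#' The scoring scheme encodes, for each sex, the ordered list of plumage and
#' bare-part traits that distinguish wild-type red junglefowl from domestic
#' chickens, with the allowed score levels per trait.  A wild character
#' state scores 1, a domestic state 0; traits whose colour can be partially
#' wild grant an intermediate 0.5 ("half-point" traits).  The sexes are
#' scored on different schemas because of the species' strong sexual
#' dimorphism: 16 male traits and 10 female traits.
#'
#' Male traits: hackles (Hack), body (Body), tail (Tail), bare parts (BP),
#' tarsus colour (TarC), primaries (Pri), secondaries (Sec), lesser coverts
#' (LC), greater and secondary coverts (GSC), scapulars (S), rump plumes
#' (RP), eye colour (Eye), lappet (Lap), beak (Beak), tarsal spur (TS),
#' white rump feathers (WRF).  Half-points: Body, Tail, Sec, S, Lap, Beak.
#'
#' Female traits: Hack, Body, Tail, BP, TarC, Pri, Sec, LC, GSC, and wattles
#' and comb (WC, wild state = absent).  Half-points: Body, BP, WC.
#'
#' @param sex `"male"` or `"female"`
#' @return data.frame with columns `trait` (abbreviation), `long_name`,
#'   and a list-column `levels` of allowed values.
#' @export
trait_schema <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  half <- c(0, 0.5, 1)
  full <- c(0, 1)
  if (sex == "male") {
    trait <- c("Hack", "Body", "Tail", "BP", "TarC", "Pri", "Sec", "LC",
               "GSC", "S", "RP", "Eye", "Lap", "Beak", "TS", "WRF")
    long_name <- c("Hackles", "Body", "Tail", "Bare Parts", "Tarsus colour",
                   "Primaries", "Secondaries", "Lesser Coverts",
                   "Greater and Secondary Coverts", "Scapulars",
                   "Rump Plumes", "Eye Colour", "Lappet", "Beak",
                   "Tarsal Spur", "White Rump Feathers")
    half_traits <- c("Body", "Tail", "Sec", "S", "Lap", "Beak")
  } else {
    trait <- c("Hack", "Body", "Tail", "BP", "TarC", "Pri", "Sec", "LC",
               "GSC", "WC")
    long_name <- c("Hackles", "Body", "Tail", "Bare Parts", "Tarsus colour",
                   "Primaries", "Secondaries", "Lesser Coverts",
                   "Greater and Secondary Coverts", "Wattles and Comb")
    half_traits <- c("Body", "BP", "WC")
  }
  out <- data.frame(trait = trait, long_name = long_name,
                    stringsAsFactors = FALSE)
  out$levels <- lapply(trait, function(t) if (t %in% half_traits) half else full)
  out
}

#' Maximum raw morphology score for a sex
#' @param sex `"male"` or `"female"`
#' @return 16 for males, 10 for females
#' @export
max_raw_score <- function(sex) nrow(trait_schema(sex))

#' Score one individual on the morphology scheme
#'
#' The raw score is the sum of the individual's trait values; it is
#' normalised by the sex-specific maximum (16 male / 10 female) and
#' expressed as a percentage so the sexes are comparable: individuals with
#' an appearance closer to the wild type score higher along a 0-100
#' continuum.
#'
#' Records with any missing trait are unscorable and return `NULL`
#' (exclusion, not imputation), as are non-adults.
#'
#' @param record a `trait_record` (see [read_traits()])
#' @return a one-row data.frame (`score_card`) with `sample_id`, `sex`,
#'   `raw_score`, `max_score`, `score_pct` (full precision) and
#'   `score_display` (half-up rounding to 2 decimals, as conventionally
#'   printed), or `NULL` if the record is unscorable.
#' @export
score_individual <- function(record) {
  stopifnot(inherits(record, "trait_record"))
  if (!record$sex %in% c("male", "female")) {
    stop("cannot score sample ", record$sample_id, ": unknown sex")
  }
  if (!record$scorable) return(NULL)
  raw <- sum(record$traits)
  mx <- max_raw_score(record$sex)
  pct <- 100 * raw / mx
  data.frame(
    sample_id = record$sample_id, sex = record$sex,
    raw_score = raw, max_score = mx,
    score_pct = pct, score_display = round_half_up(pct, 2),
    stringsAsFactors = FALSE
  )
}

# round-half-up (54.6875 -> 54.69, 15.625 -> 15.63); base round() is
# round-half-even and would print 15.62
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Score a batch of trait records
#'
#' @param records list of `trait_record`s
#' @param meta optional sample-metadata data.frame (adds `cohort` and
#'   `locality` columns and enables the per-cohort summary)
#' @return data.frame of score cards, one row per scorable record, with a
#'   `"summary"` attribute listing counts scored/excluded and per-cohort
#'   min/max/mean.
#' @export
score_table <- function(records, meta = NULL) {
  cards <- lapply(records, score_individual)
  excluded <- vapply(cards, is.null, logical(1))
  out <- do.call(rbind, cards[!excluded])
  if (is.null(out)) {
    out <- data.frame(sample_id = character(), sex = character(),
                      raw_score = numeric(), max_score = numeric(),
                      score_pct = numeric(), score_display = numeric(),
                      stringsAsFactors = FALSE)
  }
  summ <- list(
    n_scored = nrow(out), n_excluded = sum(excluded),
    excluded_ids = vapply(records[excluded], `[[`, "", "sample_id"),
    excluded_reasons = vapply(records[excluded],
                              function(r) r$reason %||% "unscorable", "")
  )
  if (!is.null(meta) && nrow(out) > 0) {
    m <- meta[match(out$sample_id, meta$sample_id), ]
    out$cohort <- m$cohort
    out$locality <- m$locality
    summ$by_cohort <- do.call(rbind, lapply(split(out, out$cohort), function(d) {
      data.frame(cohort = d$cohort[1], n = nrow(d), min = min(d$score_pct),
                 max = max(d$score_pct), mean = mean(d$score_pct))
    }))
    rownames(summ$by_cohort) <- NULL
  }
  attr(out, "summary") <- summ
  out
}
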