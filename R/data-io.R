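#' Pipeline run configuration
#'
#' Collects the thresholds used across the pipeline.  Defaults follow the
#' lenient whole-genome filter regime (presence 0.90, MAF 0.01); the stricter
#' contemporary-only regime uses `locus_presence_min = 0.95, maf_min = 0.05`.
#'
#' @param locus_presence_min minimum fraction of samples with a call at a
#'   locus (0.90 or 0.95).
#' @param maf_min minimum minor-allele frequency (0.01 or 0.05).
#' @param sample_missing_max samples with missingness strictly greater than
#'   this are removed (0.15).
#' @param ld_r2_max pairwise squared genotype correlation above which one
#'   member of a locus pair is pruned (0.5).
#' @param ld_window,ld_step sliding-window size and step, in loci (25 / 10).
#' @param q_wild_min admixture membership coefficient at or above which an
#'   individual is labelled wild-type (0.9).
#' @param morph_wild_min morphology score above which an individual is
#'   classed morphologically wild (75).
#' @param morph_domestic_max morphology score below which an individual is
#'   classed morphologically domestic (25).
#' @param K number of ancestry components in the admixture model.
#' @param seed integer seed for stochastic steps.
#'
#' @return a list of class `run_config`.
#' @export
run_config <- function(locus_presence_min = 0.90, maf_min = 0.01,
                       sample_missing_max = 0.15, ld_r2_max = 0.5,
                       ld_window = 25L, ld_step = 10L,
                       q_wild_min = 0.9, morph_wild_min = 75,
                       morph_domestic_max = 25, K = 2L, seed = 1L) {
  fr <- c(locus_presence_min = locus_presence_min, maf_min = maf_min,
          sample_missing_max = sample_missing_max, q_wild_min = q_wild_min)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (morph_domestic_max >= morph_wild_min) {
    stop("morph_domestic_max must be below morph_wild_min")
  }
  if (ld_step > ld_window) stop("ld_step must not exceed ld_window")
  structure(
    list(locus_presence_min = locus_presence_min, maf_min = maf_min,
         sample_missing_max = sample_missing_max, ld_r2_max = ld_r2_max,
         ld_window = as.integer(ld_window), ld_step = as.integer(ld_step),
         q_wild_min = q_wild_min, morph_wild_min = morph_wild_min,
         morph_domestic_max = morph_domestic_max, K = as.integer(K),
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a sample-metadata table
#'
#' @param path CSV with columns `sample_id`, `sex`, `locality`, `cohort`.
#' @return validated data.frame
#' @export
read_sample_meta <- function(path) {
  validate_sample_meta(read.csv(path, stringsAsFactors = FALSE))
}

#' Read hard-called genotypes from a VCF
#'
#' Reads diploid GT calls into a [genotype_matrix()].  Only biallelic SNP
#' records are retained; multi-allelic and indel records are skipped and the
#' number skipped is reported via `message()` and stored in the
#' `"skipped_records"` attribute.  Positions are kept 1-based as in the VCF.
#' Sample order follows the metadata table.
#'
#' @param vcf_path path to a VCF (v4.x) with a GT FORMAT field.
#' @param meta_path path to the sample-metadata CSV (see
#'   [read_sample_meta()]), or a data.frame already in memory.
#' @return a `genotype_matrix`; missing calls (`./.`) are `NA`.
#' @export
read_genotypes <- function(vcf_path, meta_path) {
  meta <- if (is.data.frame(meta_path)) {
    validate_sample_meta(meta_path)
  } else {
    read_sample_meta(meta_path)
  }
  vcf <- suppressWarnings(VariantAnnotation::readVcf(vcf_path))
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT genotype field: ", vcf_path)

  unknown <- setdiff(colnames(gt), meta$sample_id)
  if (length(unknown)) {
    stop("VCF sample(s) absent from metadata: ", paste(unknown, collapse = ", "))
  }
  meta <- meta[meta$sample_id %in% colnames(gt), , drop = FALSE]
  gt <- gt[, meta$sample_id, drop = FALSE]

  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  alt_list <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt_list)
  alt1 <- rep(NA_character_, length(n_alt))
  alt1[n_alt >= 1] <- as.character(unlist(alt_list))[cumsum(n_alt) - n_alt + 1][n_alt >= 1]
  keep <- n_alt == 1 & nchar(ref) == 1 & nchar(alt1) == 1 &
    ref %in% c("A", "C", "G", "T") & alt1 %in% c("A", "C", "G", "T")
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    message(n_skipped, " non-biallelic-SNP record(s) skipped")
  }

  gt <- gt[keep, , drop = FALSE]
  loci <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(rr))[keep],
    pos = BiocGenerics::start(rr)[keep],
    ref = ref[keep], alt = alt1[keep],
    stringsAsFactors = FALSE
  )
  dos <- gt_to_dosage(gt)
  G <- genotype_matrix(t(dos), loci, meta)
  attr(G, "skipped_records") <- n_skipped
  G
}

# "0/0"->0, "0/1"/"1/0"->1, "1/1"->2, anything with "." -> NA; accepts
# phased "|" separators.
gt_to_dosage <- function(gt) {
  g <- gsub("|", "/", gt, fixed = TRUE)
  out <- matrix(NA_integer_, nrow(g), ncol(g), dimnames = dimnames(g))
  out[g %in% c("0/0")] <- 0L
  out[g %in% c("0/1", "1/0")] <- 1L
  out[g %in% c("1/1")] <- 2L
  bad <- !(g %in% c("0/0", "0/1", "1/0", "1/1")) & !grepl(".", g, fixed = TRUE)
  if (any(bad)) {
    stop("unrecognised GT value(s): ", paste(unique(g[bad]), collapse = ", "))
  }
  out
}

#' Write a genotype matrix to a VCF file
#'
#' Emits a minimal VCFv4.2 file with hard GT calls that round-trips through
#' [read_genotypes()] (dosages, missingness and locus registry preserved
#' exactly).
#'
#' @param G a `genotype_matrix`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_genotypes <- function(G, path) {
  codes <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", n_loci(G), n_samples(G))
  d <- t(G$dosage)
  idx <- !is.na(d)
  gt[idx] <- codes[d[idx] + 1L]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=wildmix",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", G$samples$sample_id), collapse = "\t")
  )
  body <- paste(
    G$loci$chrom, G$loci$pos, ".", G$loci$ref, G$loci$alt, ".", ".", ".", "GT",
    apply(gt, 1L, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a categorical trait table
#'
#' Reads per-individual trait states coded on the sex-specific schema (see
#' [trait_schema()]).  Expected columns: `sample_id`, `sex`, optionally
#' `age_class` (defaults to `"adult"`), then the trait abbreviations for
#' each row's sex.  Each record carries only the traits defined for its sex.
#'
#' A value outside a trait's allowed levels is a hard error naming the trait
#' and sample.  A missing (NA/blank) trait value flags the record as
#' unscorable rather than being imputed, as does a non-adult `age_class`
#' (only adults are scored; juveniles and chicks have unstable plumage).
#'
#' @param csv_path path to the traits CSV, or a data.frame.
#' @param schema optional list with `male`/`female` schemas as returned by
#'   [trait_schema()]; defaults to the standard schema.
#' @return a list of `trait_record` objects.
#' @export
read_traits <- function(csv_path, schema = NULL) {
  df <- if (is.data.frame(csv_path)) {
    csv_path
  } else {
    read.csv(csv_path, stringsAsFactors = FALSE)
  }
  if (!all(c("sample_id", "sex") %in% names(df))) {
    stop("traits table needs sample_id and sex columns")
  }
  if (is.null(df$age_class)) df$age_class <- "adult"
  lapply(seq_len(nrow(df)), function(i) {
    trait_record_from_row(df[i, , drop = FALSE], schema)
  })
}

trait_record_from_row <- function(row, schema = NULL) {
  sex <- as.character(row$sex)
  if (!sex %in% c("male", "female")) {
    stop("sample ", row$sample_id, ": sex must be male or female for scoring")
  }
  sch <- if (is.null(schema)) trait_schema(sex) else schema[[sex]]
  vals <- setNames(rep(NA_real_, nrow(sch)), sch$trait)
  unscorable_reason <- NULL
  if (!identical(as.character(row$age_class), "adult")) {
    unscorable_reason <- paste0("age_class=", row$age_class, " (adults only)")
  }
  for (tr in sch$trait) {
    v <- if (tr %in% names(row)) row[[tr]] else NA
    if (is.character(v) && !nzchar(trimws(v))) v <- NA
    v <- suppressWarnings(as.numeric(v))
    if (is.na(v)) {
      unscorable_reason <- unscorable_reason %||%
        paste0("missing value for trait ", tr)
    } else {
      allowed <- sch$levels[[match(tr, sch$trait)]]
      if (!v %in% allowed) {
        stop("sample ", row$sample_id, ": value ", v, " for trait ", tr,
             " not in allowed levels {", paste(allowed, collapse = ", "), "}")
      }
      vals[[tr]] <- v
    }
  }
  structure(
    list(sample_id = as.character(row$sample_id), sex = sex,
         age_class = as.character(row$age_class), traits = vals,
         scorable = is.null(unscorable_reason),
         reason = unscorable_reason),
    class = "trait_record"
  )
}

#' @export
print.trait_record <- function(x, ...) {
  cat(sprintf("trait_record %s (%s, %s): %s\n", x$sample_id, x$sex,
              x$age_class,
              if (x$scorable) "scorable" else paste("unscorable:", x$reason)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
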