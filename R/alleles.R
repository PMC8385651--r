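#' Read per-sample allele depths from a VCF
#'
#' Parses a VCF (4.x) with per-sample `AD` fields into one observation per
#' site x sample. Multi-allelic records are decomposed into ref-vs-each-alt
#' pairs: a tri-allelic site with `AD = 20,15,5` yields two observations,
#' `(20, 15)` and `(20, 5)`; third alleles never contribute to either depth.
#' Sample names of the form `individual_material_tissue` (as written by
#' [emit_vcf()]) are split into metadata columns; other names are kept
#' verbatim with `NA` metadata.
#'
#' @param vcf_path Path to a VCF file (plain or bgzipped).
#' @return A tibble with `chrom`, `pos`, `ref`, `alt`, `quality`,
#'   `sample_id`, `individual_id`, `material`, `tissue`, `ref_depth`,
#'   `alt_depth`.
#' @export
read_allele_depths <- function(vcf_path) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  fmt <- vcf@gt
  if (nrow(fix) == 0) {
    abort("VCF contains no variant records")
  }
  if (!any(grepl("\\bAD\\b", fmt[, "FORMAT"]))) {
    abort("VCF FORMAT lacks the AD (allele depth) field")
  }
  ad <- vcfR::extract.gt(vcf, element = "AD")
  samples <- colnames(ad)

  per_site <- tibble(
    chrom = fix$CHROM,
    pos = as.numeric(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    quality = suppressWarnings(as.numeric(fix$QUAL)),
    .row = seq_len(nrow(fix))
  )
  long <- tidyr::expand_grid(per_site, sample_id = samples) %>%
    mutate(ad = ad[cbind(.data$.row, match(.data$sample_id, samples))]) %>%
    filter(!is.na(.data$ad), .data$ad != ".")

  # decompose: one record per alt allele, ref depth shared
  out <- long %>%
    mutate(
      alts = strsplit(.data$alt, ",", fixed = TRUE),
      depths = purrr::map(strsplit(.data$ad, ",", fixed = TRUE), as.numeric)
    ) %>%
    tidyr::unnest_longer(col = "alts", indices_to = ".alt_idx") %>%
    mutate(
      ref_depth = purrr::map_dbl(.data$depths, 1),
      alt_depth = purrr::map2_dbl(.data$depths, .data$.alt_idx + 1,
                                  function(d, i) if (length(d) >= i) d[[i]] else 0),
      alt = .data$alts
    ) %>%
    select("chrom", "pos", "ref", "alt", "quality", "sample_id",
           "ref_depth", "alt_depth")

  meta <- parse_sample_ids(unique(out$sample_id))
  out %>%
    left_join(meta, by = "sample_id") %>%
    select("chrom", "pos", "ref", "alt", "quality", "sample_id",
           "individual_id", "material", "tissue", "ref_depth", "alt_depth") %>%
    arrange(.data$chrom, .data$pos, .data$alt, .data$sample_id)
}

parse_sample_ids <- function(sample_id) {
  parts <- stringr::str_split(sample_id, "_")
  ok <- lengths(parts) == 3
  tibble(
    sample_id = sample_id,
    individual_id = ifelse(ok, purrr::map_chr(parts, 1), NA_character_),
    material = ifelse(ok, purrr::map_chr(parts, 2), NA_character_),
    tissue = ifelse(ok, purrr::map_chr(parts, 3), NA_character_)
  )
}

#' Drop low-confidence variant sites
#'
#' Removes observations whose Phred-scaled site quality is strictly below the
#' threshold (default 15, i.e. sites with quality `< 15` are filtered out).
#' Idempotent and order-preserving.
#'
#' @param obs Observation tibble with a `quality` column.
#' @param min_phred Minimum retained Phred quality.
#' @return The filtered tibble.
#' @export
filter_by_quality <- function(obs, min_phred = 15) {
  obs %>% filter(.data$quality >= min_phred)
}

#' Alternative-allele fraction
#'
#' `alt / (ref + alt)`. Errors on zero total depth rather than returning
#' `NaN`, since a fraction from no reads is meaningless.
#'
#' @param ref_depth,alt_depth Nonnegative depth vectors.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @examples
#' allelic_fraction(30, 30) # 0.5
#' @export
allelic_fraction <- function(ref_depth, alt_depth) {
  total <- ref_depth + alt_depth
  if (any(total <= 0)) abort("allelic fraction undefined at zero total depth")
  alt_depth / total
}

#' Call per-site DNA genotypes from allele depths
#'
#' A count-based genotyper for sites already present in the input: a site is
#' \describe{
#'   \item{undetermined}{if total depth `< min_depth`;}
#'   \item{het}{if the alt fraction lies inside `het_band` (the operational
#'     reading of genomic allele frequencies "about 0.5");}
#'   \item{hom_ref / hom_alt}{if the fraction lies outside the band and a
#'     two-sided exact binomial test of the minor-allele count against
#'     `error_rate` does not reject homozygosity at `alpha`;}
#'   \item{undetermined}{otherwise (too many minor reads to be a homozygote,
#'     too skewed to be a clean heterozygote).}
#' }
#'
#' @param obs DNA observation tibble (`ref_depth`, `alt_depth`; a `material`
#'   column, when present, must be `"DNA"`).
#' @param min_depth Minimum total depth for a determinate call.
#' @param het_band Two-element numeric: alt-fraction interval called het.
#' @param error_rate Assumed per-base error rate of minor-allele reads under
#'   homozygosity.
#' @param alpha Rejection level of the homozygosity test.
#' @return The input with `call` (`het`, `hom_ref`, `hom_alt`,
#'   `undetermined`), `fraction` (NA when depth is 0) and `depth` columns.
#' @export
call_genotype_dna <- function(obs, min_depth = 20, het_band = c(0.2, 0.8),
                              error_rate = 0.01, alpha = 0.05) {
  if ("material" %in% names(obs) && any(obs$material != "DNA", na.rm = TRUE)) {
    abort("call_genotype_dna expects DNA observations (found cDNA rows)")
  }
  stopifnot(length(het_band) == 2, het_band[1] < het_band[2])
  total <- obs$ref_depth + obs$alt_depth
  frac <- ifelse(total > 0, obs$alt_depth / total, NA_real_)
  minor <- pmin(obs$ref_depth, obs$alt_depth)

  hom_p <- rep(NA_real_, nrow(obs))
  need <- which(total >= min_depth & !(frac >= het_band[1] & frac <= het_band[2]))
  if (length(need) > 0) {
    key <- paste(minor[need], total[need])
    uniq <- !duplicated(key)
    pv <- vapply(need[uniq], function(i) {
      binom.test(minor[i], total[i], p = error_rate)$p.value
    }, numeric(1))
    hom_p[need] <- pv[match(key, key[uniq])]
  }

  obs$depth <- total
  obs$fraction <- frac
  obs$call <- case_when(
    total < min_depth ~ "undetermined",
    frac >= het_band[1] & frac <= het_band[2] ~ "het",
    hom_p >= alpha & frac < het_band[1] ~ "hom_ref",
    hom_p >= alpha & frac > het_band[2] ~ "hom_alt",
    TRUE ~ "undetermined"
  )
  obs
}
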