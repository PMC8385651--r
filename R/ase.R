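#' Classify allelic expression at heterozygous sites
#'
#' Joins cDNA allele depths to DNA heterozygous calls for the same site and
#' individual and classifies each informative site x tissue record. A site is
#' monoallelic when one allele's transcript dominates (cDNA major-allele
#' fraction at least `mono_threshold`, the operational reading of a
#' transcript frequency "close to 1"), biallelic when both alleles are
#' expressed, and undetermined below `min_depth`.
#'
#' @param rna_obs cDNA observation tibble (`chrom`, `pos`, `ref`, `alt`,
#'   `individual_id`, `tissue`, `ref_depth`, `alt_depth`).
#' @param dna_calls Genotype calls from [call_genotype_dna()] for the same
#'   individuals; only `call == "het"` sites are informative.
#' @param mono_threshold Major-allele cDNA fraction called monoallelic.
#' @param min_depth Minimum cDNA depth for a determinate site call.
#' @return A tibble of site calls with `class` in `biallelic`,
#'   `monoallelic_ref`, `monoallelic_alt`, `undetermined` and the
#'   `cdna_fraction` (alt fraction; NA at zero depth).
#' @export
classify_site_rna <- function(rna_obs, dna_calls, mono_threshold = 0.9,
                              min_depth = 20) {
  key <- c("chrom", "pos", "ref", "alt", "individual_id")
  missing_rna <- setdiff(c(key, "ref_depth", "alt_depth"), names(rna_obs))
  missing_dna <- setdiff(c(key, "call"), names(dna_calls))
  if (length(missing_rna) > 0 || length(missing_dna) > 0) {
    abort(paste0(
      "cannot join cDNA observations to DNA calls; missing column(s): ",
      paste(unique(c(missing_rna, missing_dna)), collapse = ", ")
    ))
  }
  if ("material" %in% names(rna_obs) && any(rna_obs$material != "cDNA", na.rm = TRUE)) {
    abort("classify_site_rna expects cDNA observations")
  }
  stopifnot(mono_threshold > 0.5, mono_threshold <= 1)
  het <- dna_calls %>% filter(.data$call == "het") %>% distinct(across(all_of(key)))
  joined <- rna_obs %>% inner_join(het, by = key)
  total <- joined$ref_depth + joined$alt_depth
  frac <- ifelse(total > 0, joined$alt_depth / total, NA_real_)
  joined$cdna_fraction <- frac
  joined$class <- case_when(
    total < min_depth ~ "undetermined",
    frac >= mono_threshold ~ "monoallelic_alt",
    frac <= 1 - mono_threshold ~ "monoallelic_ref",
    TRUE ~ "biallelic"
  )
  joined
}

#' Aggregate site-level ASE calls to gene x individual calls
#'
#' A gene is called monoallelic for an individual only when the pattern is
#' consistent across tissues: in every tissue with at least one informative
#' (determinate) site, at least `site_agreement` of the informative sites are
#' monoallelic; symmetrically for biallelic. Individuals with fewer than
#' `min_sites` distinct informative sites, or with tissues disagreeing, are
#' undetermined. Phase is not required: sites may be monoallelic for either
#' allele.
#'
#' @param site_calls Output of [classify_site_rna()], with `gene_id`,
#'   `individual_id`, `tissue`, `class` (and optionally `sex`).
#' @param min_sites Minimum distinct informative sites per gene x individual.
#' @param site_agreement Minimum fraction of informative sites in a tissue
#'   that must share the class.
#' @return A tibble with one row per gene x individual: `class`
#'   (`monoallelic`, `biallelic`, `undetermined`), `n_informative_sites`,
#'   `n_tissues_consistent`.
#' @export
aggregate_gene_ase <- function(site_calls, min_sites = 2, site_agreement = 0.8) {
  need <- c("gene_id", "individual_id", "tissue", "class")
  missing <- setdiff(need, names(site_calls))
  if (length(missing) > 0) {
    abort(paste0("site calls lack column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(site_calls) == 0) {
    return(tibble(
      gene_id = character(), individual_id = character(), sex = character(),
      class = character(), n_informative_sites = integer(),
      n_tissues_consistent = integer()
    ))
  }
  has_sex <- "sex" %in% names(site_calls)
  by_tissue <- site_calls %>%
    filter(.data$class != "undetermined") %>%
    group_by(.data$gene_id, .data$individual_id, .data$tissue) %>%
    summarise(
      n_sites = dplyr::n_distinct(.data$pos),
      prop_mono = mean(.data$class %in% c("monoallelic_ref", "monoallelic_alt")),
      prop_bi = mean(.data$class == "biallelic"),
      .groups = "drop"
    )
  keys <- site_calls %>%
    distinct(.data$gene_id, .data$individual_id,
             sex = if (has_sex) .data$sex else NA_character_)
  info_sites <- site_calls %>%
    filter(.data$class != "undetermined") %>%
    group_by(.data$gene_id, .data$individual_id) %>%
    summarise(n_informative_sites = dplyr::n_distinct(.data$pos),
              .groups = "drop")
  agg <- by_tissue %>%
    group_by(.data$gene_id, .data$individual_id) %>%
    summarise(
      n_tissues = dplyr::n(),
      n_mono_tissues = sum(.data$prop_mono >= site_agreement),
      n_bi_tissues = sum(.data$prop_bi >= site_agreement),
      .groups = "drop"
    ) %>%
    left_join(info_sites, by = c("gene_id", "individual_id")) %>%
    mutate(
      class = case_when(
        .data$n_informative_sites < min_sites ~ "undetermined",
        .data$n_mono_tissues == .data$n_tissues ~ "monoallelic",
        .data$n_bi_tissues == .data$n_tissues ~ "biallelic",
        TRUE ~ "undetermined"
      ),
      n_tissues_consistent = case_when(
        .data$class == "monoallelic" ~ .data$n_mono_tissues,
        .data$class == "biallelic" ~ .data$n_bi_tissues,
        TRUE ~ pmax(.data$n_mono_tissues, .data$n_bi_tissues)
      )
    )
  keys %>%
    left_join(agg, by = c("gene_id", "individual_id")) %>%
    mutate(
      class = dplyr::coalesce(.data$class, "undetermined"),
      n_informative_sites = dplyr::coalesce(.data$n_informative_sites, 0L),
      n_tissues_consistent = dplyr::coalesce(.data$n_tissues_consistent, 0L)
    ) %>%
    select("gene_id", "individual_id", "sex", "class",
           "n_informative_sites", "n_tissues_consistent") %>%
    arrange(.data$gene_id, .data$individual_id)
}

#' Test sex association of monoallelic expression across a cohort
#'
#' For each gene, determinate individuals form a 2x2 table of sex against
#' allelic class (monoallelic vs biallelic); undetermined individuals are
#' excluded, not imputed. A one-sided Fisher exact test is run toward the sex
#' with the larger monoallelic proportion, and the gene is labelled
#' `male_associated_ASE` / `female_associated_ASE` when `p < alpha` (after
#' optional Bonferroni correction across genes). The exact test is the
#' appropriate formalization at cohort sizes of ~20 plants.
#'
#' @param ase_calls Gene x individual calls from [aggregate_gene_ase()],
#'   including a `sex` column; at most one call per gene x individual.
#' @param alpha Significance level.
#' @param correction `"none"` (default; small fixed gene panel) or
#'   `"bonferroni"`.
#' @return An object of class `ase_assoc`; see [tidy.ase_assoc()].
#' @examples
#' calls <- tibble::tibble(
#'   gene_id = "g", individual_id = sprintf("i%02d", 1:20),
#'   sex = rep(c("male", "female"), each = 10),
#'   class = rep(c("monoallelic", "biallelic"), each = 10)
#' )
#' tidy(sex_association(calls))
#' @export
sex_association <- function(ase_calls, alpha = 0.05,
                            correction = c("none", "bonferroni")) {
  correction <- arg_match(correction)
  need <- c("gene_id", "individual_id", "sex", "class")
  missing <- setdiff(need, names(ase_calls))
  if (length(missing) > 0) {
    abort(paste0("ASE calls lack column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(ase_calls[, c("gene_id", "individual_id")])) {
    abort("each individual must contribute at most one call per gene")
  }
  per_gene <- ase_calls %>%
    group_by(.data$gene_id) %>%
    summarise(
      n_male_mono = sum(.data$sex == "male" & .data$class == "monoallelic"),
      n_male_bi = sum(.data$sex == "male" & .data$class == "biallelic"),
      n_female_mono = sum(.data$sex == "female" & .data$class == "monoallelic"),
      n_female_bi = sum(.data$sex == "female" & .data$class == "biallelic"),
      n_undetermined = sum(.data$class == "undetermined"),
      .groups = "drop"
    )
  res <- per_gene %>%
    mutate(purrr::pmap_dfr(
      list(.data$n_male_mono, .data$n_male_bi, .data$n_female_mono,
           .data$n_female_bi),
      fisher_one_sided
    ))
  n_tested <- sum(!is.na(res$p_value))
  res$p_adjusted <- if (correction == "bonferroni") {
    pmin(res$p_value * max(n_tested, 1), 1)
  } else {
    res$p_value
  }
  res$label <- dplyr::case_when(
    is.na(res$p_adjusted) | res$p_adjusted >= alpha ~ "none",
    res$direction == "male" ~ "male_associated_ASE",
    TRUE ~ "female_associated_ASE"
  )
  structure(
    list(genes = res, alpha = alpha, correction = correction,
         calls = ase_calls),
    class = "ase_assoc"
  )
}

# One-sided Fisher exact p toward the sex with the larger monoallelic
# proportion. Returns NA p when no determinate individuals remain.
fisher_one_sided <- function(n_male_mono, n_male_bi, n_female_mono, n_female_bi) {
  n_male <- n_male_mono + n_male_bi
  n_female <- n_female_mono + n_female_bi
  if (n_male + n_female == 0) {
    return(tibble(direction = NA_character_, p_value = NA_real_))
  }
  pm <- if (n_male > 0) n_male_mono / n_male else 0
  pf <- if (n_female > 0) n_female_mono / n_female else 0
  direction <- if (pm >= pf) "male" else "female"
  tab <- if (direction == "male") {
    matrix(c(n_male_mono, n_male_bi, n_female_mono, n_female_bi), 2,
           byrow = TRUE)
  } else {
    matrix(c(n_female_mono, n_female_bi, n_male_mono, n_male_bi), 2,
           byrow = TRUE)
  }
  p <- fisher.test(tab, alternative = "greater")$p.value
  tibble(direction = direction, p_value = p)
}

#' @export
print.ase_assoc <- function(x, ...) {
  cat("Sex association of monoallelic expression (one-sided Fisher exact)\n")
  cat(sprintf("  alpha = %g, correction = %s\n", x$alpha, x$correction))
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a sex-association result
#'
#' @param x An `ase_assoc` object from [sex_association()].
#' @param ... Unused.
#' @return One row per gene with the 2x2 counts, the test direction, p-value
#'   and label.
#' @method tidy ase_assoc
#' @export
tidy.ase_assoc <- function(x, ...) {
  x$genes
}

#' @rdname tidy.ase_assoc
#' @return For `glance`: a one-row summary (genes tested, genes labelled,
#'   alpha).
#' @method glance ase_assoc
#' @export
glance.ase_assoc <- function(x, ...) {
  tibble(
    n_genes = nrow(x$genes),
    n_tested = sum(!is.na(x$genes$p_value)),
    n_associated = sum(x$genes$label != "none"),
    alpha = x$alpha,
    correction = x$correction
  )
}

#' Per-gene concordance of DNA heterozygosity and cDNA expression
#'
#' The single-individual analysis comparing genomic and transcriptomic allele
#' patterns: for each gene and tissue, counts how many DNA-heterozygous sites
#' are expressed biallelically versus monoallelically in the cDNA, and
#' reports the majority pattern. In a female all three expressed SDR
#' genes are majority-biallelic; in the male the CLC-like gene is
#' majority-monoallelic while TCP- and MET1-like genes stay biallelic.
#'
#' @param dna_calls Genotype calls for one individual.
#' @param rna_obs cDNA observations for the same individual.
#' @param ... Passed to [classify_site_rna()].
#' @return A tibble per gene x tissue: `n_het_sites`, `n_biallelic`,
#'   `n_monoallelic`, `n_undetermined`, `majority`.
#' @export
compare_wgs_rna_het_sites <- function(dna_calls, rna_obs, ...) {
  ind <- unique(c(dna_calls$individual_id, rna_obs$individual_id))
  ind <- ind[!is.na(ind)]
  if (length(ind) > 1) {
    abort("compare_wgs_rna_het_sites expects data from a single individual")
  }
  site_calls <- classify_site_rna(rna_obs, dna_calls, ...)
  if (nrow(site_calls) == 0) {
    return(tibble(
      gene_id = character(), tissue = character(), n_het_sites = integer(),
      n_biallelic = integer(), n_monoallelic = integer(),
      n_undetermined = integer(), majority = character()
    ))
  }
  site_calls %>%
    group_by(.data$gene_id, .data$tissue) %>%
    summarise(
      n_het_sites = dplyr::n_distinct(.data$pos),
      n_biallelic = sum(.data$class == "biallelic"),
      n_monoallelic = sum(.data$class %in% c("monoallelic_ref", "monoallelic_alt")),
      n_undetermined = sum(.data$class == "undetermined"),
      .groups = "drop"
    ) %>%
    mutate(majority = case_when(
      .data$n_monoallelic > .data$n_biallelic ~ "monoallelic",
      .data$n_biallelic > .data$n_monoallelic ~ "biallelic",
      TRUE ~ "tied"
    ))
}
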