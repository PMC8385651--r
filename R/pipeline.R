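#' Default pipeline configuration
#'
#' Every tunable threshold of the pipeline, with its default, in one nested
#' list. `read_pipeline_config()` overlays a YAML file on these defaults and
#' rejects unknown keys; every run echoes the fully resolved configuration
#' into the output directory for provenance.
#'
#' @param outdir Output directory.
#' @param seed Integer seed governing all randomness.
#' @return A named nested list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(outdir = "sdrase_out", seed = 1) {
  structure(
    list(
      seed = seed,
      outdir = outdir,
      simulate = list(
        n_males = 10, n_females = 10,
        n_het_sites_per_gene = 6,
        wgs_depth_male = 18, wgs_depth_female = 26,
        rna_depth = 100, amplicon_depth = 2000,
        seq_error = 0.005, overdispersion_rho = 0.02,
        n_background_genes = 2000
      ),
      ase = list(
        min_phred = 15,
        dna_min_depth = 20, het_band = c(0.2, 0.8), error_rate = 0.01,
        mono_threshold = 0.9, rna_min_depth = 20,
        min_sites = 2, site_agreement = 0.8,
        alpha = 0.05, correction = "none"
      ),
      hemizygosity = list(
        male_min = 0.3, female_max = 0.1, min_run = 2, expressed_min = 0.1
      ),
      expression = list(
        min_cpm = 8, min_fold = 2, min_mean_cpm = 16
      )
    ),
    class = "pipeline_config"
  )
}

#' Read and validate a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the keys of
#'   [default_pipeline_config()]; unknown keys are rejected.
#' @param seed,outdir Optional overrides taking precedence over the file.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path = NULL, seed = NULL, outdir = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user, parent = "")
  }
  if (!is.null(seed)) cfg$seed <- seed
  if (!is.null(outdir)) cfg$outdir <- outdir
  validate_pipeline_config(cfg)
}

merge_config <- function(base, user, parent) {
  if (is.null(user)) return(base)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0) {
    abort(paste0("unknown configuration key(s): ",
                 paste0(parent, unknown, collapse = ", ")))
  }
  for (k in names(user)) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], user[[k]], paste0(parent, k, "."))
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

validate_pipeline_config <- function(cfg) {
  s <- cfg$simulate
  if (any(unlist(s[c("wgs_depth_male", "wgs_depth_female", "rna_depth",
                     "amplicon_depth")]) <= 0)) {
    abort("configured depths must be > 0")
  }
  if (s$n_males < 0 || s$n_females < 0) abort("cohort sizes must be >= 0")
  a <- cfg$ase
  if (a$alpha <= 0 || a$alpha >= 1) abort("alpha must be in (0, 1)")
  if (a$mono_threshold <= 0.5 || a$mono_threshold > 1) {
    abort("mono_threshold must be in (0.5, 1]")
  }
  structure(cfg, class = "pipeline_config")
}

config_to_truth <- function(cfg) {
  s <- cfg$simulate
  truth_config(
    n_males = s$n_males, n_females = s$n_females,
    n_het_sites_per_gene = s$n_het_sites_per_gene,
    wgs_depth_male = s$wgs_depth_male, wgs_depth_female = s$wgs_depth_female,
    rna_depth = s$rna_depth, amplicon_depth = s$amplicon_depth,
    seq_error = s$seq_error, overdispersion_rho = s$overdispersion_rho,
    n_background_genes = s$n_background_genes,
    seed = cfg$seed
  )
}

#' Run pipeline stages
#'
#' `pipeline_simulate()` generates the synthetic cohort and writes its data
#' files (VCFs, count matrix, coverage tracks, sample sheet, truth tables)
#' into `outdir`. `pipeline_ase()` runs quality filtering, DNA genotyping,
#' site/gene ASE classification and the sex-association test from the
#' amplicon VCF. `pipeline_hemizygosity()` scans the binned WGS coverage for
#' male-specific intervals and overlays RNA coverage.
#' `pipeline_expression()` computes the distance matrix, the per-tissue
#' fold-change screens and the expressed-gene filter. `pipeline_all()` runs
#' everything and writes `summary.json`.
#'
#' All stages are deterministic given `config$seed`, and the resolved
#' configuration is echoed to `config_echo.yaml`.
#'
#' @param config A `pipeline_config` (see [default_pipeline_config()],
#'   [read_pipeline_config()]).
#' @return `pipeline_all()` returns the summary list invisibly; the stage
#'   functions return their main result invisibly.
#' @export
pipeline_simulate <- function(config = default_pipeline_config()) {
  config <- validate_pipeline_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  yaml::write_yaml(unclass(config), out("config_echo.yaml"))

  cohort <- simulate_cohort(config_to_truth(config))
  emit_vcf(bind_rows(
    cohort$dna %>% filter(.data$assay == "amplicon"),
    cohort$rna %>% filter(.data$assay == "amplicon")
  ), out("amplicon.vcf"))
  emit_vcf(cohort$dna %>% filter(.data$assay == "wgs"), out("wgs_dna.vcf"))
  bulk <- cohort$rna %>% filter(.data$assay == "bulk_rna")
  if (nrow(bulk) > 0) emit_vcf(bulk, out("bulk_cdna.vcf"))
  emit_counts(cohort$counts, out("counts.tsv"))
  readr::write_tsv(cohort$libraries, out("libraries.tsv"))
  readr::write_tsv(cohort$amplicon_samples, out("amplicon_samples.tsv"))
  emit_coverage(cohort$wgs_coverage, out("wgs_coverage.tsv"))
  emit_coverage(cohort$rna_coverage, out("rna_coverage.tsv"))
  emit_truth(cohort$truth, out("truth"))
  write_annotation(sdr_genes(), out("sdr_genes.gff3"))
  invisible(cohort)
}

#' @rdname pipeline_simulate
#' @export
pipeline_ase <- function(config = default_pipeline_config()) {
  config <- validate_pipeline_config(config)
  out <- function(f) file.path(config$outdir, f)
  vcf <- out("amplicon.vcf")
  if (!file.exists(vcf)) {
    abort(paste0("missing input ", vcf, "; run pipeline_simulate() first"))
  }
  a <- config$ase
  annotation <- read_annotation(out("sdr_genes.gff3"))
  samples <- readr::read_tsv(out("amplicon_samples.tsv"),
                             show_col_types = FALSE)

  obs <- read_allele_depths(vcf) %>%
    filter_by_quality(min_phred = a$min_phred) %>%
    assign_intervals(annotation, id = "gene_id") %>%
    left_join(samples[, c("sample_id", "sex")], by = "sample_id")

  dna_calls <- obs %>%
    filter(.data$material == "DNA") %>%
    call_genotype_dna(min_depth = a$dna_min_depth, het_band = a$het_band,
                      error_rate = a$error_rate)
  site_ase <- classify_site_rna(
    obs %>% filter(.data$material == "cDNA"), dna_calls,
    mono_threshold = a$mono_threshold, min_depth = a$rna_min_depth
  )
  gene_ase <- aggregate_gene_ase(site_ase, min_sites = a$min_sites,
                                 site_agreement = a$site_agreement)
  assoc <- sex_association(gene_ase, alpha = a$alpha,
                           correction = a$correction)

  readr::write_tsv(dna_calls, out("dna_genotypes.tsv"))
  readr::write_tsv(site_ase, out("site_ase.tsv"))
  readr::write_tsv(gene_ase, out("gene_ase.tsv"))
  readr::write_tsv(tidy(assoc), out("sex_association.tsv"))
  invisible(assoc)
}

#' @rdname pipeline_simulate
#' @export
pipeline_hemizygosity <- function(config = default_pipeline_config()) {
  config <- validate_pipeline_config(config)
  out <- function(f) file.path(config$outdir, f)
  covf <- out("wgs_coverage.tsv")
  if (!file.exists(covf)) {
    abort(paste0("missing input ", covf, "; run pipeline_simulate() first"))
  }
  h <- config$hemizygosity
  cov <- readr::read_tsv(covf, show_col_types = FALSE)
  male <- cov %>% filter(.data$sex == "male") %>% normalize_track()
  female <- cov %>% filter(.data$sex == "female") %>% normalize_track()
  regions <- call_male_specific(male, female, male_min = h$male_min,
                                female_max = h$female_max, min_run = h$min_run)

  rnaf <- out("rna_coverage.tsv")
  overlay <- NULL
  if (file.exists(rnaf) && nrow(regions) > 0) {
    rna <- readr::read_tsv(rnaf, show_col_types = FALSE) %>%
      group_by(.data$library_id) %>%
      dplyr::group_modify(~ normalize_track(.x, reference = "median_nonzero")) %>%
      ungroup()
    overlay <- overlay_expression(regions, rna, expressed_min = h$expressed_min)
    readr::write_tsv(overlay, out("region_expression.tsv"))
  }
  readr::write_lines(
    sprintf("%s\t%d\t%d\tmale_specific_%d\t.\t.", regions$chrom,
            as.integer(regions$start), as.integer(regions$end),
            seq_len(nrow(regions))),
    out("male_specific_regions.bed")
  )
  invisible(list(regions = regions, overlay = overlay))
}

#' @rdname pipeline_simulate
#' @export
pipeline_expression <- function(config = default_pipeline_config()) {
  config <- validate_pipeline_config(config)
  out <- function(f) file.path(config$outdir, f)
  cf <- out("counts.tsv")
  if (!file.exists(cf)) {
    abort(paste0("missing input ", cf, "; run pipeline_simulate() first"))
  }
  e <- config$expression
  counts <- readr::read_tsv(cf, show_col_types = FALSE)
  libs <- readr::read_tsv(out("libraries.tsv"), show_col_types = FALSE)

  d <- spearman_distance(counts, min_mean_cpm = e$min_mean_cpm)
  readr::write_tsv(
    as_tibble(as.data.frame(unclass(d)), rownames = "library_id"),
    out("distance_matrix.tsv")
  )
  degs <- purrr::map(
    split(libs, libs$tissue),
    function(tl) {
      deg_screen(counts,
                 tl$library_id[tl$sex == "male"],
                 tl$library_id[tl$sex == "female"],
                 min_cpm = e$min_cpm, min_fold = e$min_fold)
    }
  )
  for (tissue in names(degs)) {
    readr::write_tsv(degs[[tissue]], out(paste0("deg_", tissue, ".tsv")))
  }

  x <- cpm(counts, tmm_factors(counts))
  sdr_ids <- sdr_genes()$gene_id
  expressed <- rowMeans(x[rownames(x) %in% sdr_ids, , drop = FALSE]) > e$min_cpm
  sdr_expr <- tibble(gene_id = names(expressed), expressed = unname(expressed))
  readr::write_tsv(sdr_expr, out("sdr_gene_expression.tsv"))
  invisible(list(distance = d, degs = degs, sdr_expression = sdr_expr))
}

#' @rdname pipeline_simulate
#' @export
pipeline_all <- function(config = default_pipeline_config()) {
  config <- validate_pipeline_config(config)
  cohort <- pipeline_simulate(config)
  assoc <- pipeline_ase(config)
  hemi <- pipeline_hemizygosity(config)
  expr <- pipeline_expression(config)

  genes <- tidy(assoc)
  summary <- list(
    seed = config$seed,
    n_individuals = nrow(cohort$individuals),
    n_amplicon_samples = nrow(cohort$amplicon_samples),
    n_rna_libraries = nrow(cohort$libraries),
    n_sdr_genes = nrow(sdr_genes()),
    n_expressed_sdr_genes = sum(expr$sdr_expression$expressed),
    n_genes_tested = nrow(genes),
    associated_genes = genes$gene_id[genes$label != "none"],
    labels = setNames(as.list(genes$label), genes$gene_id),
    n_male_specific_regions = nrow(hemi$regions),
    male_specific_bases = sum(hemi$regions$end - hemi$regions$start),
    regions_expressed = if (!is.null(hemi$overlay)) any(hemi$overlay$expressed) else FALSE
  )
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}
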