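#' Write allele-depth observations as VCF 4.2
#'
#' Emits one biallelic record per site with per-sample `GT:AD:DP` fields and
#' the site's Phred-scaled `QUAL`. Sample columns are the distinct
#' `sample_id`s of the input; a sample with zero depth at a site is written
#' as `./.:0,0:0` (assayed, nothing observed). Reading the file back with
#' [read_allele_depths()] reproduces the in-memory depths.
#'
#' @param obs Observation tibble with `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `quality`, `sample_id`, `ref_depth`, `alt_depth` columns, e.g. the `dna`
#'   or `rna` component of [simulate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
emit_vcf <- function(obs, path) {
  need <- c("chrom", "pos", "ref", "alt", "quality", "sample_id",
            "ref_depth", "alt_depth")
  missing <- setdiff(need, names(obs))
  if (length(missing) > 0) {
    abort(paste0("observations lack column(s): ", paste(missing, collapse = ", ")))
  }
  sites <- obs %>%
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt, .data$quality) %>%
    arrange(.data$chrom, .data$pos, .data$alt)
  if (anyDuplicated(sites[, c("chrom", "pos", "ref", "alt")])) {
    abort("conflicting QUAL values for the same site")
  }
  samples <- sort(unique(obs$sample_id))

  cells <- obs %>%
    mutate(
      total = .data$ref_depth + .data$alt_depth,
      gt = case_when(
        .data$ref_depth > 0 & .data$alt_depth > 0 ~ "0/1",
        .data$alt_depth > 0 ~ "1/1",
        .data$ref_depth > 0 ~ "0/0",
        TRUE ~ "./."
      ),
      field = sprintf("%s:%d,%d:%d", .data$gt, as.integer(.data$ref_depth),
                      as.integer(.data$alt_depth), as.integer(.data$total))
    ) %>%
    select("chrom", "pos", "ref", "alt", "sample_id", "field") %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "field",
                       values_fill = "./.:0,0:0")
  body <- sites %>% left_join(cells, by = c("chrom", "pos", "ref", "alt"))
  for (s in setdiff(samples, names(body))) body[[s]] <- "./.:0,0:0"

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sdrase",
    sprintf("##contig=<ID=%s>", sort(unique(sites$chrom))),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  rows <- do.call(paste, c(
    list(
      body$chrom, as.integer(body$pos), ".", body$ref, body$alt,
      format(body$quality, trim = TRUE), "PASS", ".", "GT:AD:DP"
    ),
    lapply(samples, function(s) body[[s]]),
    sep = "\t"
  ))
  readr::write_lines(c(header, rows), path)
  invisible(path)
}

#' Write a gene-by-library count matrix as TSV
#'
#' @param counts Wide tibble: `gene_id` column plus one integer column per
#'   library.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
emit_counts <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Write cohort ground truth as plain-text tables
#'
#' Writes `<prefix>_individuals.tsv`, `<prefix>_sites.tsv` (with the phased
#' Y-haplotype allele), `<prefix>_gene_classes.tsv` and
#' `<prefix>_hemizygous_regions.bed`.
#'
#' @param truth The `truth` component of a [simulate_cohort()] result.
#' @param prefix Path prefix for the output files.
#' @return Named character vector of the written paths, invisibly.
#' @export
emit_truth <- function(truth, prefix) {
  paths <- c(
    individuals = paste0(prefix, "_individuals.tsv"),
    sites = paste0(prefix, "_sites.tsv"),
    gene_classes = paste0(prefix, "_gene_classes.tsv"),
    hemizygous_regions = paste0(prefix, "_hemizygous_regions.bed")
  )
  readr::write_tsv(truth$individuals, paths[["individuals"]])
  readr::write_tsv(truth$sites, paths[["sites"]])
  readr::write_tsv(truth$gene_classes, paths[["gene_classes"]])
  hemi <- truth$hemizygous_regions
  readr::write_lines(
    sprintf("%s\t%d\t%d\t%s\t.\t%s", hemi$chrom, as.integer(hemi$start),
            as.integer(hemi$end), hemi$region_id, hemi$strand),
    paths[["hemizygous_regions"]]
  )
  invisible(paths)
}

#' Write a per-bin coverage track as TSV
#'
#' @param track Coverage tibble with `chrom`, `start`, `end`, `depth` and
#'   sample/library metadata columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
emit_coverage <- function(track, path) {
  readr::write_tsv(track, path)
  invisible(path)
}
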