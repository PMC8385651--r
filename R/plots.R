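#' Plot per-plant allele fractions for a gene, DNA vs cDNA
#'
#' The per-site alternative-allele fraction panel used to illustrate
#' sex-associated ASE: DNA fractions sit near 0.5 at heterozygous sites in
#' both sexes, while male cDNA fractions at a Y-silenced gene collapse
#' toward 0 or 1.
#'
#' @param obs Observation tibble with `individual_id`, `sex`, `material`,
#'   `tissue`, `ref_depth`, `alt_depth` (e.g. from [read_allele_depths()] or
#'   a [simulate_cohort()] component), restricted to one gene.
#' @return A ggplot object.
#' @export
plot_allele_fractions <- function(obs) {
  obs <- obs %>%
    mutate(
      fraction = if_else(.data$ref_depth + .data$alt_depth > 0,
                         .data$alt_depth / (.data$ref_depth + .data$alt_depth),
                         NA_real_),
      assay_label = paste(.data$material, .data$tissue, sep = ": ")
    )
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$individual_id,
                                    y = .data$fraction)) +
    ggplot2::geom_hline(yintercept = c(0.1, 0.5, 0.9), linetype = "dotted",
                        colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$sex), alpha = 0.7) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$assay_label)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "plant", y = "alternative-allele fraction") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot normalized coverage tracks over the scan window
#'
#' @param tracks One or more normalized tracks (long format, `sample_id` or
#'   `library_id` distinguishing them) from [normalize_track()].
#' @param regions Optional interval tibble (e.g. called male-specific
#'   regions) shaded in the background.
#' @return A ggplot object.
#' @export
plot_coverage <- function(tracks, regions = NULL) {
  id_col <- if ("library_id" %in% names(tracks)) "library_id" else "sample_id"
  p <- ggplot2::ggplot(tracks)
  if (!is.null(regions) && nrow(regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = -Inf,
                   ymax = Inf),
      fill = "grey85"
    )
  }
  p +
    ggplot2::geom_step(ggplot2::aes(x = .data$start, y = .data$norm_depth,
                                    colour = .data[[id_col]])) +
    ggplot2::labs(x = "position (bp)", y = "normalized depth",
                  colour = NULL) +
    ggplot2::theme_bw()
}

#' @describeIn sex_association Bar chart of monoallelic vs biallelic counts
#'   by sex per gene.
#' @param object An `ase_assoc` object.
#' @param ... Unused.
#' @method autoplot ase_assoc
#' @export
autoplot.ase_assoc <- function(object, ...) {
  long <- tidy(object) %>%
    select("gene_id", "n_male_mono", "n_male_bi", "n_female_mono",
           "n_female_bi") %>%
    tidyr::pivot_longer(-"gene_id", names_to = "key", values_to = "n") %>%
    mutate(
      sex = if_else(grepl("male_", .data$key) & !grepl("female", .data$key),
                    "male", "female"),
      class = if_else(grepl("mono", .data$key), "monoallelic", "biallelic")
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sex, y = .data$n,
                                     fill = .data$class)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(ggplot2::vars(.data$gene_id)) +
    ggplot2::labs(x = NULL, y = "plants", fill = NULL) +
    ggplot2::theme_bw()
}

#' Heatmap of a Spearman distance matrix
#'
#' @param d A `spearman_dist` matrix from [spearman_distance()].
#' @return A ggplot object.
#' @export
plot_distance_matrix <- function(d) {
  long <- as_tibble(as.data.frame(unclass(d)), rownames = "library_a") %>%
    tidyr::pivot_longer(-"library_a", names_to = "library_b",
                        values_to = "distance")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$library_a, y = .data$library_b,
                                     fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, NA)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "1 - rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
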