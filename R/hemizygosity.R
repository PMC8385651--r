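#' Normalize a binned coverage track
#'
#' Scales per-bin depths so that a diploid single-copy region has expected
#' normalized depth 1. By default the normalizer is the sample's median bin
#' depth (robust because hemizygous bins are a small minority of the scan
#' window); for sparse tracks such as RNA coverage, the median over non-zero
#' bins or an explicit reference depth can be used instead.
#'
#' @param track Tibble with `chrom`, `start`, `end`, `depth` (raw mean depth
#'   per bin) and optional sample metadata.
#' @param reference_depth `NULL` (use `reference` rule), or a positive number.
#' @param reference `"median"` or `"median_nonzero"`; ignored when
#'   `reference_depth` is given.
#' @return The track with `norm_depth` and `normalizer` columns added.
#' @export
normalize_track <- function(track, reference_depth = NULL,
                            reference = c("median", "median_nonzero")) {
  reference <- arg_match(reference)
  stopifnot(all(c("start", "end", "depth") %in% names(track)))
  if (is.null(reference_depth)) {
    reference_depth <- switch(
      reference,
      median = median(track$depth),
      median_nonzero = median(track$depth[track$depth > 0])
    )
  }
  if (!is.finite(reference_depth) || reference_depth <= 0) {
    abort("reference depth must be > 0; supply reference_depth explicitly for sparse tracks")
  }
  track$norm_depth <- track$depth / reference_depth
  track$normalizer <- reference_depth
  track
}

#' Call male-specific (Y-hemizygous) intervals from paired coverage
#'
#' Scans two normalized tracks on an identical bin grid for runs of bins
#' where the male retains one-haplotype coverage (normalized depth at least
#' `male_min`, expected ~0.5 for hemizygous sequence) while the female has
#' essentially none (at most `female_max`). Runs of at least `min_run`
#' consecutive qualifying bins are merged into maximal intervals; shorter
#' runs are treated as noise. Calls are invariant to rescaling both raw
#' tracks by a common library-size factor, since thresholds apply to
#' normalized depth.
#'
#' @param male_track,female_track Normalized tracks from [normalize_track()]
#'   sharing identical bins.
#' @param male_min Minimum male normalized depth per qualifying bin.
#' @param female_max Maximum female normalized depth per qualifying bin.
#' @param min_run Minimum consecutive qualifying bins.
#' @return A tibble of disjoint, sorted intervals with `n_bins` and the mean
#'   normalized depths of both samples.
#' @export
call_male_specific <- function(male_track, female_track, male_min = 0.3,
                               female_max = 0.1, min_run = 2) {
  for (tr in list(male_track, female_track)) {
    if (!"norm_depth" %in% names(tr)) {
      abort("tracks must be normalized first (see normalize_track())")
    }
  }
  same <- nrow(male_track) == nrow(female_track) &&
    all(male_track$chrom == female_track$chrom) &&
    all(male_track$start == female_track$start) &&
    all(male_track$end == female_track$end)
  if (!same) abort("male and female tracks must share identical bins")

  ok <- male_track$norm_depth >= male_min & female_track$norm_depth <= female_max
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- which(runs$values & runs$lengths >= min_run)
  if (length(keep) == 0) {
    return(tibble(
      chrom = character(), start = numeric(), end = numeric(),
      n_bins = integer(), male_mean_depth = numeric(),
      female_mean_depth = numeric()
    ))
  }
  purrr::map_dfr(keep, function(k) {
    i <- starts[k]:ends[k]
    # a run never spans a chromosome boundary on a well-formed grid
    tibble(
      chrom = male_track$chrom[i[1]],
      start = male_track$start[i[1]],
      end = male_track$end[i[length(i)]],
      n_bins = length(i),
      male_mean_depth = mean(male_track$norm_depth[i]),
      female_mean_depth = mean(female_track$norm_depth[i])
    )
  }) %>% arrange(.data$chrom, .data$start)
}

#' Flag expression over called male-specific regions
#'
#' Overlays binned RNA coverage on candidate hemizygous intervals: a region
#' is flagged expressed in a tissue when its mean normalized RNA depth over
#' the region's bins reaches `expressed_min`. Y-specific regions of poplar
#' SDRs are typically transcriptionally silent in the sampled tissues.
#'
#' @param regions Interval tibble from [call_male_specific()].
#' @param rna_tracks Normalized RNA tracks on the same bin grid, long format,
#'   with a `tissue` (or `library_id`) column.
#' @param expressed_min Mean normalized depth flagged as expressed.
#' @return A tibble with one row per region x tissue: `mean_rna_depth`,
#'   `expressed`.
#' @export
overlay_expression <- function(regions, rna_tracks, expressed_min = 0.1) {
  if (nrow(regions) == 0) {
    return(tibble(
      chrom = character(), start = numeric(), end = numeric(),
      tissue = character(), mean_rna_depth = numeric(), expressed = logical()
    ))
  }
  if (!"norm_depth" %in% names(rna_tracks)) {
    abort("RNA tracks must be normalized first (see normalize_track())")
  }
  group_col <- if ("tissue" %in% names(rna_tracks)) "tissue" else "library_id"
  purrr::pmap_dfr(
    regions[, c("chrom", "start", "end")],
    function(chrom, start, end) {
      inside <- rna_tracks$chrom == chrom &
        rna_tracks$start < end & rna_tracks$end > start
      rna_tracks[inside, ] %>%
        group_by(tissue = .data[[group_col]]) %>%
        summarise(mean_rna_depth = mean(.data$norm_depth), .groups = "drop") %>%
        mutate(chrom = chrom, start = start, end = end,
               expressed = .data$mean_rna_depth >= expressed_min) %>%
        select("chrom", "start", "end", "tissue", "mean_rna_depth", "expressed")
    }
  )
}

#' Interval-set Jaccard index
#'
#' Overlap agreement between two interval sets (base-pair intersection over
#' union), used to score recovery of planted hemizygous regions.
#'
#' @param a,b Interval tibbles (`chrom`, `start`, `end`, 0-based half-open).
#' @return A number in `[0, 1]`.
#' @export
interval_jaccard <- function(a, b) {
  if (nrow(a) == 0 && nrow(b) == 0) return(1)
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  len <- function(x) sum(x$end - x$start)
  inter <- 0
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a$start[i], b$start)
    hi <- pmin(a$end[i], b$end)
    inter <- inter + sum(pmax(0, hi - lo)[b$chrom == a$chrom[i]])
  }
  inter / (len(a) + len(b) - inter)
}
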