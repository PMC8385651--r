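#' Build a tibble of genomic intervals
#'
#' Intervals are stored 0-based half-open (`start` inclusive, `end` exclusive),
#' the convention used internally throughout the package. Use
#' [to_one_based()] / [to_zero_based()] to convert at I/O boundaries
#' (GFF3 and VCF are 1-based inclusive, BED is 0-based half-open).
#'
#' @param chrom Character vector of chromosome labels. Labels are opaque: the
#'   reference assembly used here places the poplar sex-determining region on
#'   chromosome 18 even though genetic maps put it on chromosome 19, and the
#'   package makes no attempt to reconcile assemblies.
#' @param start,end Integer positions, 0-based half-open; `end > start >= 0`.
#' @param strand One of `"+"`, `"-"`, `"*"` (also accepts `"forward"`,
#'   `"reverse"`, `"unstranded"`).
#' @return A tibble with columns `chrom`, `start`, `end`, `strand` and a
#'   computed `width` (`end - start`).
#' @examples
#' gintervals("Chr18", 16200000, 16320000)
#' @export
gintervals <- function(chrom, start, end, strand = "*") {
  start <- as.numeric(start)
  end <- as.numeric(end)
  strand <- normalize_strand(strand)
  n <- max(length(chrom), length(start), length(end), length(strand))
  out <- tibble(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(start, n),
    end = rep_len(end, n),
    strand = rep_len(strand, n)
  )
  validate_intervals(out)
  out$width <- out$end - out$start
  out
}

normalize_strand <- function(strand) {
  map <- c(
    "+" = "+", "-" = "-", "*" = "*", "." = "*",
    forward = "+", reverse = "-", unstranded = "*"
  )
  out <- unname(map[as.character(strand)])
  if (anyNA(out)) {
    abort(paste0(
      "invalid strand value(s): ",
      paste(unique(strand[is.na(out)]), collapse = ", ")
    ))
  }
  out
}

validate_intervals <- function(x) {
  stopifnot(is.data.frame(x))
  missing <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(missing) > 0) {
    abort(paste0("interval table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(x$start < 0)) abort("interval start must be >= 0")
  if (any(x$end <= x$start)) abort("interval end must be > start")
  invisible(x)
}

#' Convert between 0-based half-open and 1-based inclusive coordinates
#'
#' Involutive pair: `to_zero_based(to_one_based(x))` returns `x` unchanged.
#'
#' @param x A data frame with `start` and `end` columns.
#' @return `x` with `start`/`end` shifted to the other convention.
#' @export
to_one_based <- function(x) {
  x$start <- x$start + 1
  x
}

#' @rdname to_one_based
#' @export
to_zero_based <- function(x) {
  x$start <- x$start - 1
  x
}

#' Partition an interval into fixed-width bins
#'
#' Produces non-overlapping contiguous bins covering the region, in order.
#' When the region length is not a multiple of `width`, the final bin is kept
#' and truncated at the region end.
#'
#' @param region A one-row data frame with `chrom`, `start`, `end`
#'   (0-based half-open), e.g. from [gintervals()] or [sdr_region()].
#' @param width Positive bin width in bp. The SDR coverage scan uses 200 bp.
#' @return A tibble of bins with a `bin` index column (1-based).
#' @examples
#' nrow(bin_interval(sdr_region(), 200)) # 600
#' @export
bin_interval <- function(region, width) {
  validate_intervals(region)
  if (nrow(region) != 1) abort("region must be a single interval (one row)")
  if (!is.numeric(width) || length(width) != 1 || is.na(width) || width < 1) {
    abort("width must be a positive integer")
  }
  width <- as.numeric(width)
  starts <- seq(region$start, region$end - 1, by = width)
  tibble(
    chrom = region$chrom,
    start = starts,
    end = pmin(starts + width, region$end),
    bin = seq_along(starts)
  )
}

#' Overlap join between positions and intervals
#'
#' Assigns each (chrom, pos) 1-based point to the interval containing it.
#' Used to map variant sites onto annotated genes.
#'
#' @param x A data frame with `chrom` and 1-based `pos` columns.
#' @param annotation An interval table with `chrom`, `start`, `end` (0-based
#'   half-open) and an id column (default `gene_id`).
#' @param id Name of the annotation id column carried into the result.
#' @return `x` with the id column added; positions falling in no interval get
#'   `NA`.
#' @export
assign_intervals <- function(x, annotation, id = "gene_id") {
  validate_intervals(annotation)
  if (!id %in% names(annotation)) abort(paste0("annotation lacks column ", id))
  ann <- annotation[, c("chrom", "start", "end", id)]
  names(ann)[4] <- ".assign_id"
  hit <- purrr::map2_chr(x$chrom, x$pos, function(ch, p) {
    i <- which(ann$chrom == ch & ann$start < p & p <= ann$end)
    if (length(i) == 0) NA_character_ else ann$.assign_id[i[1]]
  })
  x[[id]] <- hit
  x
}

#' The sex-determining region scanned for hemizygosity
#'
#' The peritelomeric SDR of the male reference assembly, 120 kb on Chr18
#' (0-based half-open), which the coverage scan divides into 200-bp bins.
#'
#' @return A one-row interval tibble.
#' @export
sdr_region <- function() {
  gintervals("Chr18", 16200000, 16320000, "*")
}

#' The five annotated SDR genes
#'
#' Gene models present in both sexes of the reference poplar SDR: a T-complex
#' protein subunit (TCP), a chloride channel (CLC), a DNA methyltransferase
#' (MET1), an NB-ARC domain gene, and a gene of unknown function. Coordinates
#' are stored 0-based half-open, converted from their conventional 1-based
#' inclusive spans. Three of the five (TCP, CLC, MET1) are transcribed in the
#' tissues studied; CLC is the gene showing male-specific monoallelic
#' expression.
#'
#' @return A tibble with `gene_id`, `symbol`, `chrom`, `start`, `end`,
#'   `strand`, `width`.
#' @examples
#' sdr_genes()
#' @export
sdr_genes <- function() {
  g <- tibble(
    gene_id = c(
      "PtStettler14.18G127900", "PtStettler14.18G127800",
      "PtStettler14.18G127700", "PtStettler14.18G127600",
      "PtStettler14.18G127500"
    ),
    symbol = c("TCP", "CLC", "MET1", "NB-ARC", "unknown"),
    chrom = "Chr18",
    start = c(16275593, 16268169, 16249745, 16226313, 16214199) - 1,
    end = c(16279859, 16272894, 16259190, 16236215, 16215600),
    strand = c("-", "-", "-", "-", "+")
  )
  g$width <- g$end - g$start
  arrange(g, .data$start)
}
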