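#' Read gene annotations from GFF3 or BED
#'
#' GFF3 coordinates are 1-based inclusive and converted to the package's
#' 0-based half-open convention on load; BED is already 0-based half-open.
#' For GFF3, `ID` and `Name` attributes become `gene_id` and `symbol`; for
#' 6-column BED the `name` field is used for both (BED carries no separate
#' symbol).
#'
#' @param path File path.
#' @param format `"gff3"` or `"bed"`; guessed from the file extension when
#'   omitted.
#' @return An annotation tibble (`gene_id`, `symbol`, `chrom`, `start`, `end`,
#'   `strand`, `width`).
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "bed")) {
  format <- arg_match(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  lines <- readr::read_lines(path)
  keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0) {
    return(tibble(
      gene_id = character(), symbol = character(), chrom = character(),
      start = numeric(), end = numeric(), strand = character(),
      width = numeric()
    ))
  }
  parse_line <- if (format == "gff3") parse_gff3_line else parse_bed_line
  out <- purrr::map(keep, function(i) parse_line(lines[[i]], i))
  out <- bind_rows(out)
  validate_intervals(out)
  if (anyDuplicated(out$gene_id)) abort("duplicate gene_id in annotation")
  out$width <- out$end - out$start
  out
}

parse_gff3_line <- function(line, lineno) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) != 9) {
    abort(sprintf("malformed GFF3 line %d: expected 9 tab-separated fields, got %d",
                  lineno, length(f)))
  }
  start <- suppressWarnings(as.numeric(f[4]))
  end <- suppressWarnings(as.numeric(f[5]))
  if (is.na(start) || is.na(end)) {
    abort(sprintf("malformed GFF3 line %d: non-numeric coordinates", lineno))
  }
  attrs <- parse_gff3_attributes(f[9])
  id <- attrs[["ID"]] %||% abort(sprintf("malformed GFF3 line %d: no ID attribute", lineno))
  tibble(
    gene_id = id,
    symbol = attrs[["Name"]] %||% id,
    chrom = f[1],
    start = start - 1, # 1-based inclusive -> 0-based half-open
    end = end,
    strand = normalize_strand(f[7])
  )
}

parse_gff3_attributes <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(trimws(parts))]
  kv <- strsplit(parts, "=", fixed = TRUE)
  setNames(
    vapply(kv, function(x) utils::URLdecode(trimws(x[2])), character(1)),
    vapply(kv, function(x) trimws(x[1]), character(1))
  )
}

parse_bed_line <- function(line, lineno) {
  f <- strsplit(line, "[ \t]+")[[1]]
  if (length(f) < 6) {
    abort(sprintf("malformed BED line %d: expected 6 fields, got %d", lineno, length(f)))
  }
  start <- suppressWarnings(as.numeric(f[2]))
  end <- suppressWarnings(as.numeric(f[3]))
  if (is.na(start) || is.na(end)) {
    abort(sprintf("malformed BED line %d: non-numeric coordinates", lineno))
  }
  tibble(
    gene_id = f[4], symbol = f[4], chrom = f[1],
    start = start, end = end, strand = normalize_strand(f[6])
  )
}

#' Write gene annotations to GFF3 or BED
#'
#' GFF3 output round-trips exactly through [read_annotation()]; BED output
#' preserves intervals and ids but drops the symbol (6-column BED has a single
#' name field, written from `gene_id`).
#'
#' @param annotation An annotation tibble as returned by [sdr_genes()] or
#'   [read_annotation()].
#' @param path Output file path.
#' @param format `"gff3"` or `"bed"`; guessed from the extension when omitted.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path, format = c("auto", "gff3", "bed")) {
  format <- arg_match(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  validate_intervals(annotation)
  if (format == "gff3") {
    lines <- c(
      "##gff-version 3",
      sprintf(
        "%s\tsdrase\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
        annotation$chrom, as.integer(annotation$start + 1),
        as.integer(annotation$end), annotation$strand,
        annotation$gene_id, annotation$symbol
      )
    )
  } else {
    lines <- sprintf(
      "%s\t%d\t%d\t%s\t.\t%s",
      annotation$chrom, as.integer(annotation$start),
      as.integer(annotation$end), annotation$gene_id, annotation$strand
    )
  }
  readr::write_lines(lines, path)
  invisible(path)
}
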