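#' Construct a genetic map
#'
#' A genetic map converts physical position (bp) to cumulative genetic
#' position (cM). With `knots`, conversion linearly interpolates between
#' them and refuses to extrapolate beyond their range. Without knots the
#' map is uniform at `rate_cM_per_Mb` (default 1 cM/Mb, the genome-wide
#' average rate commonly assumed when no map is available).
#'
#' @param knots Optional data frame with columns `pos_bp` (strictly
#'   increasing) and `cM` (non-decreasing cumulative centimorgans).
#' @param rate_cM_per_Mb Uniform rate used when `knots` is NULL; must be
#'   positive.
#' @param chrom Optional chromosome label the map applies to.
#' @return An object of class `genetic_map`.
#' @export
genetic_map <- function(knots = NULL, rate_cM_per_Mb = 1, chrom = NA_character_) {
  if (!is.null(knots)) {
    knots <- as_tibble(knots)
    stopifnot(all(c("pos_bp", "cM") %in% names(knots)), nrow(knots) >= 2)
    if (any(diff(knots$pos_bp) <= 0))
      abort("genetic_map: knot positions must be strictly increasing")
    if (any(diff(knots$cM) < 0))
      abort("genetic_map: cumulative cM must be non-decreasing")
  }
  if (!is.numeric(rate_cM_per_Mb) || rate_cM_per_Mb <= 0)
    abort("genetic_map: rate_cM_per_Mb must be positive")
  structure(list(knots = knots, rate_cM_per_Mb = rate_cM_per_Mb,
                 chrom = chrom),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  if (is.null(x$knots)) {
    cat(sprintf("<genetic_map> uniform %.4g cM/Mb\n", x$rate_cM_per_Mb))
  } else {
    cat(sprintf("<genetic_map> %d knots, %.0f-%.0f bp, %.3f-%.3f cM\n",
                nrow(x$knots), min(x$knots$pos_bp), max(x$knots$pos_bp),
                min(x$knots$cM), max(x$knots$cM)))
  }
  invisible(x)
}

#' Read a recombination map from a tab-separated file
#'
#' Accepts either a two-column "position(bp) <tab> cM" file or HapMap-style
#' columns (a position column plus a cumulative map column whose name
#' contains "cM" or "Map"; a rate column, if present, is ignored).
#'
#' @param path File path.
#' @param chrom Optional chromosome label stored on the map.
#' @return A `genetic_map`.
#' @export
read_genetic_map <- function(path, chrom = NA_character_) {
  if (!file.exists(path)) abort(paste0("cannot read map file: ", path))
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(d) == 2) {
    knots <- tibble(pos_bp = as.numeric(d[[1]]), cM = as.numeric(d[[2]]))
  } else {
    pos_col <- grep("pos", names(d), ignore.case = TRUE, value = TRUE)
    map_col <- grep("map|cm", names(d), ignore.case = TRUE, value = TRUE)
    map_col <- setdiff(map_col, grep("rate", names(d), ignore.case = TRUE,
                                     value = TRUE))
    if (length(pos_col) == 0 || length(map_col) == 0)
      abort("read_genetic_map: cannot identify position and cM columns")
    knots <- tibble(pos_bp = as.numeric(d[[pos_col[1]]]),
                    cM = as.numeric(d[[map_col[length(map_col)]]]))
  }
  genetic_map(knots = knots, chrom = chrom)
}

#' Genetic length of an interval in centimorgans
#'
#' With map knots, the cumulative cM at each interval end is obtained by
#' linear interpolation and differenced; positions outside the knot range
#' are an error (silent extrapolation would corrupt downstream dating).
#' With a uniform map, length is `bp / 1e6 * rate`.
#'
#' @param intervals Interval tibble (`chrom`, `start`, `end`, 1-based).
#' @param map A [genetic_map()]; default uniform 1 cM/Mb.
#' @return Numeric vector of genetic lengths in cM.
#' @export
#' @examples
#' physical_to_genetic(genomic_interval("chr4", 122400000, 123200000))
physical_to_genetic <- function(intervals, map = genetic_map()) {
  validate_intervals(intervals)
  stopifnot(inherits(map, "genetic_map"))
  if (is.null(map$knots))
    return(interval_length(intervals) / 1e6 * map$rate_cM_per_Mb)
  rng <- range(map$knots$pos_bp)
  if (any(intervals$start < rng[1] | intervals$end > rng[2]))
    abort(sprintf(
      "physical_to_genetic: interval outside map range [%.0f, %.0f]; no extrapolation",
      rng[1], rng[2]))
  at <- function(p) approx(map$knots$pos_bp, map$knots$cM, xout = p,
                           ties = "ordered")$y
  at(intervals$end) - at(intervals$start)
}

# inverse conversion for the simulator: the physical extent (bp) reached by
# travelling `morgans` from `from_bp` in the given direction (+1/-1)
genetic_extent_to_bp <- function(map, from_bp, morgans, direction) {
  stopifnot(inherits(map, "genetic_map"), direction %in% c(-1, 1))
  cm <- morgans * 100
  if (is.null(map$knots)) return(direction * cm / map$rate_cM_per_Mb * 1e6)
  at <- function(p) approx(map$knots$pos_bp, map$knots$cM, xout = p,
                           ties = "ordered")$y
  target <- at(from_bp) + direction * cm
  target <- pmin(pmax(target, min(map$knots$cM)), max(map$knots$cM))
  inv <- approx(map$knots$cM, map$knots$pos_bp, xout = target,
                ties = "ordered")$y
  inv - from_bp
}
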