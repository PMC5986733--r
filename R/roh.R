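#' Extend a run of homozygosity outward from an index variant
#'
#' Starting at a homozygous-alternate index call, the ROH is extended in
#' each direction until the first high-confidence heterozygote. The outer
#' boundary sits one bp inside the flanking het (the het itself is
#' excluded); if no het exists on a side, the boundary clips at the track's
#' first/last marker — there is no evidence beyond the markers, and the
#' `clipped_*` flag records this. Homozygous-reference calls do not break
#' the run: an ROH is about homozygosity, not alt-ness. Missing or filtered
#' sites are invisible to the extension.
#'
#' @param track Marker-track tibble for one sample on one chromosome (from
#'   [high_confidence_filter()]), position-sorted.
#' @param index_pos Position of the index variant; the track must carry a
#'   homozygous-alternate call there.
#' @return One-row tibble: `sample_id`, `chrom`, `index_pos`, `outer_start`,
#'   `outer_end`, `left_het_pos`, `right_het_pos` (NA when absent),
#'   `clipped_left`, `clipped_right`.
#' @export
extend_roh <- function(track, index_pos) {
  stopifnot(is.data.frame(track), nrow(track) > 0)
  if (length(unique(track$chrom)) > 1 || length(unique(track$sample_id)) > 1)
    abort("extend_roh: track must be one sample on one chromosome")
  track <- arrange(track, .data$pos)
  sample_id <- track$sample_id[1]
  i <- which(track$pos == index_pos)
  if (length(i) == 0)
    abort(paste0("index position ", index_pos, " absent from track of ",
                 sample_id))
  i <- i[1]
  if (track$genotype[i] != "hom_alt")
    abort(paste0("sample ", sample_id, " is not homozygous-alternate at ",
                 "index position ", index_pos, " (genotype: ",
                 track$genotype[i], ")"))
  het_pos <- track$pos[track$genotype == "het"]
  left_het <- het_pos[het_pos < index_pos]
  right_het <- het_pos[het_pos > index_pos]
  left_het_pos <- if (length(left_het)) max(left_het) else NA_real_
  right_het_pos <- if (length(right_het)) min(right_het) else NA_real_
  tibble(
    sample_id = sample_id,
    chrom = track$chrom[1],
    index_pos = as.numeric(index_pos),
    outer_start = if (is.na(left_het_pos)) min(track$pos) else left_het_pos + 1,
    outer_end = if (is.na(right_het_pos)) max(track$pos) else right_het_pos - 1,
    left_het_pos = left_het_pos,
    right_het_pos = right_het_pos,
    clipped_left = is.na(left_het_pos),
    clipped_right = is.na(right_het_pos))
}

#' Positions homozygous for the identical alternate allele in all carriers
#'
#' A "shared homozygote" is a marker at which every track has a
#' high-confidence homozygous non-reference call carrying the same
#' alternate allele — the pattern expected of a founder haplotype. A site
#' absent (or missing, or filtered) in any carrier does not qualify.
#'
#' @param tracks Marker-track tibble covering two or more samples on one
#'   chromosome.
#' @param interval One-row interval tibble restricting the search.
#' @return Sorted numeric vector of positions.
#' @export
shared_homozygote_sites <- function(tracks, interval) {
  stopifnot(is.data.frame(tracks))
  if (length(unique(tracks$chrom)) > 1)
    abort("shared_homozygote_sites: tracks span multiple chromosomes")
  k <- length(unique(tracks$sample_id))
  if (k < 2) abort("shared_homozygote_sites: need at least 2 tracks")
  validate_intervals(interval)
  hom <- tracks |>
    filter(.data$pos >= interval$start, .data$pos <= interval$end,
           .data$genotype == "hom_alt")
  if (nrow(hom) == 0) return(numeric(0))
  hom |>
    group_by(.data$pos) |>
    summarise(n_samp = dplyr::n_distinct(.data$sample_id),
              n_allele = dplyr::n_distinct(.data$hom_allele),
              .groups = "drop") |>
    filter(.data$n_samp == k, .data$n_allele == 1) |>
    pull(.data$pos) |>
    sort()
}

#' Trim an outer ROH back to the first shared homozygote
#'
#' The outer boundaries from [extend_roh()] are pulled inward to the
#' outermost shared-homozygote marker they contain, anchoring the trimmed
#' interval on evidence every carrier shares. If no shared homozygote other
#' than the index variant lies inside, the result degenerates to the
#' single-point interval at the index and `degenerate` is flagged.
#'
#' @param outer One-row tibble from [extend_roh()].
#' @param tracks Marker tracks for all carriers (used to locate shared
#'   homozygotes inside the outer interval).
#' @return `outer` with `trimmed_start`, `trimmed_end`,
#'   `left_shared_hom_pos`, `right_shared_hom_pos`, `degenerate` appended.
#' @export
trim_to_shared <- function(outer, tracks) {
  stopifnot(nrow(outer) == 1)
  shared <- shared_homozygote_sites(
    tracks, genomic_interval(outer$chrom, outer$outer_start, outer$outer_end))
  anchors <- setdiff(shared, outer$index_pos)
  degenerate <- length(anchors) == 0
  pts <- c(shared, outer$index_pos)
  mutate(outer,
         trimmed_start = min(pts),
         trimmed_end = max(pts),
         left_shared_hom_pos = if (degenerate) NA_real_ else min(shared),
         right_shared_hom_pos = if (degenerate) NA_real_ else max(shared),
         degenerate = degenerate)
}

#' Delimit and trim ROHs for every carrier
#'
#' Runs [extend_roh()] then [trim_to_shared()] for each sample in `tracks`,
#' the per-carrier half of the shared-haplotype procedure.
#'
#' @param tracks Marker tracks for all carriers on one chromosome.
#' @param index_pos Index-variant position (homozygous-alternate in every
#'   carrier).
#' @return Tibble with one ROH-region row per carrier.
#' @export
roh_regions <- function(tracks, index_pos) {
  tracks |>
    dplyr::group_split(.data$sample_id) |>
    map_dfr(~ trim_to_shared(extend_roh(.x, index_pos), tracks))
}

#' Intersect trimmed ROH regions into the shared haplotype
#'
#' The shared haplotype is the intersection of all trimmed per-carrier
#' regions: maximum of the trimmed starts to minimum of the trimmed ends.
#' Since every region contains the index position the intersection is
#' non-empty; an empty one indicates corrupted inputs and is an error.
#'
#' @param regions ROH-region tibble from [roh_regions()].
#' @param tracks Marker tracks (to count supporting shared homozygotes
#'   inside the result).
#' @return One-row tibble: `chrom`, `start`, `end`, `n_samples`,
#'   `n_shared_hom_support`, `sample_ids` (comma-joined).
#' @export
intersect_regions <- function(regions, tracks) {
  stopifnot(is.data.frame(regions), nrow(regions) >= 2)
  if (length(unique(regions$chrom)) > 1)
    abort("intersect_regions: regions span multiple chromosomes")
  start <- max(regions$trimmed_start)
  end <- min(regions$trimmed_end)
  if (start > end)
    abort("intersect_regions: empty intersection (regions do not share the index position)")
  interval <- genomic_interval(regions$chrom[1], start, end)
  support <- shared_homozygote_sites(tracks, interval)
  mutate(interval,
         n_samples = nrow(regions),
         n_shared_hom_support = length(support),
         sample_ids = paste(sort(regions$sample_id), collapse = ","))
}
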