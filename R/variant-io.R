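#' Read genotype calls from a multi-sample VCF
#'
#' Parses a VCF 4.x file (plain or bgzipped) into a long tibble with one row
#' per sample per record. Genotypes are classified by zygosity
#' (`hom_ref` / `het` / `hom_alt` / `missing`); allele indices are kept so
#' multi-allelic sites retain allele identity, and `hom_allele` records the
#' alternate base a homozygous-alt genotype carries (used by the
#' shared-homozygote test). Half-calls and any genotype containing a missing
#' allele are treated as `missing`. Per-sample `DP` is preferred for depth;
#' the site-level `INFO/DP` is the fallback, and a missing depth is recorded
#' as 0; `dp_source` says which was used.
#'
#' @param path Path to a VCF file (optionally bgzip-compressed).
#' @param samples Optional character vector restricting to these sample IDs;
#'   an unknown ID is an error listing the samples present.
#' @return Tibble with columns `sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `genotype`, `allele1`, `allele2`, `hom_allele`, `depth`, `qual`,
#'   `var_class`, `dp_source`.
#' @export
read_vcf <- function(path, samples = NULL) {
  if (!file.exists(path)) abort(paste0("cannot read VCF file: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  available <- colnames(v@gt)[-1]
  if (is.null(samples)) samples <- available
  missing_ids <- setdiff(samples, available)
  if (length(missing_ids) > 0) {
    abort(paste0("sample(s) not in VCF header: ",
                 paste(missing_ids, collapse = ", "),
                 "; available: ", paste(available, collapse = ", ")))
  }
  fix <- v@fix
  n_rec <- nrow(fix)
  chrom <- as.character(fix[, "CHROM"])
  pos <- as.numeric(fix[, "POS"])
  ref <- as.character(fix[, "REF"])
  alt <- as.character(fix[, "ALT"])
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  var_class <- classify_variant(ref, alt)

  gt_mat <- vcfR::extract.gt(v, element = "GT")
  has_dp_fmt <- any(grepl("(^|:)DP(:|$)", v@gt[, "FORMAT"]))
  dp_mat <- if (has_dp_fmt) {
    suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  } else NULL
  info_dp <- site_info_dp(fix[, "INFO"])

  map_dfr(samples, function(s) {
    gt_raw <- gt_mat[, s]
    cls <- classify_genotype(gt_raw, alt)
    dp <- if (!is.null(dp_mat)) dp_mat[, s] else rep(NA_real_, n_rec)
    dp_source <- ifelse(!is.na(dp), "sample",
                        ifelse(!is.na(info_dp), "site", "none"))
    dp <- ifelse(!is.na(dp), dp, ifelse(!is.na(info_dp), info_dp, 0))
    tibble(sample_id = s, chrom = chrom, pos = pos, ref = ref, alt = alt,
           genotype = cls$genotype, allele1 = cls$allele1,
           allele2 = cls$allele2, hom_allele = cls$hom_allele,
           depth = as.numeric(dp), qual = qual, var_class = var_class,
           dp_source = dp_source)
  })
}

# snv iff ref and every alt allele are single bases
classify_variant <- function(ref, alt) {
  alt_list <- strsplit(alt, ",", fixed = TRUE)
  vapply(seq_along(ref), function(i) {
    a <- alt_list[[i]]
    if (any(is.na(a)) || is.na(ref[i])) return("other")
    if (!all(grepl("^[ACGTNacgtn]+$", c(ref[i], a)))) return("other")
    if (nchar(ref[i]) == 1L && all(nchar(a) == 1L)) "snv" else "indel"
  }, character(1))
}

classify_genotype <- function(gt_raw, alt) {
  alt_list <- strsplit(alt, ",", fixed = TRUE)
  n <- length(gt_raw)
  genotype <- rep("missing", n)
  allele1 <- rep(NA_integer_, n)
  allele2 <- rep(NA_integer_, n)
  hom_allele <- rep(NA_character_, n)
  parts <- strsplit(sub(":.*$", "", gt_raw %||% "."), "[/|]")
  for (i in seq_len(n)) {
    p <- parts[[i]]
    if (length(p) != 2L || any(p == ".") || any(is.na(p)) ||
        any(!grepl("^[0-9]+$", p))) next
    a <- as.integer(p)
    allele1[i] <- a[1]; allele2[i] <- a[2]
    if (a[1] == 0L && a[2] == 0L) genotype[i] <- "hom_ref"
    else if (a[1] == a[2]) {
      genotype[i] <- "hom_alt"
      hom_allele[i] <- alt_list[[i]][a[1]]
    } else genotype[i] <- "het"
  }
  list(genotype = genotype, allele1 = allele1, allele2 = allele2,
       hom_allele = hom_allele)
}

site_info_dp <- function(info) {
  m <- regmatches(info, regexpr("(?:^|;)DP=([0-9]+)", info))
  out <- rep(NA_real_, length(info))
  hit <- lengths(regmatches(info, gregexpr("(?:^|;)DP=[0-9]+", info))) > 0
  out[hit] <- as.numeric(sub("^;?DP=", "", m))
  out
}

#' Reduce calls to a high-confidence marker track
#'
#' Applies the marker-confidence criterion used for haplotype analysis:
#' only non-indel SNVs with depth at or above `min_depth` (default 10x)
#' and a called (non-missing) genotype are retained. The result is a
#' position-sorted track for one sample on one chromosome; it is the input
#' every ROH operation consumes. The filter is idempotent.
#'
#' @param calls Genotype-call tibble (one sample, one chromosome), as from
#'   [read_vcf()].
#' @param min_depth Minimum read depth; the boundary is inclusive (depth 10
#'   passes at the default).
#' @return The retained calls, sorted by position.
#' @export
high_confidence_filter <- function(calls, min_depth = 10) {
  stopifnot(is.data.frame(calls))
  if (nrow(calls) == 0) return(as_tibble(calls))
  if (length(unique(calls$chrom)) > 1)
    abort("high_confidence_filter: calls span multiple chromosomes")
  if (length(unique(calls$sample_id)) > 1)
    abort("high_confidence_filter: calls span multiple samples")
  calls |>
    filter(.data$var_class == "snv",
           .data$depth >= min_depth,
           .data$genotype != "missing") |>
    arrange(.data$pos)
}

#' High-confidence marker tracks for every sample
#'
#' Convenience wrapper applying [high_confidence_filter()] per sample (the
#' calls must already be on a single chromosome), returning one long tibble.
#'
#' @inheritParams high_confidence_filter
#' @return Filtered, position-sorted tibble covering all samples.
#' @export
marker_tracks <- function(calls, min_depth = 10) {
  if (length(unique(calls$chrom)) > 1)
    abort("marker_tracks: calls span multiple chromosomes")
  calls |>
    dplyr::group_split(.data$sample_id) |>
    map_dfr(high_confidence_filter, min_depth = min_depth)
}

#' Tally what the confidence filter removed
#'
#' @inheritParams high_confidence_filter
#' @return Tibble of counts per removal reason (plus `retained`), per sample.
#' @export
filter_tally <- function(calls, min_depth = 10) {
  calls |>
    mutate(reason = dplyr::case_when(
      .data$var_class != "snv" ~ "not_snv",
      .data$genotype == "missing" ~ "missing_genotype",
      .data$depth < min_depth ~ "low_depth",
      TRUE ~ "retained")) |>
    dplyr::count(.data$sample_id, .data$reason, name = "n_calls")
}
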