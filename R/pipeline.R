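#' Run the shared-haplotype pipeline end to end
#'
#' Orchestrates the full founder-haplotype analysis: read the VCF, reduce
#' each carrier to its high-confidence marker track, extend the ROH from
#' the index variant to the first heterozygote, trim back to the first
#' shared homozygote, intersect across carriers, convert the shared
#' interval to genetic length, and estimate the founder age with both
#' estimators (plus a parametric-bootstrap CI when requested). Every
#' carrier must be homozygous-alternate at the index position; a carrier
#' that is not is a hard error naming the sample.
#'
#' @param vcf Path to a multi-sample VCF.
#' @param index_chrom,index_pos Locus of the index variant.
#' @param samples Optional carrier sample IDs (default: all samples in the
#'   VCF); at least two are required.
#' @param map A [genetic_map()] (default uniform 1 cM/Mb).
#' @param min_depth Marker-confidence depth threshold (default 10).
#' @param gene_bed Optional BED of gene intervals to report overlaps with
#'   the shared haplotype.
#' @param ci Compute a parametric-bootstrap CI for each age estimate.
#' @param n_sims,seed Bootstrap replicates and seed (used only with `ci`).
#' @param out_dir Optional directory; when given, per-sample ROH BED,
#'   shared-haplotype BED and a JSON report are written there.
#' @return A `share_report` object; see [tidy.share_report()].
#' @export
run_share_pipeline <- function(vcf, index_chrom, index_pos, samples = NULL,
                               map = genetic_map(), min_depth = 10,
                               gene_bed = NULL, ci = FALSE, n_sims = 1000,
                               seed = 1, out_dir = NULL) {
  calls <- read_vcf(vcf, samples) |>
    filter(.data$chrom == index_chrom)
  if (nrow(calls) == 0)
    abort(paste0("no calls on ", index_chrom, " in ", vcf))
  carrier_ids <- unique(calls$sample_id)
  if (length(carrier_ids) < 2)
    abort("run_share_pipeline: need at least 2 carrier samples")

  tally <- filter_tally(calls, min_depth = min_depth)
  tracks <- marker_tracks(calls, min_depth = min_depth)
  regions <- roh_regions(tracks, index_pos)
  shared <- intersect_regions(regions, tracks)

  length_bp <- interval_length(shared)
  length_cM <- physical_to_genetic(shared, map)
  k <- length(carrier_ids)
  ages <- list(
    length_inversion = if (ci)
      bootstrap_age_ci(length_cM, k = k, method = "length_inversion",
                       n_sims = n_sims, seed = seed)
    else estimate_generations(length_cM, k = k, method = "length_inversion"),
    model_inversion = if (ci)
      bootstrap_age_ci(length_cM, k = k, method = "model_inversion",
                       n_sims = n_sims, seed = seed)
    else estimate_generations(length_cM, k = k, method = "model_inversion"))

  genes <- if (!is.null(gene_bed))
    genes_in_interval(read_bed(gene_bed), shared[, c("chrom", "start", "end")])

  report <- structure(list(
    shared = shared,
    regions = regions,
    length_bp = length_bp,
    length_cM = length_cM,
    length_label = format_bp(length_bp),
    ages = ages,
    genes = genes,
    filter_tally = tally,
    config = list(vcf = vcf, index_chrom = index_chrom,
                  index_pos = index_pos, samples = carrier_ids,
                  min_depth = min_depth,
                  cM_per_Mb = if (is.null(map$knots)) map$rate_cM_per_Mb
                              else NA_real_,
                  map_knots = if (is.null(map$knots)) 0L
                              else nrow(map$knots),
                  ci = ci, n_sims = if (ci) n_sims else NA_integer_,
                  seed = if (ci) seed else NA_integer_),
    version = as.character(packageVersion("founderhap"))),
    class = "share_report")

  if (!is.null(out_dir)) write_share_outputs(report, out_dir)
  report
}

write_share_outputs <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  roh_bed <- bind_rows(
    report$regions |>
      mutate(start = .data$outer_start, end = .data$outer_end,
             name = paste0(.data$sample_id, "_outer")),
    report$regions |>
      mutate(start = .data$trimmed_start, end = .data$trimmed_end,
             name = paste0(.data$sample_id, "_trimmed"))) |>
    select(dplyr::all_of(c("chrom", "start", "end", "name")))
  write_bed(roh_bed, file.path(out_dir, "roh_regions.bed"))
  write_bed(report$shared |> mutate(name = "shared_haplotype") |>
              select(dplyr::all_of(c("chrom", "start", "end", "name"))),
            file.path(out_dir, "shared_haplotype.bed"))
  write_report(report, file.path(out_dir, "share_report.json"))
  invisible(out_dir)
}

#' Serialise a pipeline report to JSON
#'
#' The JSON round-trips losslessly enough to be diffed: identical inputs
#' (and seed, when a bootstrap is involved) give byte-identical files.
#'
#' @param report A `share_report` or `filter_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  x <- unclass(report)
  x$ages <- lapply(x$ages, function(a) as.list(tidy(a)))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @export
print.share_report <- function(x, ...) {
  cat(sprintf("<share_report> %d carriers; shared haplotype %s:%.0f-%.0f (%s, %.4g cM)\n",
              x$shared$n_samples, x$shared$chrom, x$shared$start,
              x$shared$end, x$length_label, x$length_cM))
  cat(sprintf("  supported by %d shared homozygous markers\n",
              x$shared$n_shared_hom_support))
  for (a in x$ages)
    cat(sprintf("  %s: %.4g generations%s\n", a$method, a$g,
                if (!is.na(a$ci_low))
                  sprintf(" [%.4g, %.4g]", a$ci_low, a$ci_high) else ""))
  if (!is.null(x$genes) && nrow(x$genes) > 0)
    cat("  genes in shared interval:",
        paste(x$genes$name, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a share report into one row per carrier ROH
#'
#' @param x A `share_report`.
#' @param ... Unused.
#' @return Tibble of per-carrier outer and trimmed ROH boundaries with
#'   boundary evidence positions.
#' @exportS3Method
tidy.share_report <- function(x, ...) as_tibble(x$regions)

#' @rdname tidy.share_report
#' @exportS3Method
glance.share_report <- function(x, ...) {
  tibble(chrom = x$shared$chrom, start = x$shared$start,
         end = x$shared$end, length_bp = x$length_bp,
         length_label = x$length_label, length_cM = x$length_cM,
         n_samples = x$shared$n_samples,
         n_shared_hom_support = x$shared$n_shared_hom_support,
         g_length_inversion = x$ages$length_inversion$g,
         g_model_inversion = x$ages$model_inversion$g)
}

#' Run the recessive-model filtering pipeline
#'
#' Applies [apply_recessive_model()] then [panel_count_filter()] to an
#' annotated trio variant table, with per-stage tallies and a removal log.
#'
#' @param variants Path to a TSV (see [read_variant_table()]) or an
#'   already-read tibble.
#' @param exac_hom_max,kg_hom_max Panel homozygote-count thresholds
#'   (exclusive; defaults 20 and 10).
#' @param lenient_parents Passed to [apply_recessive_model()].
#' @param out_dir Optional directory for candidate and removal-log TSVs.
#' @return A `filter_report` with the final `candidate_set`, tallies and
#'   config echo.
#' @export
run_filter_pipeline <- function(variants, exac_hom_max = 20, kg_hom_max = 10,
                                lenient_parents = FALSE, out_dir = NULL) {
  d <- if (is.character(variants)) read_variant_table(variants)
       else validate_variant_table(variants)
  cs <- apply_recessive_model(d, lenient_parents = lenient_parents) |>
    panel_count_filter(exac_hom_max = exac_hom_max, kg_hom_max = kg_hom_max)
  tallies <- glance(cs) |>
    mutate(n_input = nrow(d),
           n_candidate_variants = nrow(tidy(cs)))
  report <- structure(list(
    candidates = cs,
    tallies = tallies,
    removal_log = cs$removed |>
      select(dplyr::any_of(c("chrom", "pos", "ref", "alt", "gene",
                             "reason"))),
    config = list(exac_hom_max = exac_hom_max, kg_hom_max = kg_hom_max,
                  lenient_parents = lenient_parents),
    version = as.character(packageVersion("founderhap"))),
    class = "filter_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(tidy(cs), file.path(out_dir, "candidates.tsv"))
    readr::write_tsv(report$removal_log, file.path(out_dir, "removal_log.tsv"))
  }
  report
}

#' @export
print.filter_report <- function(x, ...) {
  t <- x$tallies
  cat(sprintf(paste0("<filter_report> %d variants in -> %d homozygous ",
                     "candidate(s), %d compound-het pair(s); %d removed, ",
                     "%d unresolved\n"),
              t$n_input, t$n_homozygous, t$n_compound_het_pairs,
              t$n_removed, t$n_unresolved))
  invisible(x)
}

#' @exportS3Method
tidy.filter_report <- function(x, ...) tidy(x$candidates)

#' @exportS3Method
glance.filter_report <- function(x, ...) x$tallies
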