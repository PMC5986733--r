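#' Read an annotated trio variant table
#'
#' Expects a TSV with one row per variant carrying trio genotypes and
#' reference-panel homozygote counts. Required columns: `chrom`, `pos`,
#' `ref`, `alt`, `gene`, `proband_gt`, `mother_gt`, `father_gt`,
#' `exac_hom`, `kg_hom`; optional: `cds_pos`, `protein_change`. Genotypes
#' are the zygosity labels `hom_ref`/`het`/`hom_alt`/`missing`.
#'
#' @param path TSV file path.
#' @return Tibble, with an error naming any missing columns.
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read variant table: ", path))
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_variant_table(d)
}

required_variant_cols <- c("chrom", "pos", "ref", "alt", "gene",
                           "proband_gt", "mother_gt", "father_gt",
                           "exac_hom", "kg_hom")

validate_variant_table <- function(d) {
  miss <- setdiff(required_variant_cols, names(d))
  if (length(miss) > 0)
    abort(paste0("variant table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  gt_cols <- c("proband_gt", "mother_gt", "father_gt")
  ok <- c("hom_ref", "het", "hom_alt", "missing")
  bad <- unlist(lapply(gt_cols, function(cl) which(!(d[[cl]] %in% ok))))
  if (length(bad) > 0)
    abort(paste0("variant table has unrecognised genotype labels in row(s): ",
                 paste(sort(unique(bad)), collapse = ", ")))
  if (any(d$exac_hom < 0, na.rm = TRUE) || any(d$kg_hom < 0, na.rm = TRUE))
    abort("variant table has negative panel homozygote counts")
  as_tibble(d)
}

variant_key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")

#' Filter a trio variant table under the autosomal-recessive model
#'
#' Nominates candidates compatible with recessive inheritance in a trio:
#'
#' * homozygous candidates — proband homozygous-alternate with both parents
#'   heterozygous (with `lenient_parents = TRUE`, parents merely not
#'   homozygous-alternate and not missing);
#' * compound-heterozygous pairs — two distinct heterozygous proband
#'   variants in the same gene, one transmitted by each parent (one variant
#'   het in the mother and absent from the father, the other the reverse).
#'
#' A variant with any missing parental genotype that would otherwise
#' qualify is parked in the `unresolved` bucket rather than promoted.
#' Every excluded variant carries a logged reason, so the removal log
#' partitions the non-candidates.
#'
#' @param variants Annotated variant tibble (see [read_variant_table()]).
#' @param lenient_parents With the homozygous rule, accept parents that are
#'   not homozygous-alternate instead of requiring both het.
#' @return A `candidate_set`: list with tibbles `homozygous`,
#'   `compound_het_pairs`, `unresolved`, `removed` (with `reason`).
#' @export
apply_recessive_model <- function(variants, lenient_parents = FALSE) {
  d <- validate_variant_table(variants)
  d$.key <- variant_key(d)

  parent_ok <- if (lenient_parents) {
    function(gt) gt %in% c("het", "hom_ref")
  } else {
    function(gt) gt == "het"
  }
  hom_missing_parent <- d$proband_gt == "hom_alt" &
    (d$mother_gt == "missing" | d$father_gt == "missing")
  is_hom_cand <- d$proband_gt == "hom_alt" &
    parent_ok(d$mother_gt) & parent_ok(d$father_gt)

  # compound-het arms: proband het, exactly one parent transmits
  maternal <- d$proband_gt == "het" & d$mother_gt == "het" &
    d$father_gt == "hom_ref"
  paternal <- d$proband_gt == "het" & d$father_gt == "het" &
    d$mother_gt == "hom_ref"
  cht_missing_parent <- d$proband_gt == "het" &
    (d$mother_gt == "missing" | d$father_gt == "missing")

  pairs <- d |>
    filter(maternal | paternal) |>
    mutate(arm = ifelse(maternal[maternal | paternal], "maternal", "paternal"))
  pair_tbl <- pairs |>
    dplyr::group_split(.data$gene) |>
    map_dfr(function(g) {
      m <- filter(g, .data$arm == "maternal")
      p <- filter(g, .data$arm == "paternal")
      if (nrow(m) == 0 || nrow(p) == 0) return(tibble())
      tidyr::crossing(maternal_key = m$.key, paternal_key = p$.key) |>
        mutate(gene = g$gene[1])
    })
  if (nrow(pair_tbl) == 0)
    pair_tbl <- tibble(maternal_key = character(),
                       paternal_key = character(), gene = character())
  in_pair <- d$.key %in% c(pair_tbl$maternal_key, pair_tbl$paternal_key)

  unresolved <- (hom_missing_parent | cht_missing_parent) &
    !is_hom_cand & !in_pair
  kept <- is_hom_cand | in_pair | unresolved
  removed <- d |>
    filter(!kept) |>
    mutate(reason = dplyr::case_when(
      .data$proband_gt == "missing" ~ "proband_genotype_missing",
      .data$proband_gt == "hom_ref" ~ "proband_homozygous_reference",
      .data$proband_gt == "hom_alt" ~ "parental_genotypes_inconsistent",
      .data$proband_gt == "het" ~ "no_compound_het_partner_or_untransmitted",
      TRUE ~ "other"))

  new_candidate_set(
    homozygous = filter(d, is_hom_cand),
    compound_het_pairs = pair_tbl,
    unresolved = filter(d, unresolved),
    removed = removed,
    variants = d)
}

new_candidate_set <- function(homozygous, compound_het_pairs, unresolved,
                              removed, variants) {
  structure(list(homozygous = homozygous,
                 compound_het_pairs = compound_het_pairs,
                 unresolved = unresolved,
                 removed = removed,
                 variants = variants),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf(paste0("<candidate_set> %d homozygous candidate(s), ",
                     "%d compound-het pair(s), %d unresolved, %d removed\n"),
              nrow(x$homozygous), nrow(x$compound_het_pairs),
              nrow(x$unresolved), nrow(x$removed)))
  invisible(x)
}

#' Tidy a candidate set into one row per surviving candidate variant
#'
#' @param x A `candidate_set`.
#' @param ... Unused.
#' @return Tibble with `chrom`, `pos`, `ref`, `alt`, `gene`, `model`
#'   (`homozygous` or `compound_het`).
#' @exportS3Method
tidy.candidate_set <- function(x, ...) {
  hom <- x$homozygous |> mutate(model = "homozygous")
  cht <- x$variants |>
    filter(.data$.key %in% c(x$compound_het_pairs$maternal_key,
                             x$compound_het_pairs$paternal_key)) |>
    mutate(model = "compound_het")
  bind_rows(hom, cht) |>
    select(dplyr::any_of(c("chrom", "pos", "ref", "alt", "gene", "model",
                           "cds_pos", "protein_change")))
}

#' @rdname tidy.candidate_set
#' @exportS3Method
glance.candidate_set <- function(x, ...) {
  tibble(n_homozygous = nrow(x$homozygous),
         n_compound_het_pairs = nrow(x$compound_het_pairs),
         n_unresolved = nrow(x$unresolved),
         n_removed = nrow(x$removed))
}

#' Remove candidates common in reference panels
#'
#' A variant is removed when its homozygote count exceeds `exac_hom_max`
#' in ExAC-style exome panels or `kg_hom_max` in 1000-Genomes-style panels.
#' The thresholds are exclusive: counts of exactly 20 and 10 survive at
#' the defaults. A compound-het pair is removed when either member is.
#' Missing counts are treated as 0 and logged.
#'
#' @param candidates A `candidate_set` from [apply_recessive_model()].
#' @param exac_hom_max Maximum tolerated exome-panel homozygote count.
#' @param kg_hom_max Maximum tolerated 1000-Genomes homozygote count.
#' @return A `candidate_set` with panel-frequent variants moved to
#'   `removed` (reason `panel_homozygote_excess`).
#' @export
panel_count_filter <- function(candidates, exac_hom_max = 20,
                               kg_hom_max = 10) {
  stopifnot(inherits(candidates, "candidate_set"))
  if (exac_hom_max < 0 || kg_hom_max < 0)
    abort("panel_count_filter: thresholds must be non-negative")
  d <- candidates$variants
  exac <- ifelse(is.na(d$exac_hom), 0, d$exac_hom)
  kg <- ifelse(is.na(d$kg_hom), 0, d$kg_hom)
  if (any(is.na(d$exac_hom) | is.na(d$kg_hom)))
    message("panel_count_filter: missing panel counts treated as 0")
  fails <- d$.key[exac > exac_hom_max | kg > kg_hom_max]

  drop_hom <- filter(candidates$homozygous, .data$.key %in% fails)
  pair_fails <- candidates$compound_het_pairs$maternal_key %in% fails |
    candidates$compound_het_pairs$paternal_key %in% fails
  dropped_pairs <- candidates$compound_het_pairs[pair_fails, , drop = FALSE]
  kept_pairs <- candidates$compound_het_pairs[!pair_fails, , drop = FALSE]
  # pair members removed for frequency (not merely orphaned by a partner)
  pair_member_fails <- intersect(
    fails, c(candidates$compound_het_pairs$maternal_key,
             candidates$compound_het_pairs$paternal_key))
  drop_cht <- filter(candidates$variants, .data$.key %in% pair_member_fails)
  drop_unres <- filter(candidates$unresolved, .data$.key %in% fails)

  removed_now <- bind_rows(drop_hom, drop_cht, drop_unres) |>
    distinct(.data$.key, .keep_all = TRUE) |>
    mutate(reason = "panel_homozygote_excess")

  # a surviving member whose every pairing died loses candidate status too
  orphan_keys <- setdiff(
    c(dropped_pairs$maternal_key, dropped_pairs$paternal_key),
    c(kept_pairs$maternal_key, kept_pairs$paternal_key, fails,
      candidates$homozygous$.key, candidates$unresolved$.key))
  orphans <- filter(candidates$variants, .data$.key %in% orphan_keys) |>
    mutate(reason = "compound_het_partner_removed")
  removed_now <- bind_rows(removed_now, orphans)

  new_candidate_set(
    homozygous = filter(candidates$homozygous, !(.data$.key %in% fails)),
    compound_het_pairs = kept_pairs,
    unresolved = filter(candidates$unresolved, !(.data$.key %in% fails)),
    removed = bind_rows(candidates$removed, removed_now),
    variants = candidates$variants)
}

#' Codon number and within-codon offset for a coding position
#'
#' Codon number is `ceiling(cds_pos / 3)`; the offset is the position
#' within the codon (1-3). So c.41 falls in codon 14 (offset 2) and c.481
#' in codon 161 (offset 1), matching p.Leu14Pro / p.Arg161* style protein
#' annotations.
#'
#' @param cds_pos Integer vector of coding-DNA (c.) positions, >= 1.
#' @return Tibble with `cds_pos`, `codon`, `offset`.
#' @export
#' @examples
#' cds_to_codon(c(41, 481))
cds_to_codon <- function(cds_pos) {
  if (!is.numeric(cds_pos) || any(is.na(cds_pos)) || any(cds_pos < 1) ||
      any(cds_pos != floor(cds_pos)))
    abort("cds_to_codon: cds_pos must be integers >= 1")
  tibble(cds_pos = as.integer(cds_pos),
         codon = as.integer(ceiling(cds_pos / 3)),
         offset = as.integer((cds_pos - 1) %% 3 + 1))
}

#' Check that a protein change is consistent with its coding position
#'
#' Parses the residue number out of a simple HGVS p. substitution or stop
#' (`p.Leu14Pro`, `p.Arg161*`) and compares it with the codon implied by
#' the c. position. An unparseable string is a failure with a message, not
#' an error.
#'
#' @param variants Tibble with `cds_pos` and `protein_change` columns (a
#'   single `cds_pos` plus `protein_change` pair of vectors also works).
#' @param protein_change Optional vector when `variants` is a numeric
#'   `cds_pos` vector.
#' @return Tibble with `cds_pos`, `protein_change`, `codon`, `residue`,
#'   `pass`, `message`.
#' @export
#' @examples
#' check_protein_consistency(c(41, 481), c("p.Leu14Pro", "p.Arg161*"))
check_protein_consistency <- function(variants, protein_change = NULL) {
  if (is.numeric(variants) && !is.null(protein_change)) {
    variants <- tibble(cds_pos = variants, protein_change = protein_change)
  }
  stopifnot(all(c("cds_pos", "protein_change") %in% names(variants)))
  codon <- cds_to_codon(variants$cds_pos)$codon
  # accept both ASCII '*' and the typographic asterisk U+2217 for stops
  hgvs_pat <- paste0("^p\\.([A-Z][a-z]{2})([0-9]+)([A-Z][a-z]{2}|\\*|",
                     "\u2217", ")$")
  m <- regmatches(variants$protein_change,
                  regexec(hgvs_pat, variants$protein_change))
  residue <- vapply(m, function(g) {
    if (length(g) == 0) NA_integer_ else as.integer(g[3])
  }, integer(1))
  pass <- !is.na(residue) & residue == codon
  msg <- dplyr::case_when(
    is.na(residue) ~ paste0("unparseable HGVS protein change: ",
                            variants$protein_change),
    residue != codon ~ sprintf(
      "codon mismatch: c.%d implies codon %d but protein change names residue %d",
      variants$cds_pos, codon, residue),
    TRUE ~ "consistent")
  tibble(cds_pos = variants$cds_pos,
         protein_change = variants$protein_change,
         codon = codon, residue = residue, pass = pass, message = msg)
}
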