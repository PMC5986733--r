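#' Configuration for the founder-descent simulator
#'
#' The simulator emulates the data structure of an autozygosity study:
#' `k` homozygous carriers descend from a single founder `g` generations
#' back; around the index variant each carrier haplotype retains an
#' ancestral segment whose per-side genetic extent is Exponential(rate `g`
#' per Morgan) under the Haldane no-interference crossover model, and the
#' lineages are independent apart from the shared founder. Markers are
#' placed by a Poisson process at exome-like density; background alternate
#' allele frequencies are Beta-distributed truncated to [0.05, 0.5] so
#' heterozygotes are common enough to delimit ROHs sharply; genotypes
#' outside ancestral segments follow Hardy-Weinberg; genotyping errors flip
#' to each alternative genotype with equal probability; read depth is
#' Poisson and independent of genotype.
#'
#' Defaults mirror the study conditions the package is designed around:
#' three homozygous carriers of a founder allele at chr4:122,722,620 whose
#' most recent common ancestor lived about 125 generations ago, genotyped
#' on an exome-like marker grid at a uniform 1 cM/Mb map.
#'
#' @param g Generations per lineage from founder to carrier (> 0).
#' @param k Number of homozygous carriers (>= 1).
#' @param chrom Chromosome label.
#' @param chrom_length_bp Chromosome length in bp.
#' @param index_pos Index-variant position, inside the chromosome.
#' @param marker_density_per_Mb Mean marker count per Mb.
#' @param allele_freq_beta Length-2 shape parameters of the Beta model for
#'   background alternate-allele frequencies.
#' @param freq_bounds Truncation bounds for those frequencies.
#' @param genotype_error_rate Per-genotype error probability in [0, 1).
#' @param mean_depth Mean Poisson read depth.
#' @param n_noncarriers Extra non-carrier samples drawn purely from HWE.
#' @param map A [genetic_map()] for the Morgan-to-bp conversion.
#' @param seed Integer seed; all simulator output is reproducible from it.
#' @return A `founder_sim_config` list.
#' @export
founder_sim_config <- function(g = 125, k = 3, chrom = "chr4",
                               chrom_length_bp = 190000000,
                               index_pos = 122722620,
                               marker_density_per_Mb = 10,
                               allele_freq_beta = c(2, 5),
                               freq_bounds = c(0.05, 0.5),
                               genotype_error_rate = 0.001,
                               mean_depth = 30,
                               n_noncarriers = 0,
                               map = genetic_map(),
                               seed = 1) {
  stopifnot(g > 0, k >= 1, chrom_length_bp > 1,
            index_pos >= 1, index_pos <= chrom_length_bp,
            marker_density_per_Mb > 0,
            length(allele_freq_beta) == 2, all(allele_freq_beta > 0),
            genotype_error_rate >= 0, genotype_error_rate < 1,
            mean_depth > 0, n_noncarriers >= 0,
            inherits(map, "genetic_map"))
  structure(list(g = g, k = as.integer(k), chrom = chrom,
                 chrom_length_bp = chrom_length_bp, index_pos = index_pos,
                 marker_density_per_Mb = marker_density_per_Mb,
                 allele_freq_beta = allele_freq_beta,
                 freq_bounds = freq_bounds,
                 genotype_error_rate = genotype_error_rate,
                 mean_depth = mean_depth,
                 n_noncarriers = as.integer(n_noncarriers),
                 map = map, seed = as.integer(seed)),
            class = "founder_sim_config")
}

#' Draw ancestral segment extents around the focal locus
#'
#' Under Haldane's model the genetic distance from the focal locus to the
#' nearest crossover accumulated over `g` meioses is Exponential with rate
#' `g` per Morgan, independently on each side.
#'
#' @param g Generations (> 0).
#' @param n Number of lineages to draw.
#' @return Tibble with `left_morgan`, `right_morgan` (one row per lineage).
#' @export
sample_segment_extents <- function(g, n = 1) {
  if (!is.numeric(g) || g <= 0) abort("sample_segment_extents: g must be > 0")
  tibble(left_morgan = rexp(n, rate = g), right_morgan = rexp(n, rate = g))
}

# truncated Beta via inverse-CDF so the bounds carry no atoms
rbeta_trunc <- function(n, shape, lo, hi) {
  u <- runif(n, stats::pbeta(lo, shape[1], shape[2]),
             stats::pbeta(hi, shape[1], shape[2]))
  stats::qbeta(u, shape[1], shape[2])
}

#' Simulate a founder cohort with full truth records
#'
#' Generates the genotype calls of `k` carriers (plus optional non-carrier
#' samples) on one chromosome: marker positions from a Poisson process plus
#' a guaranteed marker at the index position; a founder haplotype carrying
#' the alternate allele at the index; per-haplotype ancestral segments from
#' [sample_segment_extents()] (truncated at chromosome ends, flagged);
#' founder alleles inside a haplotype's segment and Hardy-Weinberg draws
#' outside; optional genotype error and Poisson depth. The truth record
#' carries every segment, each carrier's true ROH (the intersection of its
#' two segments) and the true shared interval (intersection over all `2k`
#' segments), so parameter-recovery tests can compare pipeline output with
#' truth.
#'
#' @param config A [founder_sim_config()].
#' @param vcf_path Optional path; when given, the cohort is also written as
#'   a VCF 4.2 file (byte-identical across runs with the same config).
#' @return List with `calls` (genotype-call tibble as from [read_vcf()]),
#'   `truth` (list: `segments` tibble, `carrier_roh` tibble,
#'   `shared_interval`, `g`, `k`, `seed`), `config`, and `vcf_path`.
#' @export
simulate_cohort <- function(config, vcf_path = NULL) {
  stopifnot(inherits(config, "founder_sim_config"))
  with_local_seed(config$seed, simulate_cohort_impl(config, vcf_path))
}

simulate_cohort_impl <- function(config, vcf_path) {
  L <- config$chrom_length_bp
  if (config$index_pos < 1 || config$index_pos > L)
    abort("simulate_cohort: index marker falls outside the chromosome")
  n_bg <- rpois(1, L / 1e6 * config$marker_density_per_Mb)
  pos <- sort(unique(c(sample.int(L, min(n_bg, L)), config$index_pos)))
  n <- length(pos)
  is_index <- pos == config$index_pos

  freq <- rbeta_trunc(n, config$allele_freq_beta,
                      config$freq_bounds[1], config$freq_bounds[2])
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  ref[is_index] <- "T"; alt[is_index] <- "C"
  founder_alt <- rbinom(n, 1, freq)
  founder_alt[is_index] <- 1L

  carriers <- paste0("carrier", seq_len(config$k))
  noncarriers <- if (config$n_noncarriers > 0)
    paste0("noncarrier", seq_len(config$n_noncarriers)) else character(0)

  segments <- map_dfr(seq_len(config$k), function(j) {
    ext <- sample_segment_extents(config$g, n = 2)
    map_dfr(1:2, function(h) {
      lb <- genetic_extent_to_bp(config$map, config$index_pos,
                                 ext$left_morgan[h], -1)
      rb <- genetic_extent_to_bp(config$map, config$index_pos,
                                 ext$right_morgan[h], 1)
      start <- config$index_pos + lb
      end <- config$index_pos + rb
      tibble(sample_id = carriers[j], haplotype = h,
             left_morgan = ext$left_morgan[h],
             right_morgan = ext$right_morgan[h],
             seg_start = max(1, start), seg_end = min(L, end),
             truncated_left = start < 1, truncated_right = end > L)
    })
  })

  hwe_genotype <- function() rbinom(n, 1, freq) + rbinom(n, 1, freq)
  sample_gt <- function(s) {
    if (s %in% carriers) {
      seg <- filter(segments, .data$sample_id == s)
      hap_allele <- vapply(1:2, function(h) {
        inside <- pos >= seg$seg_start[h] & pos <= seg$seg_end[h]
        ifelse(inside, founder_alt, rbinom(n, 1, freq))
      }, numeric(n))
      gt <- hap_allele[, 1] + hap_allele[, 2]
    } else {
      gt <- hwe_genotype()
    }
    if (config$genotype_error_rate > 0) {
      err <- runif(n) < config$genotype_error_rate
      gt[err] <- (gt[err] + sample(1:2, sum(err), replace = TRUE)) %% 3
    }
    gt
  }

  all_samples <- c(carriers, noncarriers)
  calls <- map_dfr(all_samples, function(s) {
    gt <- sample_gt(s)
    depth <- rpois(n, config$mean_depth)
    tibble(sample_id = s, chrom = config$chrom, pos = as.numeric(pos),
           ref = ref, alt = alt,
           genotype = c("hom_ref", "het", "hom_alt")[gt + 1],
           allele1 = as.integer(ifelse(gt == 2, 1, 0)),
           allele2 = as.integer(ifelse(gt >= 1, 1, 0)),
           hom_allele = ifelse(gt == 2, alt, NA_character_),
           depth = as.numeric(depth), qual = NA_real_,
           var_class = "snv", dp_source = "sample")
  })

  carrier_roh <- segments |>
    group_by(.data$sample_id) |>
    summarise(roh_start = max(.data$seg_start), roh_end = min(.data$seg_end),
              .groups = "drop")
  shared_interval <- genomic_interval(config$chrom,
                                      max(segments$seg_start),
                                      min(segments$seg_end))
  truth <- list(segments = segments, carrier_roh = carrier_roh,
                shared_interval = shared_interval,
                g = config$g, k = config$k, seed = config$seed)

  if (!is.null(vcf_path)) {
    write_vcf_calls(calls, vcf_path,
                    contig_lengths = setNames(L, config$chrom))
  }
  list(calls = calls, truth = truth, config = config, vcf_path = vcf_path)
}

#' Write genotype calls as a multi-sample VCF 4.2 file
#'
#' Emits plain-text VCF with GT and DP per sample. The writer is
#' deterministic: the same calls always produce byte-identical output,
#' which the simulator's reproducibility contract relies on. Files written
#' here round-trip through [read_vcf()].
#'
#' @param calls Genotype-call tibble (long, one row per sample per site).
#' @param path Output path.
#' @param contig_lengths Optional named vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_vcf_calls <- function(calls, path, contig_lengths = NULL) {
  samples <- unique(calls$sample_id)
  sites <- calls |>
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    arrange(.data$chrom, .data$pos)
  gt_str <- ifelse(calls$genotype == "missing", "./.",
                   paste0(calls$allele1, "/", calls$allele2))
  body <- calls |>
    mutate(field = paste0(gt_str, ":", ifelse(is.na(.data$depth), ".",
                                              as.integer(.data$depth)))) |>
    select(dplyr::all_of(c("chrom", "pos", "ref", "alt", "sample_id",
                           "field"))) |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "field",
                       values_fill = "./.:.") |>
    arrange(.data$chrom, .data$pos)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=founderhap",
    if (!is.null(contig_lengths))
      sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
              as.integer(contig_lengths)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  lines <- apply(body, 1, function(r) {
    paste(c(r[["chrom"]], format(as.numeric(r[["pos"]]), scientific = FALSE),
            ".", r[["ref"]], r[["alt"]], ".", ".", ".", "GT:DP",
            unname(r[samples])), collapse = "\t")
  })
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Simulate an annotated trio variant table with known candidates
#'
#' Builds a fixture table for the recessive filter: implanted rows satisfy
#' the recessive model with panel homozygote counts under the thresholds,
#' while every background row violates at least one rule (wrong proband
#' zygosity, untransmitted or partner-less heterozygote, recessive-looking
#' but panel-frequent, or missing parental genotype). Each background row
#' gets its own gene so no accidental compound-het pair can form. The
#' `implanted` column is the truth label.
#'
#' @param n_background Number of background rows.
#' @param implant One of `"compound_het"`, `"homozygous"`, `"none"`.
#' @param seed Integer seed.
#' @return Tibble in [read_variant_table()] layout plus `implanted`.
#' @export
simulate_trio_table <- function(n_background = 50,
                                implant = c("compound_het", "homozygous",
                                            "none"),
                                seed = 1) {
  implant <- match.arg(implant)
  with_local_seed(seed, {
    templates <- list(
      function() list(p = "hom_ref", m = "het", f = "het", ex = 0, kg = 0),
      function() list(p = "hom_alt", m = "hom_ref", f = "hom_ref",
                      ex = 0, kg = 0),
      function() list(p = "het", m = "het", f = "hom_ref", ex = 0, kg = 0),
      function() list(p = "het", m = "het", f = "het", ex = 0, kg = 0),
      function() list(p = "hom_alt", m = "het", f = "het",
                      ex = 21 + rpois(1, 30), kg = 0),
      function() list(p = "hom_alt", m = "het", f = "het",
                      ex = 0, kg = 11 + rpois(1, 15)),
      function() list(p = "hom_alt", m = "missing", f = "het", ex = 0, kg = 0))
    bases <- c("A", "C", "G", "T")
    bg <- map_dfr(seq_len(n_background), function(i) {
      t <- templates[[sample(length(templates), 1)]]()
      ref <- sample(bases, 1)
      tibble(chrom = paste0("chr", sample(1:22, 1)),
             pos = sample.int(2e8, 1), ref = ref,
             alt = sample(setdiff(bases, ref), 1),
             gene = sprintf("BG%04d", i),
             proband_gt = t$p, mother_gt = t$m, father_gt = t$f,
             exac_hom = t$ex, kg_hom = t$kg,
             cds_pos = NA_integer_, protein_change = NA_character_,
             implanted = FALSE)
    })
    imp <- switch(
      implant,
      none = tibble(),
      homozygous = tibble(
        chrom = "chr4", pos = 122722620, ref = "T", alt = "C",
        gene = "CAND1", proband_gt = "hom_alt", mother_gt = "het",
        father_gt = "het", exac_hom = 0, kg_hom = 0,
        cds_pos = 41L, protein_change = "p.Leu14Pro", implanted = TRUE),
      compound_het = tibble(
        chrom = c("chr4", "chr4"), pos = c(122722620, 122737000),
        ref = c("T", "C"), alt = c("C", "T"), gene = c("CAND1", "CAND1"),
        proband_gt = c("het", "het"),
        mother_gt = c("het", "hom_ref"), father_gt = c("hom_ref", "het"),
        exac_hom = c(0, 0), kg_hom = c(0, 0),
        cds_pos = c(41L, 481L),
        protein_change = c("p.Leu14Pro", "p.Arg161*"), implanted = TRUE))
    out <- bind_rows(bg, imp)
    out[sample(nrow(out)), , drop = FALSE]
  })
}
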