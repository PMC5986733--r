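#' Build the packaged worked-example cohort
#'
#' Constructs, deterministically, the three-carrier VCF used throughout the
#' documentation: markers on chr4 engineered so the pipeline delimits a
#' shared haplotype of exactly chr4:122,400,000-123,200,000 (800 kb) around
#' an index variant at chr4:122,722,620, echoing the canonical founder
#' analysis this package implements. Carrier S1 has a long ROH (~11 Mb),
#' S3 and S4 short ones (~1 Mb), so trimming and intersection both do real
#' work. The cohort includes one low-depth site and one indel so the
#' marker-confidence filter is exercised too. A static copy ships as
#' `system.file("extdata", "worked_example.vcf", package = "founderhap")`.
#'
#' @param path Where to write the VCF (default: a tempfile).
#' @return The path, invisibly.
#' @export
worked_example_vcf <- function(path = tempfile(fileext = ".vcf")) {
  # genotype codes: 0 hom_ref, 1 het, 2 hom_alt
  site <- function(pos, ref, alt, g1, g3, g4, d1 = 40, d3 = 38, d4 = 45) {
    tibble(pos = pos, ref = ref, alt = alt,
           gt = c(g1, g3, g4), depth = c(d1, d3, d4),
           sample_id = c("S1", "S3", "S4"))
  }
  sites <- bind_rows(
    site(117000000, "G", "A", 1, 0, 0),
    site(120500000, "A", "C", 2, 1, 1),
    site(121500000, "T", "G", 0, 1, 0),
    site(122300000, "C", "T", 2, 1, 2),
    site(122350000, "G", "T", 2, 2, 1),
    site(122400000, "A", "G", 2, 2, 2),
    site(122600000, "C", "A", 2, 2, 2),
    site(122722620, "T", "C", 2, 2, 2, d1 = 34, d3 = 41, d4 = 52),
    site(122800000, "G", "C", 2, 1, 2, d3 = 7),   # S3 call fails 10x depth
    site(122900000, "AT", "A", 1, 1, 1),          # indel, filtered out
    site(123000000, "T", "A", 2, 2, 2),
    site(123200000, "G", "T", 2, 2, 2),
    site(123250000, "A", "T", 2, 2, 1),
    site(123300000, "C", "G", 0, 1, 0),
    site(124500000, "T", "C", 2, 1, 1),
    site(128000000, "A", "G", 1, 0, 0))
  calls <- sites |>
    mutate(chrom = "chr4",
           genotype = c("hom_ref", "het", "hom_alt")[.data$gt + 1],
           allele1 = as.integer(ifelse(.data$gt == 2, 1, 0)),
           allele2 = as.integer(ifelse(.data$gt >= 1, 1, 0)),
           hom_allele = ifelse(.data$gt == 2, .data$alt, NA_character_),
           qual = NA_real_,
           var_class = ifelse(nchar(.data$ref) == 1 & nchar(.data$alt) == 1,
                              "snv", "indel"),
           dp_source = "sample")
  write_vcf_calls(calls, path,
                  contig_lengths = c(chr4 = 190214555))
  invisible(path)
}
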