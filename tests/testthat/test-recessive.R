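trio_row <- function(p, m, f, gene = "G1", pos = 1000, exac = 0, kg = 0,
                     chrom = "chr1", ...) {
  tibble::tibble(chrom = chrom, pos = pos, ref = "A", alt = "C", gene = gene,
                 proband_gt = p, mother_gt = m, father_gt = f,
                 exac_hom = exac, kg_hom = kg, ...)
}

test_that("homozygous candidates need hom-alt proband with both parents het", {
  cs <- apply_recessive_model(trio_row("hom_alt", "het", "het"))
  expect_equal(nrow(cs$homozygous), 1)

  # both parents hom_ref cannot transmit two alt alleles
  cs2 <- apply_recessive_model(trio_row("hom_alt", "hom_ref", "hom_ref"))
  expect_equal(nrow(cs2$homozygous), 0)
  expect_equal(cs2$removed$reason, "parental_genotypes_inconsistent")

  # lenient mode relaxes to non-hom-alt parents
  d <- trio_row("hom_alt", "het", "hom_ref")
  expect_equal(nrow(apply_recessive_model(d)$homozygous), 0)
  expect_equal(nrow(apply_recessive_model(d, lenient_parents = TRUE)$homozygous), 1)
})

test_that("compound-het pairs take one het from each parent within a gene", {
  d <- dplyr::bind_rows(
    trio_row("het", "het", "hom_ref", pos = 100),   # maternal arm
    trio_row("het", "hom_ref", "het", pos = 200))   # paternal arm
  cs <- apply_recessive_model(d)
  expect_equal(nrow(cs$compound_het_pairs), 1)
  expect_equal(cs$compound_het_pairs$maternal_key, "chr1:100:A:C")
  expect_equal(cs$compound_het_pairs$paternal_key, "chr1:200:A:C")

  # same arms in different genes never pair
  d2 <- dplyr::bind_rows(
    trio_row("het", "het", "hom_ref", gene = "G1", pos = 100),
    trio_row("het", "hom_ref", "het", gene = "G2", pos = 200))
  expect_equal(nrow(apply_recessive_model(d2)$compound_het_pairs), 0)
})

test_that("no pair ever shares the transmitting parent (random tables)", {
  set.seed(88)
  gts <- c("hom_ref", "het", "hom_alt", "missing")
  for (i in 1:50) {
    n <- 40
    d <- tibble::tibble(
      chrom = "chr1", pos = seq_len(n) * 10, ref = "A", alt = "G",
      gene = sample(paste0("G", 1:6), n, replace = TRUE),
      proband_gt = sample(gts, n, replace = TRUE),
      mother_gt = sample(gts, n, replace = TRUE),
      father_gt = sample(gts, n, replace = TRUE),
      exac_hom = 0, kg_hom = 0)
    cs <- apply_recessive_model(d)
    if (nrow(cs$compound_het_pairs) > 0) {
      key2row <- function(k) d[match(k, paste(d$chrom, d$pos, d$ref, d$alt,
                                              sep = ":")), ]
      m <- key2row(cs$compound_het_pairs$maternal_key)
      p <- key2row(cs$compound_het_pairs$paternal_key)
      expect_true(all(m$mother_gt == "het" & m$father_gt == "hom_ref"))
      expect_true(all(p$father_gt == "het" & p$mother_gt == "hom_ref"))
      expect_true(all(cs$compound_het_pairs$maternal_key !=
                      cs$compound_het_pairs$paternal_key))
    }
    # buckets partition the input
    total <- nrow(cs$homozygous) + nrow(cs$unresolved) + nrow(cs$removed) +
      length(unique(c(cs$compound_het_pairs$maternal_key,
                      cs$compound_het_pairs$paternal_key)))
    expect_equal(total, n)
  }
})

test_that("missing parental genotypes park otherwise-qualifying variants as unresolved", {
  cs <- apply_recessive_model(trio_row("hom_alt", "missing", "het"))
  expect_equal(nrow(cs$homozygous), 0)
  expect_equal(nrow(cs$unresolved), 1)
  expect_equal(nrow(cs$removed), 0)
})

test_that("panel thresholds are exclusive: 21/11 fall, 20/10 survive", {
  d <- dplyr::bind_rows(
    trio_row("hom_alt", "het", "het", pos = 1, exac = 21, kg = 0),
    trio_row("hom_alt", "het", "het", pos = 2, exac = 0, kg = 11),
    trio_row("hom_alt", "het", "het", pos = 3, exac = 20, kg = 10))
  cs <- panel_count_filter(apply_recessive_model(d))
  expect_equal(cs$homozygous$pos, 3)
  expect_equal(sum(cs$removed$reason == "panel_homozygote_excess"), 2)
  expect_error(panel_count_filter(apply_recessive_model(d), exac_hom_max = -1),
               "non-negative")
})

test_that("a compound-het pair dies with either member; the survivor is logged as orphaned", {
  d <- dplyr::bind_rows(
    trio_row("het", "het", "hom_ref", pos = 100, exac = 25),  # frequent
    trio_row("het", "hom_ref", "het", pos = 200, exac = 0))
  cs <- panel_count_filter(apply_recessive_model(d))
  expect_equal(nrow(cs$compound_het_pairs), 0)
  expect_setequal(cs$removed$reason,
                  c("panel_homozygote_excess", "compound_het_partner_removed"))
})

test_that("panel filter equals the brute-force row predicate on random tables", {
  set.seed(77)
  for (i in 1:100) {
    n <- 30
    d <- tibble::tibble(
      chrom = "chr2", pos = seq_len(n), ref = "T", alt = "A",
      gene = paste0("G", seq_len(n)),
      proband_gt = "hom_alt", mother_gt = "het", father_gt = "het",
      exac_hom = sample(0:40, n, replace = TRUE),
      kg_hom = sample(0:20, n, replace = TRUE))
    cs <- panel_count_filter(apply_recessive_model(d))
    keep <- bf_panel_keep(d$exac_hom, d$kg_hom)
    expect_equal(sort(cs$homozygous$pos), sort(d$pos[keep]))
  }
})

test_that("the combined filter is idempotent and order-independent in thresholds", {
  tt <- simulate_trio_table(40, "compound_het", seed = 23)
  r1 <- run_filter_pipeline(tt)
  r2 <- run_filter_pipeline(tt)
  expect_identical(tidy(r1), tidy(r2))
  # re-applying the panel filter changes nothing
  again <- panel_count_filter(r1$candidates)
  expect_identical(tidy(again), tidy(r1$candidates))
})

test_that("codon arithmetic maps c. positions to residue numbers", {
  got <- cds_to_codon(c(41, 481, 3, 1, 4))
  expect_equal(got$codon, c(14, 161, 1, 1, 2))
  expect_equal(got$offset, c(2, 1, 3, 1, 1))
  expect_error(cds_to_codon(0), ">= 1")
  expect_error(cds_to_codon(-5), ">= 1")
})

test_that("protein-change consistency checks parse simple HGVS and flag mismatches", {
  got <- check_protein_consistency(
    c(41, 481, 41, 100),
    c("p.Leu14Pro", "p.Arg161*", "p.Leu15Pro", "not-hgvs"))
  expect_equal(got$pass, c(TRUE, TRUE, FALSE, FALSE))
  expect_match(got$message[3], "mismatch")
  expect_match(got$message[4], "unparseable")
})

test_that("malformed variant tables fail loudly with offending details", {
  expect_error(read_variant_table(tempfile()), "cannot read")
  expect_error(run_filter_pipeline(tibble::tibble(chrom = "chr1", pos = 1)),
               "missing column")
  bad <- trio_row("homalt", "het", "het")
  expect_error(run_filter_pipeline(bad), "row")
  expect_error(run_filter_pipeline(trio_row("hom_alt", "het", "het",
                                            exac = -2)), "negative")
})
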