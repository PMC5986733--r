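test_that("ROH extension stops one bp inside the first flanking heterozygote", {
  tr <- make_track(c(100, 200, 300, 400, 500), c(1, 2, 2, 2, 1))
  r <- extend_roh(tr, 300)
  expect_equal(r$outer_start, 101)
  expect_equal(r$outer_end, 499)
  expect_equal(r$left_het_pos, 100)
  expect_equal(r$right_het_pos, 500)
  expect_false(r$clipped_left || r$clipped_right)
})

test_that("without a flanking het the ROH clips at the track ends, flagged", {
  tr <- make_track(c(100, 200, 300), c(2, 2, 0))
  r <- extend_roh(tr, 200)
  expect_equal(r$outer_start, 100)
  expect_equal(r$outer_end, 300)
  expect_true(r$clipped_left && r$clipped_right)
})

test_that("hom-ref calls do not break a run; only heterozygotes terminate it", {
  tr <- make_track(c(10, 20, 30, 40, 50), c(1, 0, 2, 0, 1))
  r <- extend_roh(tr, 30)
  expect_equal(c(r$outer_start, r$outer_end), c(11, 49))
})

test_that("extension rejects a missing or non-hom-alt index, naming the sample", {
  tr <- make_track(c(100, 200, 300), c(2, 1, 2), sample_id = "P7")
  expect_error(extend_roh(tr, 250), "absent.*P7")
  expect_error(extend_roh(tr, 200), "P7.*not homozygous-alternate")
})

test_that("extension equals the brute-force maximal het-free window on random tracks", {
  set.seed(101)
  for (i in 1:300) {
    rt <- random_track(n = 200)
    got <- extend_roh(rt$track, rt$index_pos)
    want <- bf_extend_roh(rt$track, rt$index_pos)
    expect_equal(c(got$outer_start, got$outer_end), unname(want))
    # all markers strictly inside are non-het
    inside <- rt$track$pos > got$outer_start & rt$track$pos < got$outer_end
    expect_false(any(rt$track$genotype[inside] == "het"))
  }
})

test_that("shared homozygotes require the identical alt allele in every track", {
  t1 <- make_track(c(100, 250, 400), c(2, 2, 2), "a")
  t2 <- make_track(c(100, 250, 400), c(2, 2, 1), "b")
  t3 <- make_track(c(100, 250), c(2, 2), "c")  # 400 absent entirely
  iv <- genomic_interval("chr1", 1, 1000)
  expect_equal(shared_homozygote_sites(rbind(t1, t2, t3), iv), c(100, 250))

  # same zygosity, different allele at 250
  t2b <- make_track(c(100, 250, 400), c(2, 2, 2), "b", alt = "G")
  expect_equal(shared_homozygote_sites(rbind(t1, t2b), iv), numeric(0))

  expect_error(shared_homozygote_sites(t1, iv), "at least 2")
  t2c <- make_track(100, 2, "b", chrom = "chr9")
  expect_error(shared_homozygote_sites(rbind(t1, t2c), iv),
               "multiple chromosomes")
})

test_that("shared-homozygote detection matches per-site brute force on random tracks", {
  set.seed(202)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    pos_pool <- sort(sample.int(5000, 60))
    tracks <- dplyr::bind_rows(lapply(seq_len(k), function(j) {
      keep <- sort(sample(pos_pool, 45))
      make_track(keep, sample(0:2, length(keep), replace = TRUE),
                 sample_id = paste0("s", j))
    }))
    got <- shared_homozygote_sites(tracks, genomic_interval("chr1", 1000, 4000))
    expect_equal(got, bf_shared_homs(tracks, 1000, 4000))
  }
})

test_that("trimming pulls outer boundaries to the outermost shared homozygote", {
  # carriers share homs at 200/300/400; sample a has hets at 100 and 500
  t1 <- make_track(c(100, 200, 300, 400, 500), c(1, 2, 2, 2, 1), "a")
  t2 <- make_track(c(100, 200, 300, 400, 500), c(0, 2, 2, 2, 0), "b")
  tracks <- rbind(t1, t2)
  r <- trim_to_shared(extend_roh(t1, 300), tracks)
  expect_equal(c(r$trimmed_start, r$trimmed_end), c(200, 400))
  expect_false(r$degenerate)
  # trimmed within outer, index within trimmed
  expect_true(r$trimmed_start >= r$outer_start && r$trimmed_end <= r$outer_end)
  expect_true(r$index_pos >= r$trimmed_start && r$index_pos <= r$trimmed_end)
})

test_that("a trim with no shared homozygote beyond the index degenerates, flagged", {
  t1 <- make_track(c(100, 200, 300, 400, 500), c(1, 2, 2, 2, 1), "a")
  t2 <- make_track(c(100, 200, 300, 400, 500), c(0, 0, 2, 1, 0), "b")
  r <- trim_to_shared(extend_roh(t1, 300), rbind(t1, t2))
  expect_true(r$degenerate)
  expect_equal(c(r$trimmed_start, r$trimmed_end), c(300, 300))
})

test_that("trimming equals brute-force search over shared-hom sites", {
  set.seed(303)
  for (i in 1:100) {
    pos <- sort(sample.int(1e5, 80))
    idx <- pos[sample(20:60, 1)]
    mk <- function(s) {
      gt <- sample(0:2, length(pos), replace = TRUE)
      gt[pos == idx] <- 2
      make_track(pos, gt, s)
    }
    tracks <- rbind(mk("a"), mk("b"), mk("c"))
    outer <- extend_roh(tracks[tracks$sample_id == "a", ], idx)
    r <- trim_to_shared(outer, tracks)
    sh <- bf_shared_homs(tracks, outer$outer_start, outer$outer_end)
    pts <- c(sh, idx)
    expect_equal(c(r$trimmed_start, r$trimmed_end), range(pts))
  }
})

test_that("region intersection is max-start/min-end with shared-hom support", {
  regions <- tibble::tibble(
    sample_id = c("a", "b", "c"), chrom = "chr4", index_pos = 122722620,
    trimmed_start = c(117649360, 122400000, 122000000),
    trimmed_end = c(131644865, 123500000, 123200000))
  tracks <- dplyr::bind_rows(lapply(c("a", "b", "c"), function(s)
    make_track(c(122400000, 122722620, 123200000), c(2, 2, 2), s,
               chrom = "chr4")))
  sh <- intersect_regions(regions, tracks)
  expect_equal(c(sh$start, sh$end), c(122400000, 123200000))
  expect_equal(sh$n_shared_hom_support, 3)

  # identity on identical intervals
  same <- dplyr::mutate(regions, trimmed_start = 122400000,
                        trimmed_end = 123200000)
  expect_equal(c(intersect_regions(same, tracks)$start,
                 intersect_regions(same, tracks)$end),
               c(122400000, 123200000))
})

test_that("intersection equals a pairwise fold on random interval sets sharing a point", {
  set.seed(404)
  tracks <- rbind(make_track(5000, 2, "a"), make_track(5000, 2, "b"))
  for (i in 1:200) {
    n <- sample(2:6, 1)
    start <- sample.int(5000, n, replace = TRUE)
    end <- 5000 + sample.int(5000, n, replace = TRUE)  # all contain 5000
    regions <- tibble::tibble(sample_id = paste0("s", 1:n), chrom = "chr1",
                              index_pos = 5000,
                              trimmed_start = start, trimmed_end = end)
    fold <- Reduce(function(acc, j) c(max(acc[1], start[j]), min(acc[2], end[j])),
                   seq_len(n), c(-Inf, Inf))
    sh <- intersect_regions(regions, tracks)
    expect_equal(c(sh$start, sh$end), fold)
  }
})

test_that("interval lengths use the coordinate-difference convention with half-up rendering", {
  expect_equal(interval_length(genomic_interval("chr4", 117649360, 131644865)),
               13995505)
  expect_equal(format_bp(13995505), "14.0 Mb")
  expect_equal(interval_length(genomic_interval("chr4", 122400000, 123200000)),
               800000)
  expect_equal(format_bp(800000), "800 kb")
  expect_equal(interval_length(genomic_interval("chr1", 5, 5)), 0)
  expect_equal(format_bp(0), "0 bp")
  expect_equal(format_bp(1450000), "1.5 Mb")  # half-up, not banker's
  expect_equal(format_bp(2500), "3 kb")
})

test_that("the staged pipeline is invariant to sample order and nests correctly", {
  set.seed(505)
  pos <- sort(sample.int(1e6, 300))
  idx <- pos[150]
  mk <- function(s) {
    gt <- sample(0:2, length(pos), replace = TRUE, prob = c(0.3, 0.2, 0.5))
    gt[pos == idx] <- 2
    make_track(pos, gt, s)
  }
  tracks <- rbind(mk("a"), mk("b"), mk("c"))
  perm <- rbind(mk("c"), mk("a"), mk("b"))  # same gts? no - regenerate below
  perm <- tracks[order(factor(tracks$sample_id, levels = c("c", "a", "b"))), ]

  r1 <- roh_regions(tracks, idx)
  r2 <- roh_regions(perm, idx)
  s1 <- intersect_regions(r1, tracks)
  s2 <- intersect_regions(r2, perm)
  expect_same_interval(s1, s2)

  # interval containment chain: shared within every trimmed within outer
  expect_true(all(r1$trimmed_start >= r1$outer_start &
                  r1$trimmed_end <= r1$outer_end))
  expect_true(all(s1$start >= r1$trimmed_start & s1$end <= r1$trimmed_end))
  expect_true(all(r1$trimmed_start <= idx & r1$trimmed_end >= idx))
})
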