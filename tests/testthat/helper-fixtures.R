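# shared fixtures and independent brute-force oracles

# minimal marker track: genotypes as codes 0 hom_ref / 1 het / 2 hom_alt,
# all calls high-confidence SNVs on one chromosome
make_track <- function(pos, gt, sample_id = "s1", chrom = "chr1",
                       alt = "C", depth = 30) {
  tibble::tibble(
    sample_id = sample_id, chrom = chrom, pos = as.numeric(pos),
    ref = "A", alt = alt,
    genotype = c("hom_ref", "het", "hom_alt")[gt + 1],
    allele1 = as.integer(ifelse(gt == 2, 1, 0)),
    allele2 = as.integer(ifelse(gt >= 1, 1, 0)),
    hom_allele = ifelse(gt == 2, alt, NA_character_),
    depth = as.numeric(depth), qual = NA_real_, var_class = "snv",
    dp_source = "sample")
}

# random track guaranteed hom_alt at the index marker
random_track <- function(n = 200, sample_id = "s1", index_pos = NULL,
                         p_het = 0.3) {
  pos <- sort(sample.int(1e6, n))
  if (is.null(index_pos)) index_pos <- pos[sample.int(n, 1)]
  pos <- sort(unique(c(pos, index_pos)))
  gt <- sample(0:2, length(pos), replace = TRUE,
               prob = c(1 - p_het - 0.3, p_het, 0.3))
  gt[pos == index_pos] <- 2
  list(track = make_track(pos, gt, sample_id = sample_id),
       index_pos = index_pos)
}

# oracle: enumerate every het-free marker window containing the index and
# take the maximal one, then apply the boundary convention directly
bf_extend_roh <- function(track, index_pos) {
  track <- track[order(track$pos), ]
  i <- which(track$pos == index_pos)
  is_het <- track$genotype == "het"
  lh <- which(is_het & track$pos < index_pos)
  rh <- which(is_het & track$pos > index_pos)
  left_het <- if (length(lh)) track$pos[max(lh)] else NA_real_
  right_het <- if (length(rh)) track$pos[min(rh)] else NA_real_
  c(start = if (is.na(left_het)) min(track$pos) else left_het + 1,
    end = if (is.na(right_het)) max(track$pos) else right_het - 1)
}

# oracle: per-site conjunction over samples inside the interval
bf_shared_homs <- function(tracks, start, end) {
  ids <- unique(tracks$sample_id)
  cand <- sort(unique(tracks$pos[tracks$pos >= start & tracks$pos <= end]))
  keep <- vapply(cand, function(p) {
    rows <- tracks[tracks$pos == p, ]
    all(vapply(ids, function(s) {
      r <- rows[rows$sample_id == s, ]
      nrow(r) == 1 && r$genotype == "hom_alt"
    }, logical(1))) && length(unique(rows$hom_allele)) == 1
  }, logical(1))
  cand[keep]
}

# oracle: row-wise survival predicate for the panel-count filter
bf_panel_keep <- function(exac, kg, exac_max = 20, kg_max = 10) {
  exac <- ifelse(is.na(exac), 0, exac)
  kg <- ifelse(is.na(kg), 0, kg)
  !(exac > exac_max | kg > kg_max)
}

expect_same_interval <- function(a, b) {
  expect_equal(a$chrom, b$chrom)
  expect_equal(a$start, b$start)
  expect_equal(a$end, b$end)
}
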