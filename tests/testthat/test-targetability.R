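# Hand-crafted scored candidates covering the comparison cases.
mock_candidates <- function() {
  row <- function(key, mode, eff, ot) {
    data.frame(exon_key = key, gene_ids = "g", mode = mode,
               protospacer = strrep("A", 20), pam = "TGG", guide_strand = "+",
               contig = "chr1", proto_start = 1L, proto_end = 20L,
               target_pos_in_protospacer = 5L, target_genome_pos = 5L,
               predicted_efficiency = eff, offtarget_score = ot,
               stringsAsFactors = FALSE)
  }
  rbind(
    row("e1", "ABE", 50, 2), row("e1", "BE3", 40, 5),   # both; ABE wins both axes
    row("e2", "ABE", 35, 8), row("e2", "BE3", 45, 3),   # both; BE3 wins both axes
    row("e3", "ABE", 40, 4), row("e3", "BE3", 40, 4),   # both; double tie
    row("e4", "ABE", 60, 1),                            # ABE only
    row("e5", "BE3", 33, 9),                            # BE3 only
    row("e6", "ABE", 30, 1),                            # fails strict efficiency
    row("e7", "ABE", 55, 11)                            # fails off-target cap
  )
}

test_that("targetability records apply both thresholds with correct boundary sense", {
  rec <- targetability_records(mock_candidates())
  expect_equal(sum(rec$abe_targetable), 4)  # e1, e2, e3, e4
  expect_equal(sum(rec$be3_targetable), 4)  # e1, e2, e3, e5
  expect_false(rec$abe_targetable[rec$exon_key == "e6"])  # eff 30 is not > 30
  expect_false(rec$abe_targetable[rec$exon_key == "e7"])  # score 11 > 10
  expect_true(is.na(rec$abe_best_offtarget[rec$exon_key == "e6"]))
})

test_that("cumulative efficiency curve is a non-increasing step function", {
  rec <- targetability_records(mock_candidates())
  curve <- cumulative_by_efficiency(rec, grid = 0:100)
  expect_true(all(diff(curve$abe_count) <= 0))
  expect_true(all(diff(curve$be3_count) <= 0))
  # single-exon step behaviour: count 1 up to the best efficiency, 0 after
  one <- targetability_records(mock_candidates()[1:2, ])
  c1 <- cumulative_by_efficiency(one, grid = c(0, 40, 50, 51))
  expect_equal(c1$abe_count, c(1, 1, 1, 0))
  expect_equal(c1$be3_count, c(1, 1, 0, 0))
  # endpoint at threshold 0 equals the total count passing the off-target cap
  expect_equal(curve$abe_count[curve$threshold == 0],
               sum(!is.na(rec$abe_best_efficiency)))
  empty <- targetability_records(mock_candidates()[0, ])
  expect_equal(sum(cumulative_by_efficiency(empty)$abe_count), 0)
})

test_that("cumulative off-target curve is non-decreasing and honours the efficiency floor", {
  rec <- targetability_records(mock_candidates())
  curve <- cumulative_by_offtarget(rec, grid = seq(0, 20, 0.5))
  expect_true(all(diff(curve$abe_count) >= 0))
  expect_true(all(diff(curve$be3_count) >= 0))
  one <- targetability_records(mock_candidates()[1:2, ])
  c1 <- cumulative_by_offtarget(one, grid = c(0, 1.9, 2, 7))
  expect_equal(c1$abe_count, c(0, 0, 1, 1))
  # an exon whose only guide sits exactly at the efficiency floor never counts
  floor_only <- targetability_records(mock_candidates()[9, , drop = FALSE])
  cf <- cumulative_by_offtarget(floor_only, grid = c(0, 100))
  expect_equal(cf$abe_count, c(0, 0))
})

test_that("overlap report buckets are conserved and match a hand count", {
  rec <- targetability_records(mock_candidates())
  ov <- overlap_report(rec)
  expect_equal(ov$both, 3)          # e1, e2, e3
  expect_equal(ov$abe_only, 1)      # e4
  expect_equal(ov$be3_only, 1)      # e5
  expect_equal(ov$abe_higher_eff, 1)
  expect_equal(ov$be3_higher_eff, 1)
  expect_equal(ov$eff_ties, 1)
  expect_equal(ov$abe_lower_ot, 1)
  expect_equal(ov$be3_lower_ot, 1)
  expect_equal(ov$ot_ties, 1)
  expect_equal(ov$abe_higher_eff + ov$be3_higher_eff + ov$eff_ties, ov$both)
  expect_equal(ov$abe_lower_ot + ov$be3_lower_ot + ov$ot_ties, ov$both)
  expect_equal(ov$abe_higher_eff_frac, 1 / 3)
})

test_that("targetability results are independent of candidate row order", {
  cands <- mock_candidates()
  rec1 <- targetability_records(cands)
  set.seed(1)
  rec2 <- targetability_records(cands[sample(nrow(cands)), ])
  expect_identical(rec1, rec2)
  expect_identical(overlap_report(rec1), overlap_report(rec2))
})

test_that("toy-genome curves equal a brute-force recount", {
  b <- toy_bundle(fixture_spec(seed = 41, n_genes = 6, plant = "both"))
  cands <- rbind(design_guides(b$genome, b$inner, "ABE"),
                 design_guides(b$genome, b$inner, "BE3"))
  cands <- score_guides(cands, b$genome)
  rec <- targetability_records(cands, ot_cap = 10, eff_floor = 30)
  grid <- seq(0, 60, 5)
  curve <- cumulative_by_efficiency(rec, grid)
  brute <- vapply(grid, function(t) {
    length(unique(cands$exon_key[cands$mode == "ABE" &
                                   cands$offtarget_score <= 10 &
                                   cands$predicted_efficiency >= t]))
  }, numeric(1))
  expect_equal(curve$abe_count, as.integer(brute))
  ogrid <- seq(0, 20, 0.5)
  ocurve <- cumulative_by_offtarget(rec, ogrid)
  obrute <- vapply(ogrid, function(x) {
    length(unique(cands$exon_key[cands$mode == "BE3" &
                                   cands$predicted_efficiency > 30 &
                                   cands$offtarget_score <= x]))
  }, numeric(1))
  expect_equal(ocurve$be3_count, as.integer(obrute))
})
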