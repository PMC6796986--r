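q40 <- function(n) strrep("I", n)

make_pairs <- function(s1, s2, q1 = NULL, q2 = NULL) {
  if (is.null(q1)) q1 <- vapply(nchar(s1), q40, "")
  if (is.null(q2)) q2 <- vapply(nchar(s2), q40, "")
  ids <- sprintf("r%d", seq_along(s1))
  read_fastq_pairs(
    write_lines_tmp(fastq_lines(ids, s1, q1), ".fastq"),
    write_lines_tmp(fastq_lines(ids, s2, q2), ".fastq")
  )
}

test_that("demultiplexing assigns by primer prefix within the mismatch budget", {
  primers <- data.frame(amplicon = c("amp1", "amp2"),
                        fwd = c("ACGTACGTAC", "TTTTGGGGCC"),
                        rev = c("GGGGAAAATT", "CACACACACA"),
                        stringsAsFactors = FALSE)
  body <- strrep("A", 30)
  reads <- make_pairs(
    c(paste0("ACGTACGTAC", body),   # exact
      paste0("ACGTACGTAG", body),   # 1 mismatch in fwd
      paste0("ACGTACGAGG", body),   # 2 mismatches
      paste0("TTTTGGGGCC", body)),
    c(paste0("GGGGAAAATT", body),
      paste0("GGGGAAAATT", body),
      paste0("GGGGAAAATT", body),
      paste0("CACACACACA", body))
  )
  out <- demultiplex_by_primer(reads, primers, max_mismatches = 1)
  expect_equal(length(out$amp1$r1), 2)
  expect_equal(length(out$amp2$r1), 1)
  expect_equal(length(out$unassigned$r1), 1)
  dup <- primers; dup$fwd[2] <- dup$fwd[1]; dup$rev[2] <- dup$rev[1]
  expect_error(demultiplex_by_primer(reads, dup), "identical")
})

test_that("ambiguous primer matches go to the unassigned bin", {
  primers <- data.frame(amplicon = c("a", "b"),
                        fwd = c("AAAAAAAAAA", "AAAAAAAAAT"),
                        rev = c("CCCCCCCCCC", "CCCCCCCCCG"),
                        stringsAsFactors = FALSE)
  reads <- make_pairs(paste0("AAAAAAAAAA", strrep("G", 20)),
                      paste0("CCCCCCCCCC", strrep("G", 20)))
  out <- demultiplex_by_primer(reads, primers, max_mismatches = 1)
  expect_equal(length(out$unassigned$r1), 1)
  expect_equal(length(out$a$r1), 0)
})

test_that("3' quality trimming respects the 50-bp discard boundary", {
  mk_qual <- function(n_good, n_bad) paste0(strrep("I", n_good), strrep("+", n_bad))
  reads <- make_pairs(
    s1 = c(strrep("A", 100), strrep("A", 100), strrep("A", 100)),
    s2 = c(strrep("C", 100), strrep("C", 100), strrep("C", 100)),
    q1 = c(mk_qual(90, 10), mk_qual(50, 50), mk_qual(51, 49)),
    q2 = c(q40(100), q40(100), q40(100))
  )
  out <- trim_and_filter(reads, quant_config())
  # read 1: 90 bp kept; read 2: trimmed to exactly 50 -> pair discarded;
  # read 3: 51 bp -> kept
  expect_equal(length(out$r1), 2)
  expect_equal(attr(out, "n_discarded"), 1)
  expect_equal(sort(Biostrings::width(out$r1)), c(51, 90))
  expect_error(
    read_fastq_pairs(
      write_lines_tmp(fastq_lines("r1", "ACGT", "II"), ".fastq"),
      write_lines_tmp(fastq_lines("r1", "ACGT", "IIII"), ".fastq")
    )
  )
})

test_that("trimming is idempotent", {
  q <- paste0(strrep("I", 60), strrep("5", 5), strrep("I", 5), strrep("+", 30))
  reads <- make_pairs(strrep("A", 100), strrep("C", 100),
                      q1 = q, q2 = q40(100))
  once <- trim_and_filter(reads)
  twice <- trim_and_filter(once)
  expect_equal(Biostrings::width(once$r1), Biostrings::width(twice$r1))
  expect_identical(as.character(once$r1), as.character(twice$r1))
})

test_that("pileup windows equal the generator's per-position truth", {
  spec <- fixture_spec(seed = 51, editing_rate = 0.3, depth = 200)
  b <- toy_bundle(spec)
  gd <- b$fx$truth_guides[b$fx$truth_guides$mode == "ABE", ][1, ]
  sim <- simulate_amplicon_reads(spec, b$genome, gd$contig, gd$target_genome_pos,
                                 gd$proto_start, gd$proto_end, dir = tempfile())
  win <- build_pileup_window(sim$paths$sam, b$genome, gd$contig,
                             gd$proto_start, gd$proto_end)
  expect_equal(nrow(win), 120)
  tr <- sim$truth[match(win$pos, sim$truth$pos), ]
  expect_equal(win$count_A, tr$count_A)
  expect_equal(win$count_C, tr$count_C)
  expect_equal(win$count_G, tr$count_G)
  expect_equal(win$count_T, tr$count_T)
  expect_true(all(win$alt_depth <= win$depth))
  expect_equal(win$alt_fraction[win$depth > 0],
               (win$alt_depth / win$depth)[win$depth > 0])
})

test_that("error-free, unedited reads give an all-reference pileup", {
  spec <- fixture_spec(seed = 52, editing_rate = 0, sequencing_error = 0, depth = 50)
  b <- toy_bundle(spec)
  gd <- b$fx$truth_guides[1, ]
  sim <- simulate_amplicon_reads(spec, b$genome, gd$contig, gd$target_genome_pos,
                                 gd$proto_start, gd$proto_end, dir = tempfile())
  win <- build_pileup_window(sim$paths$sam, b$genome, gd$contig,
                             gd$proto_start, gd$proto_end)
  expect_true(all(win$alt_depth == 0))
})

test_that("global error estimate is the mean alt fraction minus excluded positions", {
  win <- data.frame(pos = 1:4, ref = "A",
                    count_A = c(999, 998, 997, 500), count_C = 0,
                    count_G = c(1, 2, 3, 500), count_T = 0,
                    depth = 1000, alt_depth = c(1, 2, 3, 500),
                    alt_fraction = c(0.001, 0.002, 0.003, 0.5),
                    zero_depth = FALSE)
  expect_equal(estimate_global_error(win, exclude_positions = 4), 0.002)
  expect_equal(estimate_global_error(win), mean(c(0.001, 0.002, 0.003, 0.5)))
  win0 <- win; win0$depth <- 0
  expect_error(estimate_global_error(win0), "no covered positions")
})

test_that("positional error comes from the control with documented fallbacks", {
  ctrl <- data.frame(pos = 10:12, ref = "A", count_A = c(998, 0, 1000),
                     count_C = 0, count_G = c(2, 0, 0), count_T = 0,
                     depth = c(1000, 0, 1000), alt_depth = c(2, 0, 0),
                     alt_fraction = c(0.002, 0, 0), zero_depth = c(FALSE, TRUE, FALSE))
  expect_equal(estimate_positional_error(ctrl, 10), 0.002)
  expect_true(is.na(estimate_positional_error(NULL, 10)))
  expect_warning(p <- estimate_positional_error(ctrl, 11), "zero depth")
  expect_true(is.na(p))
  expect_error(estimate_positional_error(ctrl, 99), "not covered")
})

test_that("binomial conversion calls match exact tail probabilities", {
  win <- data.frame(pos = 1:3, ref = "A",
                    count_A = c(1000, 99, 475), count_C = 0,
                    count_G = c(0, 1, 25), count_T = 0,
                    depth = c(1000, 100, 500), alt_depth = c(0, 1, 25),
                    alt_fraction = c(0, 0.01, 0.05), zero_depth = FALSE)
  calls <- call_conversions(win, 1:3, global_err = 0.002,
                            positional_err = c(NA, 0.01, NA))
  # k = 0: P(X >= 0) = 1
  expect_equal(calls$p_value[1], 1)
  expect_false(calls$significant[1])
  # n = 100, k = 1, p0 = 0.01 (positional dominates): 1 - 0.99^100
  expect_equal(calls$p_value[2], 1 - 0.99^100)
  expect_equal(calls$background[2], 0.01)
  expect_false(calls$significant[2])
  # n = 500, k = 25 at p0 = 0.002 is overwhelming
  expect_lt(calls$p_value[3], 1e-5)
  expect_true(calls$significant[3])
  expect_equal(calls$rate[3], 0.05)
  # background picks the larger of global and positional estimates
  expect_equal(calls$background[1], 0.002)
})

test_that("zero-depth targets yield undefined rate and no call", {
  win <- data.frame(pos = 1, ref = "T", count_A = 0, count_C = 0,
                    count_G = 0, count_T = 0, depth = 0, alt_depth = 0,
                    alt_fraction = 0, zero_depth = TRUE)
  calls <- call_conversions(win, 1, global_err = 0.002)
  expect_true(is.na(calls$rate))
  expect_false(calls$significant)
  expect_identical(calls$conversion, "T>C")
})

test_that("p-values are monotone in k and in the background rate", {
  mkwin <- function(k) data.frame(pos = 1, ref = "A", count_A = 500 - k,
                                  count_C = 0, count_G = k, count_T = 0,
                                  depth = 500, alt_depth = k,
                                  alt_fraction = k / 500, zero_depth = FALSE)
  p_at <- function(k, p0) call_conversions(mkwin(k), 1, p0)$p_value
  ks <- c(0, 1, 2, 5, 10, 20, 50)
  expect_true(all(diff(vapply(ks, p_at, numeric(1), p0 = 0.002)) <= 0))
  p0s <- c(0.001, 0.002, 0.005, 0.01, 0.05)
  expect_true(all(diff(vapply(p0s, function(p) p_at(10, p), numeric(1))) >= 0))
})
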