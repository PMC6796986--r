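# Three-exon plus-strand toy gene with distinctive exon sequences.
abc_gene <- function(up = "AAAATTTTCC", tg = "CCCCAAAATT", dn = "GGGGTTTTAA",
                     anchor = 2) {
  i1 <- paste0(strrep("T", 8), "AG")
  i2 <- paste0(strrep("T", 8), "AG")
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    "TTTT", up, i1, tg, i2, dn, "TTTT")))
  s1 <- 5; e1 <- s1 + nchar(up) - 1
  s2 <- e1 + 11; e2 <- s2 + nchar(tg) - 1
  s3 <- e2 + 11; e3 <- s3 + nchar(dn) - 1
  gtf <- write_lines_tmp(c(
    gtf_line("chr1", s1, e1, "+", "tx1"),
    gtf_line("chr1", s2, e2, "+", "tx1"),
    gtf_line("chr1", s3, e3, "+", "tx1")
  ), ".gtf")
  tx <- read_annotation(gtf)
  list(genome = genome, tx = tx, key = exon_key2("chr1", s2, e2, "+"))
}

exon_key2 <- function(contig, start, end, strand) {
  sprintf("%s:%d-%d:%s", contig, start, end, strand)
}

test_that("junction probes are anchored concatenations of flanking exon sequence", {
  g <- abc_gene(up = "AAAA", tg = "CCCC", dn = "GGGG")
  js <- build_junction_set(g$genome, g$tx, g$key, anchor = 2)
  expect_identical(js$skipped, "AAGG")
  expect_identical(js$canonical_5p, "AACC")
  expect_identical(js$canonical_3p, "CCGG")
  expect_error(build_junction_set(g$genome, g$tx, g$key, anchor = 5),
               "smaller anchor")
})

test_that("minus-strand probes are built in transcript orientation", {
  plus <- abc_gene()
  js_plus <- build_junction_set(plus$genome, plus$tx, plus$key, anchor = 3)
  # the same gene encoded on the minus strand of a reverse-complemented contig
  rc <- Biostrings::DNAStringSet(c(chr1 = revcomp(as.character(plus$genome[[1]]))))
  L <- length(rc[[1]])
  flip <- function(s, e) c(L - e + 1, L - s + 1)
  coords <- lapply(list(c(5, 14), c(25, 34), c(45, 54)), function(x) flip(x[1], x[2]))
  gtf <- write_lines_tmp(vapply(coords, function(x) {
    gtf_line("chr1", x[1], x[2], "-", "tx1")
  }, ""), ".gtf")
  tx <- read_annotation(gtf)
  key <- exon_key2("chr1", coords[[2]][1], coords[[2]][2], "-")
  js_minus <- build_junction_set(rc, tx, key, anchor = 3)
  expect_identical(js_minus$skipped, js_plus$skipped)
  expect_identical(js_minus$canonical_5p, js_plus$canonical_5p)
  expect_identical(js_minus$canonical_3p, js_plus$canonical_3p)
  # a minus-strand read (reverse complement of the probe context) still matches
  read <- revcomp(paste0("TT", js_minus$skipped, "AA"))
  counts <- classify_reads(read, js_minus)
  expect_equal(counts$skipped_reads, 1)
})

test_that("reads are classified by junction with exclusion of ambiguous/background", {
  g <- abc_gene()
  js <- build_junction_set(g$genome, g$tx, g$key, anchor = 3)
  pad <- function(p) paste0("TTT", p, "TTT")
  reads <- c(rep(pad(js$skipped), 10), rep(pad(js$canonical_5p), 60),
             rep(pad(js$canonical_3p), 30),
             paste0(js$skipped, js$canonical_5p),  # ambiguous: both classes
             strrep("T", 20))                      # no junction
  counts <- classify_reads(reads, js)
  expect_equal(counts$skipped_reads, 10)
  expect_equal(counts$canonical_reads, 90)
  expect_equal(counts$excluded_reads, 2)
  expect_equal(counts$skipping_rate, 0.10)
  expect_equal(counts$skipped_reads + counts$canonical_reads + counts$excluded_reads,
               length(reads))
})

test_that("degenerate junction counts are handled", {
  g <- abc_gene()
  js <- build_junction_set(g$genome, g$tx, g$key, anchor = 3)
  none <- classify_reads(c("TTTTTTTT"), js)
  expect_true(is.na(none$skipping_rate))
  only_canonical <- classify_reads(rep(paste0("AA", js$canonical_5p, "AA"), 50), js)
  expect_equal(only_canonical$skipping_rate, 0)
})

test_that("adding excluded-class reads never changes the skipping rate", {
  g <- abc_gene()
  js <- build_junction_set(g$genome, g$tx, g$key, anchor = 3)
  core <- c(rep(paste0("A", js$skipped, "A"), 5), rep(paste0("A", js$canonical_3p, "A"), 15))
  base <- classify_reads(core, js)
  with_bg <- classify_reads(c(core, rep(strrep("C", 25), 40)), js)
  expect_equal(base$skipping_rate, with_bg$skipping_rate)
  expect_equal(with_bg$excluded_reads, 40)
})

test_that("rate is invariant under reverse-complementing all reads", {
  spec <- fixture_spec(seed = 61, skip_fraction = 0.3, n_junction_reads = 400,
                       n_background_reads = 100)
  b <- toy_bundle(spec)
  key <- b$fx$truth_guides$exon_key[1]
  rna <- simulate_rna_reads(spec, b$genome, b$transcripts, key)
  js <- build_junction_set(b$genome, b$transcripts, key)
  fwd <- classify_reads(rna$reads, js)
  rc <- classify_reads(revcomp(rna$reads), js)
  expect_equal(fwd$skipping_rate, rc$skipping_rate)
  expect_equal(fwd$skipped_reads, rc$skipped_reads)
})

test_that("replicate averaging is the unweighted mean with NA handling", {
  expect_equal(average_replicates(c(0.10, 0.20)), 0.15)
  expect_equal(average_replicates(0.3), 0.3)
  expect_warning(m <- average_replicates(c(0.1, NA, 0.3)), "undefined")
  expect_equal(m, 0.2)
  expect_error(average_replicates(numeric(0)), "no replicate")
})

test_that("densitometry formula and boundaries are exact", {
  expect_equal(percent_skipping_from_bands(100, 300), 25)
  expect_equal(percent_skipping_from_bands(0, 123), 0)
  expect_equal(percent_skipping_from_bands(55, 0), 100)
  expect_error(percent_skipping_from_bands(0, 0), "zero")
  expect_error(percent_skipping_from_bands(-1, 10), "non-negative")
})
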