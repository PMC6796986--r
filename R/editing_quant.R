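#' Configuration for amplicon editing quantification
#'
#' Defaults follow the standard amplicon deep-sequencing workflow for base
#' editing: reads are quality-trimmed at the 3' end to Phred 20, pairs with a
#' mate trimmed to 50 bp or less are discarded, per-position allele depths
#' are tallied over a 120-bp window centered on the protospacer, and A>G or
#' T>C conversion is called with a one-sided binomial test at p < 1e-5
#' against the sequencing-error background.
#'
#' @param trim_quality Phred threshold for 3' quality trimming.
#' @param min_mate_length Pairs with a mate trimmed to this length or less
#'   are discarded.
#' @param window_width Width in bp of the pileup window.
#' @param p_cutoff Significance cutoff of the binomial test.
#' @param demux_max_mismatches Mismatches tolerated in a primer prefix match.
#' @param min_base_quality Minimum base quality counted in pileups.
#' @return A `quant_config` list.
#' @export
quant_config <- function(trim_quality = 20L, min_mate_length = 50L,
                         window_width = 120L, p_cutoff = 1e-5,
                         demux_max_mismatches = 1L, min_base_quality = 20L) {
  stopifnot(p_cutoff > 0, p_cutoff < 1, trim_quality >= 0, window_width >= 20)
  structure(list(trim_quality = as.integer(trim_quality),
                 min_mate_length = as.integer(min_mate_length),
                 window_width = as.integer(window_width),
                 p_cutoff = p_cutoff,
                 demux_max_mismatches = as.integer(demux_max_mismatches),
                 min_base_quality = as.integer(min_base_quality)),
            class = "quant_config")
}

#' Read a paired FASTQ into a read-pair object
#'
#' @param r1_path,r2_path Paths to the mate-1 and mate-2 FASTQ files
#'   (Phred+33 qualities).
#' @return A list with elements `r1` and `r2`, each a
#'   [Biostrings::QualityScaledDNAStringSet] of equal length.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  read_one <- function(path) {
    lines <- readLines(path)
    if (length(lines) %% 4L != 0L) stop("truncated FASTQ record in ", path)
    seq_len_ok <- nchar(lines[seq(2L, length(lines), by = 4L)]) ==
      nchar(lines[seq(4L, length(lines), by = 4L)])
    if (any(!seq_len_ok)) {
      stop("sequence/quality length mismatch in ", path, " (read ",
           which(!seq_len_ok)[1], ")")
    }
    # the parser attaches metadata columns that narrow() later warns about
    x <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w))) invokeRestart("muffleWarning")
      }
    )
    S4Vectors::mcols(x) <- NULL
    x
  }
  r1 <- read_one(r1_path)
  r2 <- read_one(r2_path)
  if (length(r1) != length(r2)) stop("mate files differ in read count")
  list(r1 = r1, r2 = r2)
}

hamming_prefix <- function(read, primer) {
  k <- nchar(primer)
  if (nchar(read) < k) return(Inf)
  sum(strsplit(substr(read, 1, k), "")[[1]] != strsplit(primer, "")[[1]])
}

#' Demultiplex read pairs by PCR primer sequences
#'
#' Assigns each pair to the unique amplicon whose forward primer
#' prefix-matches mate 1 and reverse primer prefix-matches mate 2, each with
#' at most `max_mismatches` mismatches. Pairs matching no amplicon, or more
#' than one equally, go to the `"unassigned"` bin.
#'
#' @param pairs Read pairs from [read_fastq_pairs()].
#' @param primer_table Data.frame with columns `amplicon`, `fwd`, `rev`.
#' @param max_mismatches Mismatch tolerance per primer (default 1).
#' @return Named list of read-pair objects, one per amplicon plus
#'   `unassigned`.
#' @export
demultiplex_by_primer <- function(pairs, primer_table, max_mismatches = 1L) {
  stopifnot(all(c("amplicon", "fwd", "rev") %in% names(primer_table)))
  sig <- paste(toupper(primer_table$fwd), toupper(primer_table$rev))
  if (anyDuplicated(sig)) stop("two amplicons share identical primer pairs")
  n <- length(pairs$r1)
  s1 <- as.character(pairs$r1)
  s2 <- as.character(pairs$r2)
  assign <- rep("unassigned", n)
  for (i in seq_len(n)) {
    d <- vapply(seq_len(nrow(primer_table)), function(j) {
      max(hamming_prefix(s1[i], toupper(primer_table$fwd[j])),
          hamming_prefix(s2[i], toupper(primer_table$rev[j])))
    }, numeric(1))
    hit <- which(d <= max_mismatches)
    if (length(hit) == 1L) assign[i] <- primer_table$amplicon[hit]
  }
  out <- lapply(c(unique(primer_table$amplicon), "unassigned"), function(a) {
    idx <- which(assign == a)
    list(r1 = pairs$r1[idx], r2 = pairs$r2[idx])
  })
  names(out) <- c(unique(primer_table$amplicon), "unassigned")
  out
}

quality_ints <- function(qsset) {
  as(Biostrings::quality(qsset), "IntegerList")
}

trim_one_set <- function(qsset, threshold) {
  quals <- quality_ints(qsset)
  keep_len <- vapply(seq_along(qsset), function(i) {
    q <- quals[[i]]
    good <- which(q >= threshold)
    if (length(good) == 0L) 0L else max(good)
  }, integer(1))
  IRanges::narrow(qsset, start = 1L, width = keep_len)
}

#' Quality-trim read pairs and discard short mates
#'
#' Each mate is trimmed from the 3' end: trailing bases with quality below
#' `trim_quality` are removed (trimming stops at the last base meeting the
#' threshold). Pairs in which either mate is trimmed to `min_mate_length` bp
#' or less are discarded entirely. Trimming is idempotent.
#'
#' @param pairs Read pairs from [read_fastq_pairs()].
#' @param config A [quant_config()].
#' @return Trimmed read pairs (same structure, possibly fewer pairs), with a
#'   `n_discarded` attribute.
#' @export
trim_and_filter <- function(pairs, config = quant_config()) {
  r1 <- trim_one_set(pairs$r1, config$trim_quality)
  r2 <- trim_one_set(pairs$r2, config$trim_quality)
  keep <- Biostrings::width(r1) > config$min_mate_length &
    Biostrings::width(r2) > config$min_mate_length
  out <- list(r1 = r1[keep], r2 = r2[keep])
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Per-position allele depths over a window around a protospacer
#'
#' Converts a coordinate-sorted SAM file to BAM ([Rsamtools::asBam()]) and
#' tallies aligned bases per position with [Rsamtools::pileup()] over a
#' `window_width` window centered on the protospacer midpoint. Bases below
#' `min_base_quality` are ignored; deletions and reference skips do not count
#' toward depth. The window is truncated with a warning where it extends past
#' the contig.
#'
#' @param sam_path Path to a SAM (or BAM) file with per-base qualities.
#' @param genome Reference [Biostrings::DNAStringSet] for ref-base lookup.
#' @param contig Contig of the amplicon.
#' @param proto_start,proto_end 1-based protospacer coordinates.
#' @param config A [quant_config()].
#' @return A `pileup_window` data.frame: `pos`, `ref`, `count_A`, `count_C`,
#'   `count_G`, `count_T`, `depth`, `alt_depth`, `alt_fraction` (0 with a
#'   `zero_depth` flag column when depth is 0).
#' @export
build_pileup_window <- function(sam_path, genome, contig, proto_start, proto_end,
                                config = quant_config()) {
  mid <- (proto_start + proto_end) %/% 2L
  w <- config$window_width
  lo <- mid - (w - 1L) %/% 2L
  hi <- lo + w - 1L
  len <- contig_length(genome, contig)
  if (lo < 1L || hi > len) {
    warning("pileup window truncated at contig boundary")
    lo <- max(lo, 1L); hi <- min(hi, len)
  }
  bam <- if (grepl("\\.bam$", sam_path)) {
    sam_path
  } else {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(sam_path, destination = dest, overwrite = TRUE,
                     indexDestination = TRUE)
  }
  which <- GenomicRanges::GRanges(contig, IRanges::IRanges(lo, hi))
  pp <- Rsamtools::PileupParam(
    max_depth = 1000000L,
    min_base_quality = config$min_base_quality,
    min_mapq = 0L, min_nucleotide_depth = 1L,
    distinguish_strands = FALSE, distinguish_nucleotides = TRUE,
    ignore_query_Ns = TRUE,
    include_deletions = FALSE, include_insertions = FALSE
  )
  res <- Rsamtools::pileup(bam, scanBamParam = Rsamtools::ScanBamParam(which = which),
                           pileupParam = pp)
  pos <- lo:hi
  counts <- matrix(0L, nrow = length(pos), ncol = 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  if (nrow(res) > 0L) {
    res <- res[res$nucleotide %in% c("A", "C", "G", "T"), , drop = FALSE]
    idx <- match(res$pos, pos)
    ok <- !is.na(idx)
    for (r in which(ok)) {
      counts[idx[r], as.character(res$nucleotide[r])] <-
        counts[idx[r], as.character(res$nucleotide[r])] + res$count[r]
    }
  }
  ref <- strsplit(extract_sequence(genome, contig, lo, hi, "+"), "")[[1]]
  depth <- as.integer(rowSums(counts))
  ref_count <- vapply(seq_along(pos), function(i) {
    if (ref[i] %in% colnames(counts)) counts[i, ref[i]] else 0L
  }, numeric(1))
  alt_depth <- as.integer(depth - ref_count)
  out <- data.frame(
    pos = pos, ref = ref,
    count_A = counts[, "A"], count_C = counts[, "C"],
    count_G = counts[, "G"], count_T = counts[, "T"],
    depth = depth, alt_depth = alt_depth,
    alt_fraction = ifelse(depth > 0, alt_depth / depth, 0),
    zero_depth = depth == 0L,
    stringsAsFactors = FALSE
  )
  class(out) <- c("pileup_window", "data.frame")
  out
}

#' Global sequencing-error estimate from a pileup window
#'
#' Unweighted mean of the per-position alternative-allele fraction over all
#' covered positions, excluding the candidate edited position(s) so that true
#' editing signal does not inflate the error background.
#'
#' @param window A [build_pileup_window()] table.
#' @param exclude_positions Genome positions to leave out (the candidate
#'   edited sites).
#' @return Error probability in `[0, 1]`.
#' @export
estimate_global_error <- function(window, exclude_positions = integer(0)) {
  use <- window$depth > 0 & !(window$pos %in% exclude_positions)
  if (!any(use)) stop("no covered positions available for the global error estimate")
  mean(window$alt_fraction[use])
}

#' Position-dependent sequencing-error estimate from a control sample
#'
#' The alternative-allele fraction at one position of an untreated control
#' pileup. Returns `NA` (with a warning) when the control has no coverage at
#' that position, in which case callers fall back to the global estimate.
#'
#' @param control_window A [build_pileup_window()] table from a control
#'   (untreated) sample, or `NULL` when no control is available.
#' @param position Genome position.
#' @return Error probability, or `NA_real_` when unavailable.
#' @export
estimate_positional_error <- function(control_window, position) {
  if (is.null(control_window)) return(NA_real_)
  i <- match(position, control_window$pos)
  if (is.na(i)) stop("position ", position, " not covered by the control window")
  if (control_window$depth[i] == 0L) {
    warning("control has zero depth at position ", position,
            "; falling back to the global error estimate")
    return(NA_real_)
  }
  control_window$alt_fraction[i]
}

#' Call significant A>G / T>C conversion at target positions
#'
#' For each target position with reference base `A` (or `T` for the
#' opposite-strand readout), the conversion-specific alternative depth `k`
#' (reads showing `G` over an `A` reference, `C` over `T`) is tested against
#' the background error probability `p0 = max(global, positional)` with a
#' one-sided exact binomial test: `p = P(X >= k)`, `X ~ Binomial(n, p0)`.
#' A position is significant when `p < p_cutoff`. The editing rate `k/n` is
#' reported regardless of significance; zero-depth targets are emitted with
#' an undefined rate and `significant = FALSE`.
#'
#' @param window A [build_pileup_window()] table from the treated sample.
#' @param targets Genome positions of candidate edited bases.
#' @param global_err Global error probability from [estimate_global_error()].
#' @param positional_err Optional numeric vector (one per target, or a single
#'   value) of position-dependent error estimates; `NA` entries fall back to
#'   the global estimate alone.
#' @param config A [quant_config()].
#' @return Data.frame: `pos`, `ref`, `conversion`, `depth`, `alt_depth`,
#'   `rate`, `background`, `p_value`, `significant`.
#' @export
call_conversions <- function(window, targets, global_err, positional_err = NULL,
                             config = quant_config()) {
  if (is.null(positional_err)) positional_err <- rep(NA_real_, length(targets))
  positional_err <- rep_len(as.numeric(positional_err), length(targets))
  i <- match(targets, window$pos)
  if (anyNA(i)) {
    stop("target position(s) outside the pileup window: ",
         paste(targets[is.na(i)], collapse = ", "))
  }
  ref <- window$ref[i]
  bad <- !ref %in% c("A", "T")
  if (any(bad)) {
    stop("target position ", targets[bad][1], " has reference base ",
         ref[bad][1], "; conversion calling expects A or T")
  }
  k <- ifelse(ref == "A", window$count_G[i], window$count_C[i])
  n <- window$depth[i]
  p0 <- pmax(global_err, ifelse(is.na(positional_err), -Inf, positional_err))
  p <- ifelse(n > 0L, stats::pbinom(k - 1L, n, p0, lower.tail = FALSE), NA_real_)
  data.frame(
    pos = targets, ref = ref,
    conversion = ifelse(ref == "A", "A>G", "T>C"),
    depth = as.integer(n), alt_depth = as.integer(k),
    rate = ifelse(n > 0L, k / n, NA_real_),
    background = p0, p_value = p,
    significant = !is.na(p) & p < config$p_cutoff,
    stringsAsFactors = FALSE
  )
}
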