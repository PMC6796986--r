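#' Load mismatch-penalty weights for off-target scoring
#'
#' Reads the position-specific mismatch weight vector and penalty constants
#' from `inst/extdata/offtarget_weights.json` (or a user-supplied file with
#' the same schema). Position 1 is PAM-distal; PAM-proximal mismatches carry
#' larger weights because they disrupt Cas9 binding more.
#'
#' @param path Optional path to an alternative JSON config.
#' @return List with `weights` (length 20, values in `[0,1]`),
#'   `d_denominator`, `d_multiplier`, `d_offset` and `count_exponent`.
#' @export
default_mismatch_weights <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "offtarget_weights.json", package = "skipedit")
  }
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- as.numeric(cfg$weights)
  if (length(w) != 20L) stop("weight vector must have exactly 20 entries")
  if (any(w < 0 | w > 1)) stop("weights must be in [0,1]")
  list(weights = w,
       d_denominator = cfg$d_denominator, d_multiplier = cfg$d_multiplier,
       d_offset = cfg$d_offset, count_exponent = cfg$count_exponent)
}

#' Per-hit off-target score
#'
#' Position-weighted mismatch score of a single genomic near-match, scaled so
#' a perfect match scores 100. For `m >= 1` mismatches at protospacer
#' positions `p`:
#' \deqn{100 \prod_p (1 - w_p) \times
#'   \frac{1}{((19 - \bar d)/19) \cdot 4 + 1} \times \frac{1}{m^2}}
#' where \eqn{\bar d} is the mean pairwise distance between mismatch
#' positions. For a single mismatch the distance and count terms are 1, so
#' a mismatch with zero weight leaves the score at 100. Higher scores mean
#' the site is more likely to be cleaved, so specific guides have *low*
#' aggregate scores.
#'
#' @param mismatch_positions Sorted integer vector of protospacer positions
#'   (1-20) that differ; empty for a perfect match.
#' @param weights Config from [default_mismatch_weights()].
#' @return Score in `[0, 100]`.
#' @export
hit_score <- function(mismatch_positions, weights = default_mismatch_weights()) {
  m <- length(mismatch_positions)
  if (m == 0L) return(100)
  if (any(mismatch_positions < 1L | mismatch_positions > 20L)) {
    stop("mismatch positions must be in 1..20")
  }
  t1 <- prod(1 - weights$weights[mismatch_positions])
  if (m == 1L) return(100 * t1)
  dbar <- mean(stats::dist(mismatch_positions))
  t2 <- 1 / (((weights$d_denominator - dbar) / weights$d_denominator) *
               weights$d_multiplier + weights$d_offset)
  t3 <- 1 / m^weights$count_exponent
  100 * t1 * t2 * t3
}

empty_hits <- function() {
  data.frame(
    contig = character(0), strand = character(0), start = integer(0),
    end = integer(0), site = character(0), pam = character(0),
    n_mismatches = integer(0), mismatch_positions = character(0),
    hit_score = numeric(0), stringsAsFactors = FALSE
  )
}

pam_ok <- function(pam, include_nag) {
  if (grepl("N", pam, fixed = TRUE)) return(FALSE)
  tail2 <- substr(pam, 2, 3)
  tail2 == "GG" || (include_nag && tail2 == "AG")
}

#' Enumerate genome-wide off-target sites of a protospacer
#'
#' Scans both strands of every contig for 20-mers within `max_mismatches`
#' (Hamming distance, no indels) of the protospacer that are followed by an
#' NGG PAM (optionally also NAG). Sites whose protospacer or PAM contains `N`
#' are excluded. The candidate search uses
#' [Biostrings::matchPattern()] with `max.mismatch`; tests cross-check the
#' result against a direct brute-force Hamming scan.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param protospacer 20-nt guide sequence.
#' @param max_mismatches Maximum Hamming distance (default 2).
#' @param include_nag Accept NAG PAMs as well as NGG.
#' @param weights Scoring config from [default_mismatch_weights()].
#' @return Hit data.frame: `contig`, `strand`, `start`/`end` (1-based genome
#'   coordinates of the 20-mer in `+` orientation), `site` and `pam` read in
#'   guide orientation, `n_mismatches`, comma-joined `mismatch_positions`,
#'   `hit_score`.
#' @export
enumerate_offtargets <- function(genome, protospacer, max_mismatches = 2L,
                                 include_nag = FALSE,
                                 weights = default_mismatch_weights()) {
  if (nchar(protospacer) != 20L) stop("protospacer must be 20 nt")
  pat <- Biostrings::DNAString(protospacer)
  proto_chars <- strsplit(protospacer, "")[[1]]
  rows <- list()
  for (ctg in names(genome)) {
    subj <- genome[[ctg]]
    len <- length(subj)
    for (strand in c("+", "-")) {
      scan_seq <- if (strand == "+") subj else Biostrings::reverseComplement(subj)
      m <- Biostrings::matchPattern(pat, scan_seq, max.mismatch = max_mismatches,
                                    with.indels = FALSE, fixed = TRUE)
      if (length(m) == 0L) next
      starts <- Biostrings::start(m)
      scan_chr <- as.character(scan_seq)
      for (s in starts) {
        if (s + 22L > len) next  # PAM would run off the contig
        site <- substr(scan_chr, s, s + 19L)
        pam <- substr(scan_chr, s + 20L, s + 22L)
        if (grepl("N", site, fixed = TRUE) || !pam_ok(pam, include_nag)) next
        mm <- which(strsplit(site, "")[[1]] != proto_chars)
        if (length(mm) > max_mismatches) next
        g_start <- if (strand == "+") s else len - s - 18L
        rows[[length(rows) + 1L]] <- data.frame(
          contig = ctg, strand = strand, start = g_start, end = g_start + 19L,
          site = site, pam = pam, n_mismatches = length(mm),
          mismatch_positions = paste(mm, collapse = ","),
          hit_score = hit_score(mm, weights),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) return(empty_hits())
  out <- do.call(rbind, rows)
  out <- out[order(out$contig, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate off-target score of a guide
#'
#' Sum of [hit_score()] over every enumerated site except the design locus
#' itself. A guide with no off-target near-matches scores 0; a perfect
#' duplicate of the protospacer elsewhere contributes 100 on its own.
#' Guides with aggregate score above 10 are conventionally removed.
#'
#' @param hits Table from [enumerate_offtargets()] for a single guide.
#' @param on_target List with `contig`, `start` and `strand` of the design
#'   locus; it must be present among `hits` (otherwise the scan and the
#'   design disagree and an error is raised).
#' @return Non-negative aggregate score.
#' @export
aggregate_offtarget_score <- function(hits, on_target) {
  is_on <- hits$contig == on_target$contig &
    hits$start == on_target$start &
    hits$strand == on_target$strand
  if (sum(is_on) != 1L) {
    stop("on-target site not found (or found multiply) in hit table; scan/locus mismatch")
  }
  sum(hits$hit_score[!is_on])
}
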