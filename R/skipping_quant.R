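#' Junction probes for one skippable exon
#'
#' Builds the three splice-junction probe sequences used to classify RNA
#' reads: the exon-skipped junction (3' end of the upstream exon joined to
#' the 5' start of the downstream exon) and the two canonical junctions
#' (upstream->target and target->downstream), each with `anchor` bp of exonic
#' sequence on either side, assembled in transcript orientation. When the
#' exon is inner in several transcripts with different flanking exons, one
#' probe set is built per context and deduplicated.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param transcripts Exon table from [read_annotation()].
#' @param key Exon key (`contig:start-end:strand`) of the target exon.
#' @param anchor Exonic bp on each side of a junction (default 10).
#' @return A `junction_set` list: `exon_key`, `anchor`, `skipped`,
#'   `canonical_5p`, `canonical_3p` (character vectors, one entry per
#'   flanking context).
#' @export
build_junction_set <- function(genome, transcripts, key, anchor = 10L) {
  anchor <- as.integer(anchor)
  stopifnot(anchor >= 1L)
  contexts <- list()
  for (tx in split(transcripts, transcripts$transcript_id)) {
    tx <- tx[order(tx$exon_rank), , drop = FALSE]
    keys <- exon_key(tx$contig, tx$start, tx$end, tx$strand)
    i <- which(keys == key)
    for (j in i) {
      if (j <= 1L || j >= nrow(tx)) next  # terminal in this transcript
      contexts[[length(contexts) + 1L]] <- tx[(j - 1L):(j + 1L), , drop = FALSE]
    }
  }
  if (length(contexts) == 0L) {
    stop("exon ", key, " has no transcript context with both flanking exons")
  }
  exon_seq <- function(e) {
    extract_sequence(genome, e$contig, e$start, e$end, e$strand)
  }
  probes <- lapply(contexts, function(ctx) {
    up <- exon_seq(ctx[1, ]); tg <- exon_seq(ctx[2, ]); dn <- exon_seq(ctx[3, ])
    if (nchar(up) < anchor || nchar(dn) < anchor || nchar(tg) < anchor) {
      stop("anchor ", anchor, " exceeds an exon length for ", key,
           "; use a smaller anchor")
    }
    last_a <- function(s) substr(s, nchar(s) - anchor + 1L, nchar(s))
    first_a <- function(s) substr(s, 1L, anchor)
    list(skipped = paste0(last_a(up), first_a(dn)),
         canonical_5p = paste0(last_a(up), first_a(tg)),
         canonical_3p = paste0(last_a(tg), first_a(dn)))
  })
  skipped <- unique(vapply(probes, `[[`, "", "skipped"))
  c5 <- unique(vapply(probes, `[[`, "", "canonical_5p"))
  c3 <- unique(vapply(probes, `[[`, "", "canonical_3p"))
  if (any(skipped %in% c(c5, c3))) {
    stop("skipped and canonical junction probes coincide for ", key,
         "; anchor ", anchor, " is too short to distinguish the isoforms")
  }
  structure(list(exon_key = key, anchor = anchor, skipped = skipped,
                 canonical_5p = c5, canonical_3p = c3),
            class = "junction_set")
}

probe_hit <- function(reads, probe, max_mismatches) {
  hit <- rep(FALSE, length(reads))
  for (orient in c(probe, revcomp(probe))) {
    if (max_mismatches == 0L) {
      hit <- hit | grepl(orient, reads, fixed = TRUE)
    } else {
      m <- Biostrings::vcountPattern(orient, Biostrings::DNAStringSet(reads),
                                     max.mismatch = max_mismatches,
                                     with.indels = FALSE, fixed = TRUE)
      hit <- hit | m > 0L
    }
  }
  hit
}

#' Classify RNA reads by splice junction and compute the skipping rate
#'
#' Each read (mates are treated as independent single reads) containing the
#' exon-skipped junction probe, in either orientation, counts toward the
#' skipped isoform; a read containing the 5' or 3' canonical junction counts
#' toward the canonical isoform; reads containing both probe classes are
#' ambiguous and excluded, as are reads containing neither. The skipping rate
#' is `skipped / (skipped + canonical)`, undefined (NA, flagged) when no
#' junction reads are present.
#'
#' @param reads Character vector of read sequences.
#' @param junction_set A [build_junction_set()].
#' @param max_mismatches Mismatch tolerance of probe matching (default 0,
#'   exact substring).
#' @return A `junction_counts` list: `skipped_reads`, `canonical_reads`,
#'   `excluded_reads`, `skipping_rate`.
#' @export
classify_reads <- function(reads, junction_set, max_mismatches = 0L) {
  reads <- toupper(as.character(reads))
  skip_hit <- rep(FALSE, length(reads))
  for (p in junction_set$skipped) skip_hit <- skip_hit | probe_hit(reads, p, max_mismatches)
  can_hit <- rep(FALSE, length(reads))
  for (p in c(junction_set$canonical_5p, junction_set$canonical_3p)) {
    can_hit <- can_hit | probe_hit(reads, p, max_mismatches)
  }
  skipped <- sum(skip_hit & !can_hit)
  canonical <- sum(can_hit & !skip_hit)
  excluded <- length(reads) - skipped - canonical
  rate <- if (skipped + canonical > 0L) skipped / (skipped + canonical) else NA_real_
  structure(list(skipped_reads = skipped, canonical_reads = canonical,
                 excluded_reads = excluded, skipping_rate = rate),
            class = "junction_counts")
}

#' Average replicate skipping rates
#'
#' Unweighted arithmetic mean over biological replicates; replicates with an
#' undefined rate (no junction-spanning reads) are dropped with a warning.
#'
#' @param rates Numeric vector of per-replicate skipping rates.
#' @return Overall skipping rate.
#' @export
average_replicates <- function(rates) {
  if (length(rates) == 0L) stop("no replicate rates supplied")
  if (anyNA(rates)) {
    warning(sum(is.na(rates)), " replicate(s) with undefined rate excluded from the average")
    rates <- rates[!is.na(rates)]
  }
  if (length(rates) == 0L) stop("all replicate rates are undefined")
  mean(rates)
}

#' Percent exon skipping from gel band densitometry
#'
#' Computes `100 * skipped / (wt + skipped)` from background-subtracted band
#' intensities (each intensity the sum of pixel grayscale values over the
#' band area).
#'
#' @param skipped_intensity,wt_intensity Non-negative band intensities of the
#'   exon-skipped and wild-type RT-PCR products.
#' @return Percent exon skipping in `[0, 100]`.
#' @export
percent_skipping_from_bands <- function(skipped_intensity, wt_intensity) {
  if (skipped_intensity < 0 || wt_intensity < 0) stop("band intensities must be non-negative")
  if (skipped_intensity + wt_intensity == 0) stop("both band intensities are zero")
  100 * skipped_intensity / (wt_intensity + skipped_intensity)
}
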