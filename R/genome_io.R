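#' Read a genome FASTA into a validated DNAStringSet
#'
#' Loads every record of a (possibly line-wrapped) multi-record FASTA file.
#' Sequences are normalized to uppercase and restricted to the alphabet
#' `A/C/G/T/N`; contig names are truncated at the first whitespace of the
#' header line.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by contig.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("FASTA file contains no records: ", path)
  nm <- sub("\\s.*$", "", names(raw))
  dup <- nm[duplicated(nm)]
  if (length(dup) > 0L) {
    stop("duplicate contig name(s) in FASTA: ", paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(raw))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for contig(s): ", paste(nm[!nzchar(seqs)], collapse = ", "))
  }
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("non-IUPAC character '%s' in contig '%s' at position %d",
                 substr(seqs[i], bad[i], bad[i]), nm[i], bad[i]))
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- nm
  out
}

#' Read transcript models from a GTF annotation
#'
#' Parses exon features from a GENCODE-dialect GTF and returns one row per
#' exon, grouped by transcript and ordered 5'->3' in transcript orientation
#' (ascending genome coordinate on `+`, descending on `-`). Coordinates stay
#' 1-based inclusive, the GTF and Bioconductor convention. Transcript biotype
#' is taken from the `transcript_type` attribute, falling back to `gene_type`
#' (GENCODE keys); transcripts not matching `biotype_filter` are dropped.
#'
#' @param path Path to a GTF file.
#' @param biotype_filter Biotype to retain; `NULL` keeps everything.
#' @return A data.frame with columns `transcript_id`, `gene_id`, `contig`,
#'   `strand`, `start`, `end`, `exon_rank` (1 = 5'-most exon of the
#'   transcript) and `biotype`.
#' @export
read_annotation <- function(path, biotype_filter = "protein_coding") {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon features in GTF: ", path)
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$transcript_id) || anyNA(mc$transcript_id)) {
    stop("exon feature without transcript_id attribute")
  }
  if (is.null(mc$gene_id) || anyNA(mc$gene_id)) {
    stop("exon feature without gene_id attribute")
  }
  biotype <- if (!is.null(mc$transcript_type)) {
    mc$transcript_type
  } else if (!is.null(mc$gene_type)) {
    mc$gene_type
  } else {
    rep(NA_character_, length(gr))
  }
  df <- data.frame(
    transcript_id = as.character(mc$transcript_id),
    gene_id = as.character(mc$gene_id),
    contig = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    biotype = as.character(biotype),
    stringsAsFactors = FALSE
  )
  if (!is.null(biotype_filter)) {
    df <- df[!is.na(df$biotype) & df$biotype == biotype_filter, , drop = FALSE]
  }
  if (nrow(df) == 0L) return(cbind(df[0, ], exon_rank = integer(0)))
  validate_transcripts(df)
  out <- do.call(rbind, lapply(split(df, df$transcript_id), function(tx) {
    ord <- order(tx$start, decreasing = tx$strand[1] == "-")
    tx <- tx[ord, , drop = FALSE]
    tx$exon_rank <- seq_len(nrow(tx))
    tx
  }))
  rownames(out) <- NULL
  out
}

validate_transcripts <- function(df) {
  for (tx in split(df, df$transcript_id)) {
    if (length(unique(tx$contig)) != 1L || length(unique(tx$strand)) != 1L) {
      stop("transcript ", tx$transcript_id[1], " spans multiple contigs or strands")
    }
    if (any(!tx$strand %in% c("+", "-"))) {
      stop("transcript ", tx$transcript_id[1], " has unstranded exon(s)")
    }
    if (any(tx$end < tx$start)) {
      stop("transcript ", tx$transcript_id[1], " has an exon with end < start")
    }
    o <- order(tx$start)
    if (nrow(tx) > 1L && any(tx$start[o][-1] <= tx$end[o][-nrow(tx)])) {
      stop("overlapping exons within transcript ", tx$transcript_id[1])
    }
  }
  invisible(TRUE)
}

exon_key <- function(contig, start, end, strand) {
  sprintf("%s:%d-%d:%s", contig, start, end, strand)
}

#' Enumerate inner exons and their splice-acceptor coordinates
#'
#' An exon is *inner* when it is neither the first nor the last exon of a
#' transcript; only inner exons have an upstream splice acceptor and a
#' downstream donor and are therefore skippable. Exons are deduplicated by
#' genomic identity `(contig, start, end, strand)`; the transcripts in which
#' the exon is non-terminal are recorded. The conserved acceptor dinucleotide
#' sits in the intron immediately 5' of the exon (transcript orientation):
#' on `+` the G is at `start - 1` and the A at `start - 2`; on `-` the G is
#' at `end + 1` and the A at `end + 2` (1-based genome coordinates).
#'
#' @param transcripts Exon table from [read_annotation()].
#' @return A data.frame with one row per unique inner exon: `exon_key`,
#'   `contig`, `strand`, `start`, `end`, `gene_ids`,
#'   `supporting_transcripts` (comma-joined), `acceptor_A_pos`,
#'   `acceptor_G_pos`.
#' @export
enumerate_inner_exons <- function(transcripts) {
  empty <- data.frame(
    exon_key = character(0), contig = character(0), strand = character(0),
    start = integer(0), end = integer(0), gene_ids = character(0),
    supporting_transcripts = character(0),
    acceptor_A_pos = integer(0), acceptor_G_pos = integer(0),
    stringsAsFactors = FALSE
  )
  if (is.null(transcripts) || nrow(transcripts) == 0L) return(empty)
  inner <- do.call(rbind, lapply(split(transcripts, transcripts$transcript_id), function(tx) {
    n <- nrow(tx)
    if (n < 3L) return(NULL)
    tx[order(tx$exon_rank), , drop = FALSE][2:(n - 1L), , drop = FALSE]
  }))
  if (is.null(inner) || nrow(inner) == 0L) return(empty)
  inner$exon_key <- exon_key(inner$contig, inner$start, inner$end, inner$strand)
  agg <- lapply(split(inner, inner$exon_key), function(e) {
    data.frame(
      exon_key = e$exon_key[1], contig = e$contig[1], strand = e$strand[1],
      start = e$start[1], end = e$end[1],
      gene_ids = paste(sort(unique(e$gene_id)), collapse = ","),
      supporting_transcripts = paste(sort(unique(e$transcript_id)), collapse = ","),
      acceptor_A_pos = if (e$strand[1] == "+") e$start[1] - 2L else e$end[1] + 2L,
      acceptor_G_pos = if (e$strand[1] == "+") e$start[1] - 1L else e$end[1] + 1L,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$contig, out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Check splice acceptors against the genome
#'
#' Reads the acceptor dinucleotide of each inner exon in transcript
#' orientation and flags canonical (`AG`) acceptors. Non-canonical acceptors
#' are retained with `canonical_acceptor = FALSE` rather than dropped, so
#' they remain auditable; guide design skips them by default. Acceptors whose
#' dinucleotide falls outside the contig, or contains `N`, are flagged
#' non-canonical as well.
#'
#' @param inner_exons Table from [enumerate_inner_exons()].
#' @param genome A [Biostrings::DNAStringSet] from [read_fasta()].
#' @return `inner_exons` with added `acceptor_dinucleotide` and
#'   `canonical_acceptor` columns.
#' @export
check_acceptors <- function(inner_exons, genome) {
  n <- nrow(inner_exons)
  dinuc <- character(n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    ctg <- inner_exons$contig[i]
    len <- contig_length(genome, ctg)
    a <- inner_exons$acceptor_A_pos[i]
    g <- inner_exons$acceptor_G_pos[i]
    lo <- min(a, g); hi <- max(a, g)
    if (lo < 1L || hi > len) {
      dinuc[i] <- NA_character_
      ok[i] <- FALSE
      next
    }
    dinuc[i] <- extract_sequence(genome, ctg, lo, hi, inner_exons$strand[i])
    ok[i] <- identical(dinuc[i], "AG")
  }
  inner_exons$acceptor_dinucleotide <- dinuc
  inner_exons$canonical_acceptor <- ok
  inner_exons
}

contig_length <- function(genome, contig) {
  if (!contig %in% names(genome)) stop("contig not in genome: ", contig)
  length(genome[[contig]])
}

#' Extract genomic sequence with strand handling
#'
#' Returns the 1-based inclusive slice `[start, end]` of a contig; for
#' `strand = "-"` the reverse complement is returned, i.e. the sequence read
#' in transcript orientation of a minus-strand feature.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param contig Contig name.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @return A character scalar.
#' @export
extract_sequence <- function(genome, contig, start, end, strand = "+") {
  len <- contig_length(genome, contig)
  if (start < 1L || end > len || start > end) {
    stop(sprintf("range [%d,%d] out of bounds for contig %s (length %d)",
                 start, end, contig, len))
  }
  s <- Biostrings::subseq(genome[[contig]], start, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Reverse complement of a DNA string
#'
#' @param x Character scalar or vector over `A/C/G/T/N`.
#' @return Reverse complement(s) of `x`.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
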