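# Independent brute-force oracles and tiny fixture builders. These
# deliberately re-derive results from raw strings, not through the package's
# search code paths.

# All guide placements for one acceptor, by scanning every 20-mer adjacent to
# an NGG on the relevant strand of the raw sequence.
brute_force_guides <- function(genome, inner_row, mode, window) {
  contig_chr <- as.character(genome[[inner_row$contig]])
  len <- nchar(contig_chr)
  if (mode == "ABE") {
    scan_strand <- inner_row$strand
    target_genome <- inner_row$acceptor_A_pos
    target_base <- "A"
  } else {
    scan_strand <- if (inner_row$strand == "+") "-" else "+"
    target_genome <- inner_row$acceptor_G_pos
    target_base <- "C"
  }
  sense <- if (scan_strand == "+") contig_chr else revcomp(contig_chr)
  t_idx <- if (scan_strand == "+") target_genome else len - target_genome + 1L
  found <- list()
  for (p in window) {
    st <- t_idx - (p - 1L)
    if (st < 1L || st + 22L > len) next
    s23 <- substr(sense, st, st + 22L)
    if (grepl("N", s23, fixed = TRUE)) next
    if (substr(s23, p, p) != target_base) next
    if (substr(s23, 22L, 23L) != "GG") next
    found[[length(found) + 1L]] <- data.frame(
      mode = mode, position = p,
      protospacer = substr(s23, 1L, 20L), pam = substr(s23, 21L, 23L),
      guide_strand = scan_strand, stringsAsFactors = FALSE
    )
  }
  if (length(found) == 0L) {
    return(data.frame(mode = character(0), position = integer(0),
                      protospacer = character(0), pam = character(0),
                      guide_strand = character(0)))
  }
  do.call(rbind, found)
}

# Direct Hamming-distance scan over every NGG-adjacent 20-mer of the genome.
brute_force_offtargets <- function(genome, protospacer, max_mm = 2L) {
  pr <- strsplit(protospacer, "")[[1]]
  rows <- list()
  for (ctg in names(genome)) {
    plus <- as.character(genome[[ctg]])
    len <- nchar(plus)
    if (len < 23L) next
    for (strand in c("+", "-")) {
      s <- if (strand == "+") plus else revcomp(plus)
      i <- seq_len(len - 22L)
      sites <- substring(s, i, i + 19L)
      pams <- substring(s, i + 20L, i + 22L)
      cand <- which(substr(pams, 2, 3) == "GG" &
                      !grepl("N", sites) & !grepl("N", pams))
      for (j in cand) {
        mm <- which(strsplit(sites[j], "")[[1]] != pr)
        if (length(mm) > max_mm) next
        g_start <- if (strand == "+") j else len - j - 18L
        rows[[length(rows) + 1L]] <- data.frame(
          contig = ctg, strand = strand, start = g_start,
          site = sites[j], n_mismatches = length(mm),
          mismatch_positions = paste(mm, collapse = ","),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(contig = character(0), strand = character(0),
                      start = integer(0), site = character(0),
                      n_mismatches = integer(0),
                      mismatch_positions = character(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$contig, out$start, out$strand), , drop = FALSE]
}

# Hand transcription of the per-hit scoring formula, kept separate from
# hit_score() so the two can disagree.
oracle_hit_score <- function(mm, w) {
  if (length(mm) == 0L) return(100)
  base <- 100
  for (p in mm) base <- base * (1 - w[p])
  if (length(mm) == 1L) return(base)
  dsum <- 0; npair <- 0
  for (a in seq_along(mm)) {
    for (b in seq_along(mm)) {
      if (b > a) { dsum <- dsum + abs(mm[b] - mm[a]); npair <- npair + 1 }
    }
  }
  dbar <- dsum / npair
  base * (1 / (((19 - dbar) / 19) * 4 + 1)) * (1 / length(mm)^2)
}

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Minimal GTF exon line in GENCODE dialect.
gtf_line <- function(contig, start, end, strand, tx, gene = "G1",
                     biotype = "protein_coding") {
  paste(contig, "test", "exon", start, end, ".", strand, ".",
        sprintf('gene_id "%s"; transcript_id "%s"; transcript_type "%s";',
                gene, tx, biotype),
        sep = "\t")
}

# FASTQ with explicit quality strings (Phred+33).
fastq_lines <- function(ids, seqs, quals) {
  as.vector(rbind(paste0("@", ids), seqs, "+", quals))
}

# Fixture genome + annotation + design truth, shared across tests.
toy_bundle <- function(spec) {
  fx <- make_toy_genome(spec)
  gtf_path <- write_lines_tmp(fx$gtf, ".gtf")
  tx <- read_annotation(gtf_path)
  inner <- check_acceptors(enumerate_inner_exons(tx), fx$genome)
  list(fx = fx, genome = fx$genome, transcripts = tx, inner = inner)
}
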