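# Deterministic synthetic fixtures: toy genomes with planted splice acceptors
# and PAMs, amplicon reads with a known conversion rate, and RNA reads drawn
# from a two-isoform mixture. Every generator records exact ground truth so
# downstream modules can be tested without external data.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Random DNA with no GG or CC dinucleotide anywhere. Scrubbing homotypic
# G/C pairs removes every NGG PAM (both strands) from the background, so the
# only PAMs in a fixture genome are the ones planted on purpose.
sample_no_gg <- function(n, last = "") {
  if (n == 0L) return("")
  bases <- c("A", "C", "G", "T")
  pools <- list(G = c("A", "C", "T"), C = c("A", "G", "T"))
  u <- stats::runif(n)
  out <- character(n)
  for (i in seq_len(n)) {
    pool <- if (last %in% c("G", "C")) pools[[last]] else bases
    out[i] <- pool[ceiling(u[i] * length(pool))]
    last <- out[i]
  }
  paste(out, collapse = "")
}

#' Specification of a synthetic fixture set
#'
#' Defines the toy-genome layout and the simulation parameters shared by the
#' fixture generators. Genes alternate between `+` and `-` strands; every
#' non-first exon gets a canonical intronic `AG` acceptor; for each inner
#' exon, PAMs are planted so the acceptor target base sits at a requested
#' protospacer window position for ABE (NGG in the exon) and/or BE3 (a CC on
#' the sense strand in the intron, i.e. NGG on the antisense strand). The
#' background sequence contains no GG/CC dinucleotides, so planted PAMs are
#' the only PAMs.
#'
#' @param seed Integer seed driving all randomness of the generators.
#' @param n_genes Number of genes (one transcript each).
#' @param exons_per_gene Exons per transcript (>= 3 gives inner exons).
#' @param exon_length,intron_length,flank_length Segment lengths in bp.
#' @param plant Editor plant per inner exon, cycled: `"ABE"`, `"BE3"` or
#'   `"both"`.
#' @param abe_positions,be3_positions Window positions cycled over planted
#'   inner exons.
#' @param editing_rate True per-fragment conversion rate of the amplicon
#'   simulator.
#' @param sequencing_error Per-base substitution probability, uniform over
#'   the three alternative bases.
#' @param read_length,depth Amplicon read length and fragment count.
#' @param skip_fraction True exon-skipped isoform fraction of the RNA
#'   simulator.
#' @param n_junction_reads,n_background_reads RNA junction-spanning and
#'   exon-interior read counts.
#' @param rna_read_length RNA read length (must not exceed `exon_length`).
#' @param anchor Junction-probe anchor used when placing RNA reads.
#' @param planted_offtargets Optional data.frame (`guide`, `n_mismatches`,
#'   `strand`) planting near-match copies of truth guides (by row index) on a
#'   separate decoy contig.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_genes = 6L, exons_per_gene = 4L,
                         exon_length = 80L, intron_length = 120L,
                         flank_length = 60L,
                         plant = c("ABE", "BE3", "both"),
                         abe_positions = 4:9, be3_positions = 4:8,
                         editing_rate = 0.05, sequencing_error = 0.002,
                         read_length = 150L, depth = 1000L,
                         skip_fraction = 0.25, n_junction_reads = 2000L,
                         n_background_reads = 500L, rna_read_length = 60L,
                         anchor = 10L, planted_offtargets = NULL) {
  stopifnot(exons_per_gene >= 3L, exon_length >= 30L, intron_length >= 30L,
            editing_rate >= 0, editing_rate <= 1,
            sequencing_error >= 0, sequencing_error <= 1,
            skip_fraction >= 0, skip_fraction <= 1,
            rna_read_length <= exon_length)
  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    exon_length = as.integer(exon_length),
    intron_length = as.integer(intron_length),
    flank_length = as.integer(flank_length),
    plant = plant, abe_positions = as.integer(abe_positions),
    be3_positions = as.integer(be3_positions),
    editing_rate = editing_rate, sequencing_error = sequencing_error,
    read_length = as.integer(read_length), depth = as.integer(depth),
    skip_fraction = skip_fraction,
    n_junction_reads = as.integer(n_junction_reads),
    n_background_reads = as.integer(n_background_reads),
    rna_read_length = as.integer(rna_read_length), anchor = as.integer(anchor),
    planted_offtargets = planted_offtargets
  ), class = "fixture_spec")
}

mutate_at <- function(s, pos, base) {
  substr(s, pos, pos) <- base
  s
}

# Build one gene in transcript orientation. Returns the local sequence,
# local exon coordinates and the planted-guide bookkeeping.
build_gene_local <- function(spec, gene_idx, plant_state) {
  ex_len <- spec$exon_length; in_len <- spec$intron_length
  segs <- character(0)
  last <- ""
  add <- function(s) { segs <<- c(segs, s); last <<- substr(s, nchar(s), nchar(s)) }
  add(sample_no_gg(spec$flank_length, last))
  exon_local <- matrix(0L, nrow = spec$exons_per_gene, ncol = 2)
  pos <- spec$flank_length
  for (e in seq_len(spec$exons_per_gene)) {
    if (e > 1L) {
      intron <- paste0(sample_no_gg(in_len - 2L, last), "AG")
      add(intron)
      pos <- pos + in_len
      last <- "G"
    }
    add(sample_no_gg(ex_len, last))
    exon_local[e, ] <- c(pos + 1L, pos + ex_len)
    pos <- pos + ex_len
  }
  add(sample_no_gg(spec$flank_length, last))
  seq_local <- paste(segs, collapse = "")

  plants <- list()
  for (e in 2:(spec$exons_per_gene - 1L)) {
    which_plant <- spec$plant[(plant_state$k %% length(spec$plant)) + 1L]
    modes <- if (which_plant == "both") c("ABE", "BE3") else which_plant
    a_loc <- exon_local[e, 1] - 2L  # acceptor A, transcript orientation
    g_loc <- exon_local[e, 1] - 1L  # acceptor G
    for (mode in modes) {
      if (mode == "ABE") {
        p <- spec$abe_positions[(plant_state$ka %% length(spec$abe_positions)) + 1L]
        plant_state$ka <- plant_state$ka + 1L
        # NGG PAM at protospacer positions 21-23; flanks guarded against
        # shifted-PAM readings
        seq_local <- mutate_at(seq_local, a_loc + 21L - p, "T")
        seq_local <- mutate_at(seq_local, a_loc + 22L - p, "G")
        seq_local <- mutate_at(seq_local, a_loc + 23L - p, "G")
        seq_local <- mutate_at(seq_local, a_loc + 24L - p, "A")
      } else {
        p <- spec$be3_positions[(plant_state$kb %% length(spec$be3_positions)) + 1L]
        plant_state$kb <- plant_state$kb + 1L
        # CC on the sense strand reads as an NGG PAM on the antisense strand
        seq_local <- mutate_at(seq_local, g_loc - (24L - p), "T")
        seq_local <- mutate_at(seq_local, g_loc - (23L - p), "C")
        seq_local <- mutate_at(seq_local, g_loc - (22L - p), "C")
        seq_local <- mutate_at(seq_local, g_loc - (21L - p), "A")
      }
      plants[[length(plants) + 1L]] <- list(exon_idx = e, mode = mode, position = p)
    }
    plant_state$k <- plant_state$k + 1L
  }
  list(seq = seq_local, exons = exon_local, plants = plants, state = plant_state)
}

# Truth protospacer/PAM strings from the gene-local (transcript-orientation)
# sequence; independent bookkeeping, not a call into the design code.
local_guide_truth <- function(seq_local, exon_start_local, mode, p) {
  a <- exon_start_local - 2L
  g <- exon_start_local - 1L
  if (mode == "ABE") {
    list(protospacer = substr(seq_local, a - (p - 1L), a + (20L - p)),
         pam = substr(seq_local, a + (21L - p), a + (23L - p)))
  } else {
    proto <- revcomp(substr(seq_local, g - (20L - p), g + (p - 1L)))
    pam <- revcomp(substr(seq_local, g + p - 23L, g + p - 21L))
    list(protospacer = proto, pam = pam)
  }
}

#' Generate a toy genome with planted splice acceptors, PAMs and off-targets
#'
#' Emits a genome (one gene contig, plus a decoy contig when off-target
#' copies are planted), a GENCODE-dialect GTF with one protein-coding
#' transcript per gene, and exact truth tables: every planted guide candidate
#' (exon, mode, window position, protospacer, PAM, guide strand, genomic
#' footprint) and every planted off-target site. With a fixed seed the
#' emitted files are byte-identical across runs.
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional directory; when given, writes `genome.fa`,
#'   `annotation.gtf`, `truth_guides.tsv` (and `truth_offtargets.tsv`).
#' @return List with `genome` ([Biostrings::DNAStringSet]), `gtf` (character
#'   lines), `truth_guides` (data.frame), `truth_offtargets` (data.frame or
#'   NULL) and `paths` (when `dir` given).
#' @export
make_toy_genome <- function(spec, dir = NULL) {
  with_seed(spec$seed, {
    state <- list(k = 0L, ka = 0L, kb = 0L)
    contig <- "chrT"
    blocks <- character(spec$n_genes)
    gtf <- character(0)
    truth <- list()
    offset <- 0L
    spacer <- 50L
    for (g in seq_len(spec$n_genes)) {
      strand <- if (g %% 2L == 1L) "+" else "-"
      built <- build_gene_local(spec, g, state)
      state <- built$state
      L <- nchar(built$seq)
      placed <- if (strand == "+") built$seq else revcomp(built$seq)
      lead <- sample_no_gg(spacer, "")
      blocks[g] <- paste0(lead, placed)
      block_start <- offset + spacer  # genome offset of the gene block
      # genome coordinates of each exon
      ex <- built$exons
      gstart <- integer(nrow(ex)); gend <- integer(nrow(ex))
      for (e in seq_len(nrow(ex))) {
        if (strand == "+") {
          gstart[e] <- block_start + ex[e, 1]
          gend[e] <- block_start + ex[e, 2]
        } else {
          gstart[e] <- block_start + L - ex[e, 2] + 1L
          gend[e] <- block_start + L - ex[e, 1] + 1L
        }
      }
      for (e in order(gstart)) {
        gtf <- c(gtf, paste(
          contig, "skipedit_fixture", "exon", gstart[e], gend[e], ".", strand, ".",
          sprintf('gene_id "G%d"; transcript_id "TX%d"; transcript_type "protein_coding"; gene_type "protein_coding";',
                  g, g),
          sep = "\t"
        ))
      }
      for (pl in built$plants) {
        tr <- local_guide_truth(built$seq, built$exons[pl$exon_idx, 1], pl$mode, pl$position)
        a_loc <- built$exons[pl$exon_idx, 1] - 2L
        g_loc <- built$exons[pl$exon_idx, 1] - 1L
        # local footprint of the 20-mer, transcript orientation
        if (pl$mode == "ABE") {
          lo_loc <- a_loc - (pl$position - 1L); hi_loc <- a_loc + (20L - pl$position)
          guide_strand <- strand
          target_loc <- a_loc
        } else {
          lo_loc <- g_loc - (20L - pl$position); hi_loc <- g_loc + (pl$position - 1L)
          guide_strand <- if (strand == "+") "-" else "+"
          target_loc <- g_loc
        }
        if (strand == "+") {
          proto_start <- block_start + lo_loc
          proto_end <- block_start + hi_loc
          target_genome <- block_start + target_loc
        } else {
          proto_start <- block_start + L - hi_loc + 1L
          proto_end <- block_start + L - lo_loc + 1L
          target_genome <- block_start + L - target_loc + 1L
        }
        truth[[length(truth) + 1L]] <- data.frame(
          exon_key = exon_key(contig, gstart[pl$exon_idx], gend[pl$exon_idx], strand),
          gene_id = sprintf("G%d", g), mode = pl$mode,
          position = pl$position,
          protospacer = tr$protospacer, pam = tr$pam,
          guide_strand = guide_strand, contig = contig,
          proto_start = proto_start, proto_end = proto_end,
          target_genome_pos = target_genome,
          stringsAsFactors = FALSE
        )
      }
      offset <- offset + spacer + L
    }
    tail_pad <- sample_no_gg(spacer, "")
    genome_seq <- paste0(paste(blocks, collapse = ""), tail_pad)
    truth_guides <- do.call(rbind, truth)
    seqs <- c(chrT = genome_seq)

    truth_ot <- NULL
    if (!is.null(spec$planted_offtargets) && nrow(spec$planted_offtargets) > 0L) {
      po <- spec$planted_offtargets
      decoy <- sample_no_gg(40L, "")
      rows <- list()
      for (i in seq_len(nrow(po))) {
        gd <- truth_guides[po$guide[i], ]
        site <- gd$protospacer
        mm <- integer(0)
        if (po$n_mismatches[i] > 0L) {
          mm <- sort(sample(1:20, po$n_mismatches[i]))
          for (p in mm) {
            orig <- substr(site, p, p)
            site <- mutate_at(site, p, sample(setdiff(c("A", "C", "G", "T"), orig), 1L))
          }
        }
        insert <- paste0(site, "TGG")
        strand_i <- if (!is.null(po$strand)) po$strand[i] else "+"
        placed <- if (strand_i == "+") insert else revcomp(insert)
        pad <- sample_no_gg(20L, substr(decoy, nchar(decoy), nchar(decoy)))
        start_in_decoy <- nchar(decoy) + nchar(pad) + 1L
        decoy <- paste0(decoy, pad, placed)
        site_start <- if (strand_i == "+") start_in_decoy else start_in_decoy + 3L
        rows[[i]] <- data.frame(
          guide = po$guide[i], contig = "decoy", strand = strand_i,
          start = site_start, end = site_start + 19L,
          site = site, pam = "TGG", n_mismatches = length(mm),
          mismatch_positions = paste(mm, collapse = ","),
          stringsAsFactors = FALSE
        )
      }
      decoy <- paste0(decoy, sample_no_gg(40L, substr(decoy, nchar(decoy), nchar(decoy))))
      seqs <- c(seqs, decoy = decoy)
      truth_ot <- do.call(rbind, rows)
    }

    genome <- Biostrings::DNAStringSet(seqs)
    out <- list(genome = genome, gtf = gtf, truth_guides = truth_guides,
                truth_offtargets = truth_ot)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      paths <- list(
        genome = file.path(dir, "genome.fa"),
        gtf = file.path(dir, "annotation.gtf"),
        truth_guides = file.path(dir, "truth_guides.tsv")
      )
      Biostrings::writeXStringSet(genome, paths$genome)
      writeLines(gtf, paths$gtf)
      utils::write.table(truth_guides, paths$truth_guides, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      if (!is.null(truth_ot)) {
        paths$truth_offtargets <- file.path(dir, "truth_offtargets.tsv")
        utils::write.table(truth_ot, paths$truth_offtargets, sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
      out$paths <- paths
    }
    out
  })
}

# Substitute each base with probability eps, uniformly over the three
# alternatives. Works on a character matrix (reads x positions).
apply_seq_error <- function(mat, eps) {
  if (eps <= 0) return(mat)
  alt <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
               G = c("A", "C", "T"), T = c("A", "C", "G"))
  hit <- which(stats::runif(length(mat)) < eps)
  if (length(hit) > 0L) {
    pick <- sample.int(3L, length(hit), replace = TRUE)
    mat[hit] <- alt[cbind(match(mat[hit], rownames(alt)), pick)]
  }
  mat
}

fastq_block <- function(ids, seqs, quals) {
  as.vector(rbind(paste0("@", ids), seqs, "+", quals))
}

#' Simulate amplicon sequencing reads over an edited locus
#'
#' Draws `depth` fragments of a fixed amplicon (the region centered on the
#' protospacer midpoint) in which a fraction `editing_rate` of fragments
#' carry the base conversion at the target position (A>G on the reference
#' strand holding an A, T>C otherwise); every emitted base is independently
#' substituted with probability `sequencing_error`, uniformly over the three
#' alternative bases. Mate 1 reads the first `read_length` bases of the
#' amplicon, mate 2 the last `read_length` bases (reverse-complemented in
#' FASTQ). Alignments are emitted directly as coordinate-sorted SAM at known
#' positions, so no aligner is needed, and the truth table records the exact
#' per-position base composition of all aligned bases.
#'
#' @param spec A [fixture_spec()] (uses `editing_rate`, `sequencing_error`,
#'   `read_length`, `depth`).
#' @param genome Fixture genome.
#' @param contig Contig of the locus.
#' @param target_pos Genome position of the edited base (reference A or T).
#' @param proto_start,proto_end Protospacer footprint, used to center the
#'   amplicon.
#' @param half_width Half-width of the amplicon around the protospacer
#'   midpoint (default 100, i.e. a 201-bp amplicon).
#' @param seed Seed for this simulation stream (default `spec$seed + 1`).
#' @param dir Optional output directory for `reads_R1.fastq`,
#'   `reads_R2.fastq`, `aln.sam`, `truth_pileup.tsv`.
#' @return List with `fastq_r1`, `fastq_r2`, `sam` (character lines), `lo`,
#'   `hi` (amplicon bounds), `truth` (per-position counts data.frame with the
#'   edited-fragment tally `n_edited` as an attribute) and `paths` (when
#'   `dir` given).
#' @export
simulate_amplicon_reads <- function(spec, genome, contig, target_pos,
                                    proto_start, proto_end, half_width = 100L,
                                    seed = spec$seed + 1L, dir = NULL) {
  with_seed(seed, {
    len <- contig_length(genome, contig)
    mid <- (proto_start + proto_end) %/% 2L
    lo <- max(1L, mid - half_width)
    hi <- min(len, mid + half_width)
    amp_len <- hi - lo + 1L
    L <- spec$read_length
    if (amp_len < L) stop("amplicon shorter than the read length")
    ref_amp <- strsplit(extract_sequence(genome, contig, lo, hi, "+"), "")[[1]]
    t_idx <- target_pos - lo + 1L
    ref_base <- ref_amp[t_idx]
    if (!ref_base %in% c("A", "T")) {
      stop("target position must have reference base A or T, got ", ref_base)
    }
    edited_base <- if (ref_base == "A") "G" else "C"

    edited <- stats::runif(spec$depth) < spec$editing_rate
    qual <- strrep("I", L)
    r2_start <- amp_len - L + 1L
    mk_mate <- function(lo_idx) {
      idx <- lo_idx:(lo_idx + L - 1L)
      m <- matrix(ref_amp[idx], nrow = spec$depth, ncol = L, byrow = TRUE)
      if (t_idx %in% idx) m[edited, which(idx == t_idx)] <- edited_base
      apply_seq_error(m, spec$sequencing_error)
    }
    m1 <- mk_mate(1L)
    m2 <- mk_mate(r2_start)
    counts <- matrix(0L, nrow = amp_len, ncol = 4,
                     dimnames = list(NULL, c("A", "C", "G", "T")))
    for (b in colnames(counts)) {
      counts[1:L, b] <- counts[1:L, b] + colSums(m1 == b)
      counts[r2_start:amp_len, b] <- counts[r2_start:amp_len, b] + colSums(m2 == b)
    }
    collapse_rows <- function(m) do.call(paste0, lapply(seq_len(ncol(m)), function(j) m[, j]))
    r1_seq <- collapse_rows(m1)
    r2_seq <- collapse_rows(m2)
    ids <- sprintf("frag%05d", seq_len(spec$depth))
    fq1 <- fastq_block(paste0(ids, "/1"), r1_seq, qual)
    fq2 <- fastq_block(paste0(ids, "/2"), revcomp(r2_seq), qual)
    header <- c("@HD\tVN:1.6\tSO:coordinate",
                sprintf("@SQ\tSN:%s\tLN:%d", contig, len))
    cigar <- sprintf("%dM", L)
    sam1 <- sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                    ids, contig, lo, cigar, r1_seq, qual)
    sam2 <- sprintf("%s\t16\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                    ids, contig, lo + r2_start - 1L, cigar, r2_seq, qual)
    sam <- c(header, sam1, sam2)  # R1 POS < R2 POS, so this is sorted
    truth <- data.frame(pos = lo:hi, ref = ref_amp,
                        count_A = counts[, "A"], count_C = counts[, "C"],
                        count_G = counts[, "G"], count_T = counts[, "T"],
                        stringsAsFactors = FALSE)
    attr(truth, "n_edited") <- sum(edited)
    out <- list(fastq_r1 = fq1, fastq_r2 = fq2, sam = sam, lo = lo, hi = hi,
                target_pos = target_pos, truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      paths <- list(r1 = file.path(dir, "reads_R1.fastq"),
                    r2 = file.path(dir, "reads_R2.fastq"),
                    sam = file.path(dir, "aln.sam"),
                    truth = file.path(dir, "truth_pileup.tsv"))
      writeLines(fq1, paths$r1); writeLines(fq2, paths$r2)
      writeLines(sam, paths$sam)
      utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      out$paths <- paths
    }
    out
  })
}

#' Simulate RNA reads from a canonical / exon-skipped isoform mixture
#'
#' Junction-spanning reads are drawn from the exon-skipped isoform with
#' probability `skip_fraction` and from the canonical isoform otherwise
#' (choosing its 5' or 3' junction uniformly); each read spans its junction
#' with at least `anchor` exonic bases on both sides. Background reads are
#' drawn from exon interiors and span no junction, so a correct classifier
#' must exclude them. Half of all reads are emitted reverse-complemented.
#' Truth records the exact skipped / canonical / background tallies.
#'
#' @param spec A [fixture_spec()] (uses `skip_fraction`, `n_junction_reads`,
#'   `n_background_reads`, `rna_read_length`, `anchor`).
#' @param genome Fixture genome.
#' @param transcripts Exon table from [read_annotation()].
#' @param key Exon key of the target (skippable) exon.
#' @param seed Seed for this simulation stream (default `spec$seed + 2`).
#' @param dir Optional output directory for `rna_reads.fastq` and
#'   `truth_rna.json`.
#' @return List with `reads` (character), `fastq` (lines), `truth` (list:
#'   `skipped`, `canonical`, `background`) and `paths` (when `dir` given).
#' @export
simulate_rna_reads <- function(spec, genome, transcripts, key,
                               seed = spec$seed + 2L, dir = NULL) {
  with_seed(seed, {
    ctx <- NULL
    for (tx in split(transcripts, transcripts$transcript_id)) {
      tx <- tx[order(tx$exon_rank), , drop = FALSE]
      keys <- exon_key(tx$contig, tx$start, tx$end, tx$strand)
      j <- which(keys == key)
      if (length(j) == 1L && j > 1L && j < nrow(tx)) {
        ctx <- tx[(j - 1L):(j + 1L), , drop = FALSE]
        break
      }
    }
    if (is.null(ctx)) stop("exon ", key, " has no flanking exons in any transcript")
    sq <- vapply(1:3, function(i) {
      extract_sequence(genome, ctx$contig[i], ctx$start[i], ctx$end[i], ctx$strand[i])
    }, "")
    canonical <- paste0(sq[1], sq[2], sq[3])
    skipped <- paste0(sq[1], sq[3])
    L <- spec$rna_read_length; anchor <- spec$anchor
    draw_junction_read <- function(iso_seq, junc) {
      lo <- max(1L, junc + anchor - L + 1L)
      hi <- min(nchar(iso_seq) - L + 1L, junc - anchor + 1L)
      st <- if (hi > lo) sample(lo:hi, 1L) else lo
      substr(iso_seq, st, st + L - 1L)
    }
    n_skip_true <- 0L
    reads <- character(0)
    for (i in seq_len(spec$n_junction_reads)) {
      if (stats::runif(1) < spec$skip_fraction) {
        n_skip_true <- n_skip_true + 1L
        reads <- c(reads, draw_junction_read(skipped, nchar(sq[1])))
      } else {
        junc <- if (stats::runif(1) < 0.5) nchar(sq[1]) else nchar(sq[1]) + nchar(sq[2])
        reads <- c(reads, draw_junction_read(canonical, junc))
      }
    }
    exon_bounds <- list(c(1L, nchar(sq[1])),
                        c(nchar(sq[1]) + 1L, nchar(sq[1]) + nchar(sq[2])),
                        c(nchar(sq[1]) + nchar(sq[2]) + 1L, nchar(canonical)))
    for (i in seq_len(spec$n_background_reads)) {
      b <- exon_bounds[[sample(3L, 1L)]]
      st <- sample(b[1]:(b[2] - L + 1L), 1L)
      reads <- c(reads, substr(canonical, st, st + L - 1L))
    }
    flip <- stats::runif(length(reads)) < 0.5
    reads[flip] <- revcomp(reads[flip])
    truth <- list(skipped = n_skip_true,
                  canonical = spec$n_junction_reads - n_skip_true,
                  background = spec$n_background_reads)
    fq <- fastq_block(sprintf("rna%05d", seq_along(reads)), reads,
                      strrep("I", L))
    out <- list(reads = reads, fastq = fq, truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      paths <- list(fastq = file.path(dir, "rna_reads.fastq"),
                    truth = file.path(dir, "truth_rna.json"))
      writeLines(fq, paths$fastq)
      jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE)
      out$paths <- paths
    }
    out
  })
}
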