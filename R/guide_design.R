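#' Build a position-dependent editing-efficiency table
#'
#' Base editors convert their target base efficiently only within a window of
#' protospacer positions (numbered 1 = PAM-distal to 20 = PAM-proximal, PAM
#' at 21-23). An efficiency table maps window positions to predicted absolute
#' editing efficiency in percent; positions absent from the window predict 0.
#' Relative per-position efficiencies are scaled by `max_efficiency`.
#'
#' @param mode `"ABE"` (adenine editor, targets the acceptor A) or `"BE3"`
#'   (cytidine editor, targets the C opposite the acceptor G).
#' @param relative Named numeric vector of relative efficiencies in `[0, 1]`,
#'   names are protospacer positions.
#' @param max_efficiency Maximum absolute editing efficiency in percent used
#'   to scale `relative`.
#' @return An `efficiency_table` list with `mode`, `window` (named numeric,
#'   percent) and `max_efficiency`.
#' @export
efficiency_table <- function(mode, relative, max_efficiency) {
  mode <- match.arg(mode, c("ABE", "BE3"))
  if (is.null(names(relative)) || any(!nzchar(names(relative)))) {
    stop("relative efficiencies must be named by protospacer position")
  }
  pos <- as.integer(names(relative))
  if (anyNA(pos) || any(pos < 1L | pos > 20L)) {
    stop("protospacer positions must be integers in 1..20")
  }
  if (any(relative < 0 | relative > 1)) stop("relative efficiencies must be in [0,1]")
  if (max_efficiency < 0 || max_efficiency > 100) stop("max_efficiency must be in [0,100]")
  window <- as.numeric(relative) * max_efficiency
  names(window) <- as.character(pos)
  structure(list(mode = mode, window = window, max_efficiency = max_efficiency),
            class = "efficiency_table")
}

#' Load the default efficiency tables shipped with the package
#'
#' Reads `inst/extdata/efficiency_tables.json` (or a user-supplied file with
#' the same schema). The shipped values are editable placeholders; users with
#' editor-specific calibration data should supply their own table.
#'
#' @param mode `"ABE"` or `"BE3"`.
#' @param path Optional path to an alternative JSON config.
#' @return An [efficiency_table()].
#' @export
default_efficiency_table <- function(mode = c("ABE", "BE3"), path = NULL) {
  mode <- match.arg(mode)
  if (is.null(path)) {
    path <- system.file("extdata", "efficiency_tables.json", package = "skipedit")
  }
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg[[mode]])) stop("no entry for mode ", mode, " in ", path)
  efficiency_table(mode, unlist(cfg[[mode]]$relative), cfg[[mode]]$max_efficiency)
}

#' Predicted editing efficiency at a protospacer position
#'
#' @param position Integer protospacer position(s), 1-based, PAM-distal = 1.
#' @param table An [efficiency_table()].
#' @return Predicted efficiency in percent; 0 for positions outside the
#'   table's window.
#' @export
predict_editing_efficiency <- function(position, table) {
  stopifnot(inherits(table, "efficiency_table"))
  out <- table$window[as.character(position)]
  out[is.na(out)] <- 0
  unname(out)
}

# Genomic footprint of a candidate protospacer+PAM placing the target base at
# protospacer position p. Returns NULL when the site runs off the contig.
guide_site <- function(genome, contig, guide_strand, target_pos, p) {
  len <- contig_length(genome, contig)
  if (guide_strand == "+") {
    start <- target_pos - (p - 1L)
    end <- start + 19L
    pam_lo <- end + 1L; pam_hi <- end + 3L
    if (start < 1L || pam_hi > len) return(NULL)
    proto <- extract_sequence(genome, contig, start, end, "+")
    pam <- extract_sequence(genome, contig, pam_lo, pam_hi, "+")
  } else {
    end <- target_pos + (p - 1L)
    start <- end - 19L
    pam_lo <- start - 3L; pam_hi <- start - 1L
    if (pam_lo < 1L || end > len) return(NULL)
    proto <- extract_sequence(genome, contig, start, end, "-")
    pam <- extract_sequence(genome, contig, pam_lo, pam_hi, "-")
  }
  list(protospacer = proto, pam = pam, start = start, end = end)
}

is_ngg <- function(pam) substr(pam, 2, 3) == "GG" & !grepl("N", pam, fixed = TRUE)

empty_candidates <- function() {
  data.frame(
    exon_key = character(0), gene_ids = character(0), mode = character(0),
    protospacer = character(0), pam = character(0), guide_strand = character(0),
    contig = character(0), proto_start = integer(0), proto_end = integer(0),
    target_pos_in_protospacer = integer(0), target_genome_pos = integer(0),
    predicted_efficiency = numeric(0), offtarget_score = numeric(0),
    stringsAsFactors = FALSE
  )
}

#' Find base-editor protospacers at a splice acceptor
#'
#' Scans for sgRNA placements that put the acceptor target base inside the
#' editor's active window with an NGG PAM at protospacer positions 21-23.
#' ABE guides lie on the transcript sense strand, where the conserved
#' acceptor adenine reads as `A`; converting it to `G` destroys the acceptor
#' AG. BE3 guides lie on the antisense strand, where the conserved acceptor
#' guanine reads as `C`; C>T conversion likewise destroys the acceptor.
#' For each window position `p` a candidate is emitted iff the 20-mer placing
#' the target base at position `p` is followed by NGG and the protospacer+PAM
#' contains no `N`. Non-canonical acceptors yield no candidates. Sites
#' running off the contig are skipped with a warning.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param inner_exon One row of a [check_acceptors()] table.
#' @param mode `"ABE"` or `"BE3"`.
#' @param table An [efficiency_table()] for `mode`; its window positions
#'   define the scan.
#' @return A candidate data.frame (possibly empty) with the protospacer, PAM,
#'   guide strand, genomic footprint, window position and predicted
#'   efficiency; `offtarget_score` is `NA` until scored.
#' @export
find_protospacers <- function(genome, inner_exon, mode = c("ABE", "BE3"),
                              table = default_efficiency_table(mode)) {
  mode <- match.arg(mode)
  stopifnot(nrow(inner_exon) == 1L)
  if (is.null(inner_exon$canonical_acceptor)) {
    inner_exon <- check_acceptors(inner_exon, genome)
  }
  if (!isTRUE(inner_exon$canonical_acceptor)) return(empty_candidates())
  gene_strand <- inner_exon$strand
  if (mode == "ABE") {
    guide_strand <- gene_strand
    target_pos <- inner_exon$acceptor_A_pos
    target_base <- "A"
  } else {
    guide_strand <- if (gene_strand == "+") "-" else "+"
    target_pos <- inner_exon$acceptor_G_pos
    target_base <- "C"
  }
  window <- sort(as.integer(names(table$window)))
  rows <- lapply(window, function(p) {
    site <- guide_site(genome, inner_exon$contig, guide_strand, target_pos, p)
    if (is.null(site)) {
      warning(sprintf("acceptor at %s:%d too close to contig edge for window position %d; skipped",
                      inner_exon$contig, target_pos, p))
      return(NULL)
    }
    if (grepl("N", paste0(site$protospacer, site$pam), fixed = TRUE)) return(NULL)
    if (!is_ngg(site$pam)) return(NULL)
    stopifnot(substr(site$protospacer, p, p) == target_base)
    data.frame(
      exon_key = inner_exon$exon_key,
      gene_ids = inner_exon$gene_ids,
      mode = mode,
      protospacer = site$protospacer, pam = site$pam,
      guide_strand = guide_strand,
      contig = inner_exon$contig,
      proto_start = site$start, proto_end = site$end,
      target_pos_in_protospacer = p,
      target_genome_pos = target_pos,
      predicted_efficiency = predict_editing_efficiency(p, table),
      offtarget_score = NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty_candidates() else out
}

#' Design guides for a set of inner exons
#'
#' Runs [find_protospacers()] over every canonical inner exon and returns all
#' candidates in deterministic order (exon key, mode, window position, guide
#' strand).
#'
#' @inheritParams find_protospacers
#' @param inner_exons Table from [check_acceptors()].
#' @return Candidate data.frame across exons.
#' @export
design_guides <- function(genome, inner_exons, mode = c("ABE", "BE3"),
                          table = default_efficiency_table(mode)) {
  mode <- match.arg(mode)
  rows <- lapply(seq_len(nrow(inner_exons)), function(i) {
    find_protospacers(genome, inner_exons[i, , drop = FALSE], mode, table)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) return(empty_candidates())
  out <- out[order(out$exon_key, out$mode, out$target_pos_in_protospacer,
                   out$guide_strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach aggregate off-target scores to guide candidates
#'
#' For each candidate, enumerates genome-wide near-matches within
#' `max_mismatches` and sums the per-hit scores over all sites other than the
#' design locus (see [aggregate_offtarget_score()]).
#'
#' @param candidates Candidate table from [design_guides()].
#' @param genome A [Biostrings::DNAStringSet].
#' @param weights Mismatch-penalty config from [default_mismatch_weights()].
#' @param max_mismatches Maximum Hamming distance searched (default 2).
#' @param include_nag Also accept NAG PAMs at off-target sites.
#' @return `candidates` with `offtarget_score` filled in.
#' @export
score_guides <- function(candidates, genome, weights = default_mismatch_weights(),
                         max_mismatches = 2L, include_nag = FALSE) {
  if (nrow(candidates) == 0L) return(candidates)
  for (i in seq_len(nrow(candidates))) {
    hits <- enumerate_offtargets(genome, candidates$protospacer[i],
                                 max_mismatches = max_mismatches,
                                 include_nag = include_nag, weights = weights)
    candidates$offtarget_score[i] <- aggregate_offtarget_score(
      hits,
      on_target = list(contig = candidates$contig[i],
                       start = candidates$proto_start[i],
                       strand = candidates$guide_strand[i])
    )
  }
  candidates
}

#' Filter candidates by thresholds and pick the best guide per exon
#'
#' Keeps candidates with predicted efficiency strictly above `eff_threshold`
#' and off-target score at most `ot_threshold` (guides scoring above the
#' threshold are removed; a score exactly at the threshold is retained).
#' Among survivors of each exon, the candidate with the highest predicted
#' efficiency is flagged `best` (ties broken by lower off-target score, then
#' 5'-most window position). Exons with no surviving candidate are listed in
#' the `untargetable` component.
#'
#' @param candidates Scored candidate table from [score_guides()].
#' @param eff_threshold Efficiency threshold in percent (strict, default 30).
#' @param ot_threshold Off-target score cap (inclusive, default 10).
#' @return List with `report` (surviving candidates plus a logical `best`
#'   column) and `untargetable` (character vector of exon keys).
#' @export
design_for_exons <- function(candidates, eff_threshold = 30, ot_threshold = 10) {
  if (any(is.na(candidates$offtarget_score))) {
    stop("candidates must be scored (see score_guides) before filtering")
  }
  keep <- candidates$predicted_efficiency > eff_threshold &
    candidates$offtarget_score <= ot_threshold
  surv <- candidates[keep, , drop = FALSE]
  surv$best <- logical(nrow(surv))
  for (k in unique(surv$exon_key)) {
    idx <- which(surv$exon_key == k)
    sub <- surv[idx, ]
    o <- order(-sub$predicted_efficiency, sub$offtarget_score,
               sub$target_pos_in_protospacer)
    surv$best[idx[o[1]]] <- TRUE
  }
  rownames(surv) <- NULL
  list(report = surv,
       untargetable = setdiff(unique(candidates$exon_key), unique(surv$exon_key)))
}
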