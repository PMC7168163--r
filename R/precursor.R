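# Residue classes used by the signal-peptide heuristic.
SP_HYDROPHOBIC <- c("A", "I", "L", "V", "F", "M", "W")
SP_SMALL_M1 <- c("A", "G", "S", "C") # allowed at the -1 position
SP_SMALL_M3 <- c("A", "G", "S", "V", "C") # allowed at the -3 position

#' Predict the signal-peptide cleavage site of a precursor
#'
#' Scans candidate cleavage positions 15..30 (the candidate is the last
#' signal-peptide residue) and scores each as: number of hydrophobic
#' residues (A/I/L/V/F/M/W) among the 11 residues preceding the candidate,
#' plus 2 if the -1 residue is small (A/G/S/C) and 1 if the -3 residue is
#' small-ish (A/G/S/V/C) — a von Heijne-style (3,-1) rule without a trained
#' model. Ties are broken towards position 20, the typical mytilin
#' signal-peptide length.
#'
#' @param residues Precursor sequence(s), at least 40 residues.
#' @return Integer vector: predicted position of the last signal-peptide
#'   residue. Errors with "no plausible signal peptide" when no candidate
#'   window has a hydrophobic core (>= 5 hydrophobic residues).
#' @export
predict_signal_cleavage <- function(residues) {
  vapply(residues, function(seq) {
    if (nchar(seq) < 40) {
      abort("precursor too short for signal-peptide prediction (< 40 aa)")
    }
    chars <- strsplit(seq, "")[[1]]
    cands <- 15:30
    hyd <- vapply(cands, function(p) {
      win <- chars[max(1, p - 11):(p - 1)]
      sum(win %in% SP_HYDROPHOBIC)
    }, numeric(1))
    sc <- hyd +
      2 * (chars[cands] %in% SP_SMALL_M1) +
      1 * (chars[cands - 2] %in% SP_SMALL_M3)
    ok <- hyd >= 5
    if (!any(ok)) abort("no plausible signal peptide")
    sc[!ok] <- -Inf
    best <- which(sc == max(sc))
    best <- best[order(abs(cands[best] - 20L), cands[best])][1]
    as.integer(cands[best])
  }, integer(1), USE.NAMES = FALSE)
}

#' Segment a precursor by alignment to an annotated reference
#'
#' Globally aligns the precursor to a reference precursor whose tripartite
#' annotation (signal peptide end, mature peptide end) is known, and maps
#' the reference boundaries through the alignment. A boundary that lands in
#' a column where the precursor is gapped snaps to the nearest precursor
#' residue towards the mature-region interior. Coordinates are 1-based
#' inclusive throughout.
#'
#' @param precursor Precursor sequence (character scalar).
#' @param reference Reference precursor sequence.
#' @param reference_annotation List or one-row data frame with `sp_end` and
#'   `mature_end` (positions of the last signal-peptide and last
#'   mature-peptide residue in the reference).
#' @param min_identity Hard floor on global percent identity below which the
#'   reference is rejected as too distant (default 25).
#' @return A list with `sp_end`, `mature_start`, `mature_end`, `ctail_start`,
#'   `ctail_end` (NA when the C-terminal extension is empty/truncated) and
#'   `method = "by_alignment"`.
#' @export
segment_by_alignment <- function(precursor, reference, reference_annotation,
                                 min_identity = 25) {
  sp_end_ref <- reference_annotation$sp_end
  mat_end_ref <- reference_annotation$mature_end
  stopifnot(
    sp_end_ref >= 1, mat_end_ref > sp_end_ref,
    mat_end_ref <= nchar(reference)
  )
  al <- align_global(precursor, reference)
  if (al$percent_identity < min_identity) {
    abort(sprintf(
      "reference too distant (%.1f%% identity < %g%%)",
      al$percent_identity, min_identity
    ))
  }
  qc <- strsplit(al$aligned_query, "")[[1]]
  tc <- strsplit(al$aligned_target, "")[[1]]
  q_pos <- cumsum(qc != "-") # precursor residue index per column (0 before first)
  t_pos <- cumsum(tc != "-")
  col_of_ref <- function(p) which(t_pos == p & tc != "-")[1]

  # mature start: first column at/after the reference mature start that has a
  # precursor residue (snap rightwards, into the mature region)
  col_ms <- col_of_ref(sp_end_ref + 1L)
  cols_right <- col_ms:length(qc)
  ms_col <- cols_right[qc[cols_right] != "-"][1]
  if (is.na(ms_col)) abort("alignment leaves no mature region in the precursor")
  mature_start <- q_pos[ms_col]

  # mature end: last column at/before the reference mature end with a
  # precursor residue (snap leftwards, into the mature region)
  col_me <- col_of_ref(mat_end_ref)
  cols_left <- seq_len(col_me)
  me_col <- rev(cols_left[qc[cols_left] != "-"])[1]
  if (is.na(me_col)) abort("alignment leaves no mature region in the precursor")
  mature_end <- q_pos[me_col]
  if (mature_end < mature_start) abort("degenerate mature region after mapping")

  len <- nchar(precursor)
  list(
    sp_end = mature_start - 1L,
    mature_start = mature_start,
    mature_end = mature_end,
    ctail_start = if (mature_end < len) mature_end + 1L else NA_integer_,
    ctail_end = if (mature_end < len) len else NA_integer_,
    method = "by_alignment"
  )
}

#' Annotate precursors with the tripartite segmentation
#'
#' Segments each precursor into signal peptide, mature peptide and
#' C-terminal extension. The mature/C-tail boundary is always taken by
#' alignment to the annotated reference (there is no ab initio C-tail
#' caller); the signal-peptide end comes either from the same alignment
#' mapping (`sp_method = "alignment"`) or from the [predict_signal_cleavage()]
#' heuristic (`sp_method = "heuristic"`). A mature length outside \[30, 45\]
#' is flagged in the `note` column as a sanity failure.
#'
#' @param peptides Tibble of precursors with columns `id`, `residues`.
#' @param reference,reference_annotation As in [segment_by_alignment()].
#' @param sp_method `"alignment"` or `"heuristic"`.
#' @return A tibble: `peptide_id`, `sp_end`, `mature_start`, `mature_end`,
#'   `ctail_start`, `ctail_end`, `method`, `note`.
#' @export
annotate_precursors <- function(peptides, reference, reference_annotation,
                                sp_method = c("alignment", "heuristic")) {
  sp_method <- match.arg(sp_method)
  purrr::map2_dfr(peptides$id, peptides$residues, function(id, seq) {
    seg <- segment_by_alignment(seq, reference, reference_annotation)
    if (sp_method == "heuristic") {
      sp <- predict_signal_cleavage(seq)
      seg$sp_end <- sp
      seg$mature_start <- sp + 1L
    }
    note <- NA_character_
    mat_len <- seg$mature_end - seg$mature_start + 1L
    if (mat_len < 30 || mat_len > 45) {
      note <- sprintf("mature length %d outside [30, 45]", mat_len)
    }
    tibble(
      peptide_id = id,
      sp_end = seg$sp_end,
      mature_start = seg$mature_start,
      mature_end = seg$mature_end,
      ctail_start = seg$ctail_start,
      ctail_end = seg$ctail_end,
      method = if (sp_method == "heuristic") "heuristic" else "by_alignment",
      note = note
    )
  })
}

#' Extract a segment of annotated precursors
#'
#' @param peptides Tibble with `id`, `residues`.
#' @param annotations Tibble as returned by [annotate_precursors()].
#' @param segment `"sp"`, `"mature"` or `"ctail"`.
#' @return A tibble `id`, `residues` restricted to the requested segment;
#'   precursors without the segment (e.g., truncated C-tails) are dropped.
#' @export
extract_segment <- function(peptides, annotations,
                            segment = c("mature", "sp", "ctail")) {
  segment <- match.arg(segment)
  joined <- dplyr::inner_join(peptides, annotations,
    by = c(id = "peptide_id"), suffix = c("", ".annotation")
  )
  bounds <- switch(segment,
    sp = list(from = rep(1L, nrow(joined)), to = joined$sp_end),
    mature = list(from = joined$mature_start, to = joined$mature_end),
    ctail = list(from = joined$ctail_start, to = joined$ctail_end)
  )
  keep <- !is.na(bounds$from) & !is.na(bounds$to)
  tibble(
    id = joined$id[keep],
    residues = substring(joined$residues[keep], bounds$from[keep],
                         bounds$to[keep])
  )
}
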