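# Karlin-Altschul-style constants for BLOSUM62 gapped local alignments,
# used by the screen's approximate significance estimate.
KA_K <- 0.041
KA_LAMBDA <- 0.267

translate_nt <- function(nt) {
  # no.init.codon: a leading CTG/TTG must translate as L, not as an
  # initiator M, or spurious upstream starts appear
  suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(nt), if.fuzzy.codon = "X",
                          no.init.codon = TRUE)
  ))
}

#' Enumerate complete six-frame ORFs of a transcript
#'
#' Translates all three frames of both strands and reports every complete
#' ATG..stop ORF of at least `min_len` amino acids. Within a frame, nested
#' ORFs sharing a stop are collapsed to the longest (leftmost start).
#' Reverse-strand ORFs are reported in forward-strand coordinates with a
#' negative frame. Intervals are 1-based inclusive and include the stop
#' codon; `protein` excludes the stop.
#'
#' @param transcript One-row tibble (or list) with `id` and `nucleotides`.
#' @param min_len Minimum protein length in residues (default 60).
#' @return A tibble: `transcript_id`, `frame`, `orf_start`, `orf_end`,
#'   `protein`.
#' @export
six_frame_orfs <- function(transcript, min_len = 60L) {
  nt <- transcript$nucleotides
  id <- transcript$id
  len <- nchar(nt)
  out <- list()
  for (strand in c("+", "-")) {
    seq <- if (strand == "+") nt else revcomp(nt)
    for (f in 1:3) {
      n_codons <- (nchar(seq) - f + 1L) %/% 3L
      if (n_codons < min_len + 1L) next
      aa <- translate_nt(substr(seq, f, f + n_codons * 3L - 1L))
      chars <- strsplit(aa, "")[[1]]
      stops <- which(chars == "*")
      seg_start <- 1L
      for (st in stops) {
        if (st > seg_start) {
          ms <- which(chars[seg_start:(st - 1L)] == "M")
          if (length(ms)) {
            m <- seg_start + ms[1] - 1L
            if (st - m >= min_len) {
              # coordinates on the translated strand, then map to forward
              s_nt <- f + (m - 1L) * 3L
              e_nt <- f + st * 3L - 1L
              if (strand == "+") {
                orf_start <- s_nt
                orf_end <- e_nt
                frame <- f
              } else {
                orf_start <- len - e_nt + 1L
                orf_end <- len - s_nt + 1L
                frame <- -f
              }
              out[[length(out) + 1L]] <- tibble(
                transcript_id = id, frame = frame,
                orf_start = orf_start, orf_end = orf_end,
                protein = paste(chars[m:(st - 1L)], collapse = "")
              )
            }
          }
        }
        seg_start <- st + 1L
      }
    }
  }
  if (!length(out)) {
    return(tibble(
      transcript_id = character(0), frame = integer(0),
      orf_start = integer(0), orf_end = integer(0), protein = character(0)
    ))
  }
  bind_rows(out)
}

#' Approximate E-value of a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` with fixed Karlin-Altschul-style
#' constants for BLOSUM62 (`K = 0.041`, `lambda = 0.267`); `m` and `n` are
#' the query and target lengths in residues. An approximation adequate for
#' thresholding candidate hits, not a calibrated statistic.
#'
#' @param score Local alignment score (matrix units).
#' @param m,n Query and target sequence lengths.
#' @return E-value estimate (monotone decreasing in `score`).
#' @export
evalue_like <- function(score, m, n) {
  KA_K * m * n * exp(-KA_LAMBDA * score)
}

#' Iterative seed-based homology screen for mytilin-like ORFs
#'
#' Mirrors an iterative translated-search protocol: every candidate ORF
#' translation is locally aligned against the current seed list; ORFs whose
#' best E-value falls below `e_threshold` are segmented by alignment to
#' their best seed, gated on a mytilin-classifiable cysteine array
#' (canonical or alternative) in the mature region, and — if accepted —
#' join the seed list. Iteration continues until a pass adds no hit (or
#' `max_iter` is reached, with a warning), so divergent family members
#' reachable only through intermediate relatives are still recovered.
#'
#' Alignment queries are the seeds' *mature regions* (the conserved module;
#' signal peptides and acidic tails carry mostly compositional signal), and
#' the E-value search space is query length times the total translated
#' database size (sum of candidate ORF lengths), mirroring how translated
#' database searches are thresholded.
#'
#' @param seeds Tibble of annotated seed precursors: `id`, `residues`,
#'   `sp_end`, `mature_end`.
#' @param transcripts Tibble of transcripts: `id`, `nucleotides`.
#' @param e_threshold Acceptance threshold on [evalue_like()] (default 1e-3).
#' @param min_len Minimum ORF protein length (default 60).
#' @param max_iter Iteration cap (default 20).
#' @return A tibble of accepted hits: `transcript_id`, `frame`, `orf_start`,
#'   `orf_end`, `precursor`, `best_seed_id`, `local_score`, `evalue`,
#'   `sp_end`, `mature_start`, `mature_end`, `array_class`,
#'   `iteration_found`.
#' @export
iterative_screen <- function(seeds, transcripts, e_threshold = 1e-3,
                             min_len = 60L, max_iter = 20L) {
  stopifnot(nrow(seeds) >= 1)
  orfs <- purrr::map_dfr(seq_len(nrow(transcripts)), function(i) {
    six_frame_orfs(transcripts[i, ], min_len = min_len)
  })
  if (!nrow(orfs)) return(empty_hits())
  orfs$orf_id <- paste0(orfs$transcript_id, "|", orfs$frame, "|",
                        orfs$orf_start)
  n_db <- sum(nchar(orfs$protein)) # translated search space (residues)
  seed_list <- seeds[, c("id", "residues", "sp_end", "mature_end")]
  seed_list$mature <- substring(seed_list$residues, seed_list$sp_end + 1L,
                                seed_list$mature_end)
  accepted <- rep(FALSE, nrow(orfs))
  hits <- list()
  # best local score of every ORF against every seed, grown column-wise as
  # the seed list grows
  scores <- matrix(
    NA_real_, nrow(orfs), nrow(seed_list),
    dimnames = list(orfs$orf_id, seed_list$id)
  )
  iter <- 0L
  repeat {
    iter <- iter + 1L
    new_cols <- which(colSums(!is.na(scores)) == 0)
    for (j in new_cols) {
      scores[, j] <- vapply(orfs$protein, function(p) {
        align_local(seed_list$mature[j], p)$score
      }, numeric(1), USE.NAMES = FALSE)
    }
    added <- FALSE
    for (i in which(!accepted)) {
      ev <- evalue_like(scores[i, ], nchar(seed_list$mature), n_db)
      best <- which.min(ev)
      if (ev[best] >= e_threshold) next
      seed <- seed_list[best, ]
      seg <- tryCatch(
        segment_by_alignment(
          orfs$protein[i], seed$residues,
          list(sp_end = seed$sp_end, mature_end = seed$mature_end)
        ),
        error = function(e) NULL
      )
      if (is.null(seg)) next
      mature <- substring(orfs$protein[i], seg$mature_start, seg$mature_end)
      cls <- classify_cys_array(mature)$array_class
      if (!cls %in% c("canonical", "alternative")) next
      accepted[i] <- TRUE
      added <- TRUE
      hits[[length(hits) + 1L]] <- tibble(
        transcript_id = orfs$transcript_id[i],
        frame = orfs$frame[i],
        orf_start = orfs$orf_start[i],
        orf_end = orfs$orf_end[i],
        precursor = orfs$protein[i],
        best_seed_id = seed_list$id[best],
        local_score = scores[i, best],
        evalue = unname(ev[best]),
        sp_end = seg$sp_end,
        mature_start = seg$mature_start,
        mature_end = seg$mature_end,
        array_class = cls,
        iteration_found = iter
      )
      # accepted hit joins the seed list (annotated by its own segmentation)
      seed_list <- bind_rows(seed_list, tibble(
        id = orfs$orf_id[i], residues = orfs$protein[i],
        sp_end = seg$sp_end, mature_end = seg$mature_end,
        mature = mature
      ))
      scores <- cbind(
        scores,
        matrix(NA_real_, nrow(orfs), 1,
               dimnames = list(NULL, orfs$orf_id[i]))
      )
    }
    if (!added) break
    if (iter >= max_iter) {
      warn(sprintf("screen stopped at max_iter = %d", max_iter))
      break
    }
  }
  if (!length(hits)) return(empty_hits())
  bind_rows(hits)
}

empty_hits <- function() {
  tibble(
    transcript_id = character(0), frame = integer(0),
    orf_start = integer(0), orf_end = integer(0), precursor = character(0),
    best_seed_id = character(0), local_score = numeric(0),
    evalue = numeric(0), sp_end = integer(0), mature_start = integer(0),
    mature_end = integer(0), array_class = character(0),
    iteration_found = integer(0)
  )
}

#' Flag novel hits against a set of known peptides
#'
#' A hit is novel iff its global percent identity to every known peptide is
#' strictly below `cutoff` (default 95); a hit at exactly the cutoff is not
#' novel. Comparison uses the hit's precursor (or `residues`) column.
#'
#' @param hits Tibble with a `precursor` (or `residues`) column.
#' @param known Tibble of known peptides (`id`, `residues`).
#' @param cutoff Identity percentage (default 95).
#' @return `hits` with added columns `novel` and `max_identity`.
#' @export
novelty_filter <- function(hits, known, cutoff = 95) {
  seq_col <- if ("precursor" %in% names(hits)) "precursor" else "residues"
  if (!nrow(hits)) {
    hits$novel <- logical(0)
    hits$max_identity <- numeric(0)
    return(hits)
  }
  max_id <- vapply(hits[[seq_col]], function(s) {
    max(vapply(known$residues, function(k) {
      align_global(s, k)$percent_identity
    }, numeric(1)))
  }, numeric(1), USE.NAMES = FALSE)
  hits$novel <- max_id < cutoff
  hits$max_identity <- max_id
  hits
}
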