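# Spacing templates for the mytilin cysteine array, expressed as the number
# of non-member residues between consecutive structural cysteines C1..C8.
#
# The canonical array is C-x3-C-x3-C-x4-C-x11-C-x-C-x-C-x2-C. Loop sizes
# vary slightly across genera (the 32-aa Trichomya mature has a 2-residue
# C3-C4 loop; Perna CCC arrays compress the C6-C7 gap to 0), so the
# classifier first tries the strict template and then a relaxed one that
# keeps the diagnostic geometry: C5 immediately ahead of the C6..C8 terminal
# block. The alternative array keeps the C1-C4 block spacing (x3, x4) and
# the terminal block, but C5 is displaced towards C4 (it sits on the first
# beta strand instead of the second, changing the C1-C5 bond topology).
CANONICAL_GAPS <- c(3L, 3L, 4L, 11L, 1L, 1L, 2L)

is_strict_canonical <- function(g) identical(as.integer(g), CANONICAL_GAPS)

is_relaxed_canonical <- function(g) {
  g[1] == 3 && g[2] == 3 && g[3] >= 2 && g[3] <= 6 &&
    g[4] >= 6 && g[4] <= 16 && g[5] == 1 && g[6] <= 2 && g[7] == 2
}

is_alternative <- function(g) {
  g[2] == 3 && g[3] == 4 && g[5] > 1 && g[6] <= 2 && g[7] == 2
}

gaps_between <- function(pos) diff(pos) - 1L

# Classify one mature sequence. Returns the fields of the per-peptide report.
classify_cys_array <- function(seq) {
  pos <- as.integer(stringr::str_locate_all(seq, "C")[[1]][, 1])
  n <- length(pos)
  has_ccc <- stringr::str_detect(seq, "CCC")
  out <- list(
    cys_positions = pos, n_cys = n, array_class = "noncanonical",
    has_ccc = has_ccc, structural = integer(0), c5_candidates = integer(0),
    missing_c8 = FALSE,
    c1_c2_loop_len = if (n >= 2) pos[2] - pos[1] - 1L else NA_integer_
  )
  if (n < 8) {
    out$missing_c8 <- has_truncated_canonical(pos)
    return(out)
  }
  subsets <- combn(n, 8L) # columns in lexicographic order: leftmost C1 first
  gaps <- apply(subsets, 2, function(idx) gaps_between(pos[idx]))
  strict <- which(apply(gaps, 2, is_strict_canonical))
  relaxed <- which(apply(gaps, 2, is_relaxed_canonical))
  if (length(strict) || length(relaxed)) {
    pick <- if (length(strict)) strict[1] else relaxed[1]
    out$array_class <- "canonical"
    out$structural <- pos[subsets[, pick]]
    out$c1_c2_loop_len <- gaps_between(out$structural)[1]
    return(out)
  }
  alt <- which(apply(gaps, 2, is_alternative))
  if (length(alt)) {
    pick <- alt[1]
    chosen <- pos[subsets[, pick]]
    # Other matching subsets that differ from the chosen one only in the C5
    # member expose sterically plausible alternatives for the C1-C5 bond
    # (nine-cysteine, mytilin-K-like arrays).
    c5s <- vapply(alt, function(j) {
      s <- pos[subsets[, j]]
      if (identical(s[-5], chosen[-5])) s[5] else NA_integer_
    }, integer(1))
    out$array_class <- "alternative"
    out$structural <- chosen
    out$c5_candidates <- sort(unique(c5s[!is.na(c5s)]))
    out$c1_c2_loop_len <- gaps_between(chosen)[1]
    return(out)
  }
  out$missing_c8 <- has_truncated_canonical(pos)
  out
}

# TRUE when some 7-cysteine subset matches the canonical array truncated
# before C8 (seen in one P. viridis mature lacking the final cysteine).
has_truncated_canonical <- function(pos) {
  n <- length(pos)
  if (n < 7) return(FALSE)
  subsets <- combn(n, 7L)
  any(apply(subsets, 2, function(idx) {
    g <- gaps_between(pos[idx])
    g[1] == 3 && g[2] == 3 && g[3] >= 2 && g[3] <= 6 &&
      g[4] >= 6 && g[4] <= 16 && g[5] == 1 && g[6] <= 2
  }))
}

#' Detect and classify cysteine arrays of mature peptides
#'
#' Locates cysteines, selects the eight structural ones (the leftmost subset
#' matching the canonical spacing template is preferred; an `x` position in
#' the template may itself be a cysteine), and classifies the array as
#' `canonical` (C5 adjacent to the C6..C8 terminal block, C1-C5 bond to the
#' second beta strand), `alternative` (C5 displaced towards C4) or
#' `noncanonical`. The middle cysteine of a `CCC` triad is never part of the
#' structural eight; cysteines outside the structural eight are reported as
#' `unpaired`. A sequence whose cysteines match a canonical array truncated
#' before C8 is flagged via `missing_c8` rather than raising an error.
#'
#' @param peptides Tibble of mature peptides with columns `id`, `residues`.
#' @return A tibble with one row per peptide: `peptide_id`, `n_cys`,
#'   `array_class`, `has_ccc`, `c1_c2_loop_len` (residues strictly between
#'   C1 and C2), `missing_c8`, and list columns `cys_positions`,
#'   `structural` (positions of the structural eight), `c5_candidates`
#'   (alternative C5 positions, when ambiguous) and `unpaired` (indices into
#'   `cys_positions` of cysteines outside the structural set).
#' @examples
#' detect_cysteine_arrays(tibble::tibble(
#'   id = "a", residues = "SCASRCKYRCRARRCRYYVSVRYGWFCYCRCLHC"
#' ))
#' @export
detect_cysteine_arrays <- function(peptides) {
  purrr::map2_dfr(peptides$id, peptides$residues, function(id, seq) {
    r <- classify_cys_array(seq)
    ranks <- seq_along(r$cys_positions)
    structural_ranks <- match(r$structural, r$cys_positions)
    tibble(
      peptide_id = id,
      n_cys = r$n_cys,
      array_class = r$array_class,
      has_ccc = r$has_ccc,
      c1_c2_loop_len = r$c1_c2_loop_len,
      missing_c8 = r$missing_c8,
      cys_positions = list(r$cys_positions),
      structural = list(r$structural),
      c5_candidates = list(r$c5_candidates),
      unpaired = list(setdiff(ranks, structural_ranks))
    )
  })
}

#' Assign disulfide topology from a cysteine-array report
#'
#' For canonical and alternative arrays the four disulfide bonds connect the
#' structural cysteines as C1-C5, C2-C6, C3-C7 and C4-C8. Cysteines outside
#' the structural eight (e.g., the middle cysteine of a CCC triad, whose
#' side chain points outwards and is unlikely to bond intra-molecularly) are
#' listed as unpaired. When two C5 positions are sterically plausible
#' (nine-cysteine arrays without a CCC triad), one complete pairing per
#' candidate is returned, distinguished by the `pairing` column.
#'
#' @param report Output of [detect_cysteine_arrays()].
#' @return A tibble with one row per bond: `peptide_id`, `pairing`
#'   (1-based pairing variant), `bond` (e.g. `"C1-C5"`), `cys_from`,
#'   `cys_to` (indices into the peptide's cysteine list), `pos_from`,
#'   `pos_to` (residue positions).
#' @export
assign_disulfides <- function(report) {
  bad <- report$array_class == "noncanonical"
  if (any(bad)) {
    abort(paste0(
      "topology undefined for noncanonical array(s): ",
      paste(report$peptide_id[bad], collapse = ", ")
    ))
  }
  purrr::pmap_dfr(
    list(report$peptide_id, report$cys_positions, report$structural,
         report$c5_candidates),
    function(id, pos, structural, c5s) {
      variants <- if (length(c5s) > 1) {
        lapply(c5s, function(c5) sort(c(structural[-5], c5)))
      } else {
        list(structural)
      }
      purrr::imap_dfr(variants, function(s, k) {
        idx <- match(s, pos)
        from <- 1:4
        to <- 5:8
        tibble(
          peptide_id = id,
          pairing = as.integer(k),
          bond = sprintf("C%d-C%d", from, to),
          cys_from = idx[from], cys_to = idx[to],
          pos_from = s[from], pos_to = s[to]
        )
      })
    }
  )
}

#' Count peptides containing a CCC triplet
#'
#' @param peptides Tibble with a `residues` column.
#' @return Integer count of peptides whose sequence contains at least one
#'   `CCC` substring.
#' @examples
#' count_ccc(dplyr::filter(mytilin_matures(), grepl("^P", name))) # 13
#' @export
count_ccc <- function(peptides) {
  if (!nrow(peptides)) return(0L)
  sum(stringr::str_detect(peptides$residues, "CCC"))
}
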