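# pKa set used for isoelectric-point calculations (EMBOSS values). Exposed
# as a constant so an alternative table can be swapped in one place.
PKA_EMBOSS <- c(
  nterm = 8.6, cterm = 3.6,
  C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5, Y = 10.1
)

#' Integer net charge of a peptide
#'
#' Counting rule: K and R contribute +1, D and E contribute -1; histidine,
#' cysteine, tyrosine and the free termini are ignored. This simple rule
#' reproduces the reported net charge of every peptide in the packaged
#' mytilin set (see [validate_mature_table()]).
#'
#' @param x Character vector of peptide sequences.
#' @return Integer vector of net charges.
#' @examples
#' net_charge("SCASRCKYRCRARRCRYYVSVRYGWFCYCRCLHC") # +9
#' @export
net_charge <- function(x) {
  as.integer(
    stringr::str_count(x, "K") + stringr::str_count(x, "R") -
      stringr::str_count(x, "D") - stringr::str_count(x, "E")
  )
}

# Henderson-Hasselbalch net charge of a peptide at a given pH, with free
# termini and D/E/C/Y/H/K/R side chains ionizable.
charge_at_ph <- function(seq, ph, pka = PKA_EMBOSS) {
  n <- function(res) stringr::str_count(seq, stringr::fixed(res))
  pos_frac <- function(pk) 1 / (1 + 10^(ph - pk))
  neg_frac <- function(pk) -1 / (1 + 10^(pk - ph))
  pos_frac(pka[["nterm"]]) +
    n("H") * pos_frac(pka[["H"]]) +
    n("K") * pos_frac(pka[["K"]]) +
    n("R") * pos_frac(pka[["R"]]) +
    neg_frac(pka[["cterm"]]) +
    n("C") * neg_frac(pka[["C"]]) +
    n("D") * neg_frac(pka[["D"]]) +
    n("E") * neg_frac(pka[["E"]]) +
    n("Y") * neg_frac(pka[["Y"]])
}

#' Isoelectric point of a peptide
#'
#' The pH at which the Henderson-Hasselbalch net charge (side chains
#' D, E, C, Y, H, K, R plus the free termini, EMBOSS pKa values) crosses
#' zero, found by bisection on \[0, 14\] to a charge tolerance of 1e-4.
#' The charge is strictly decreasing in pH, so the root is unique.
#'
#' @param x Character vector of non-empty peptide sequences.
#' @param pka Named pKa vector; defaults to the EMBOSS set.
#' @return Numeric vector of pI values in \[0, 14\].
#' @export
isoelectric_point <- function(x, pka = PKA_EMBOSS) {
  vapply(x, function(seq) {
    if (!nzchar(seq)) abort("isoelectric_point() needs a non-empty sequence")
    lo <- 0
    hi <- 14
    if (charge_at_ph(seq, lo, pka) < 0) return(0)
    if (charge_at_ph(seq, hi, pka) > 0) return(14)
    for (i in 1:100) {
      mid <- (lo + hi) / 2
      q <- charge_at_ph(seq, mid, pka)
      if (abs(q) < 1e-4) break
      if (q > 0) lo <- mid else hi <- mid
    }
    mid
  }, numeric(1), USE.NAMES = FALSE)
}

#' Sliding-window isoelectric-point profile
#'
#' Computes, for each peptide, the pI of every window of `window` residues
#' (leading-edge indexed: window *i* covers residues \[i, i+window-1\]).
#' Sequences shorter than the window yield a single whole-sequence value.
#' Plotted against window centers this reproduces the characteristic sharp
#' shift between the cationic mature region and the anionic C-terminal
#' extension of mytilin precursors.
#'
#' @param peptides Tibble with columns `id` and `residues`.
#' @param window Window size in residues (default 15).
#' @return A tibble with columns `peptide_id`, `start`, `center`
#'   (both 1-based) and `pi`.
#' @export
sliding_pi_profile <- function(peptides, window = 15L) {
  stopifnot(window >= 1L)
  purrr::map2_dfr(peptides$id, peptides$residues, function(id, seq) {
    len <- nchar(seq)
    w <- min(window, len)
    starts <- seq_len(max(len - window + 1L, 1L))
    subs <- substring(seq, starts, starts + w - 1L)
    tibble(
      peptide_id = id,
      start = as.integer(starts),
      center = as.integer(starts + (w - 1L) %/% 2L),
      pi = isoelectric_point(subs)
    )
  })
}
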