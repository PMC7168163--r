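# Cysteine-spacing templates (residues between consecutive cysteines) used
# by the generator. canonical/ccc/alternative mirror the three mytilin
# arrays; myticin_like and defensin_like are distinct CS-alpha-beta-style
# spacings that must NOT classify as mytilin arrays (decoy families).
ARRAY_TEMPLATES <- list(
  canonical = c(3L, 3L, 4L, 11L, 1L, 1L, 2L),
  ccc = c(3L, 3L, 4L, 11L, 1L, 0L, 0L, 2L),
  alternative = c(2L, 3L, 4L, 4L, 8L, 1L, 2L),
  myticin_like = c(4L, 3L, 4L, 7L, 0L, 3L, 4L),
  defensin_like = c(5L, 3L, 3L, 9L, 1L, 4L, 2L)
)

# Filler alphabets: cysteine-free so generated arrays are exact by
# construction. The mature filler up-weights K/R (cationic mature region);
# the C-tail filler up-weights D/E (anionic extension).
FILLER_NEUTRAL <- c("S", "G", "N", "Q", "T", "Y", "A", "V", "I", "L", "F",
                    "H", "P", "M", "W")
MATURE_FILLER_PROBS <- local({
  p <- c(
    S = 8, G = 6, N = 4, Q = 3, T = 4, Y = 6, A = 6, V = 4, I = 3, L = 3,
    F = 3, H = 3, P = 2, M = 1, W = 1, K = 10, R = 14, D = 2, E = 2
  )
  p / sum(p)
})
CTAIL_FILLER_PROBS <- local({
  p <- c(
    S = 6, G = 5, N = 4, Q = 4, T = 4, Y = 2, A = 5, V = 3, I = 2, L = 3,
    F = 2, H = 2, P = 3, M = 1, W = 1, K = 2, R = 2, D = 12, E = 12
  )
  p / sum(p)
})

# One most-frequent codon per amino acid (fixed, for reproducible
# back-translation); TAA as the stop codon.
CODON_TABLE <- c(
  A = "GCT", R = "CGT", N = "AAC", D = "GAT", C = "TGC", Q = "CAG",
  E = "GAA", G = "GGT", H = "CAC", I = "ATT", L = "CTG", K = "AAG",
  M = "ATG", F = "TTC", P = "CCA", S = "TCT", T = "ACT", W = "TGG",
  Y = "TAC", V = "GTT"
)

#' Configuration for the synthetic mytilin corpus
#'
#' Bundles the parameters of the synthetic-data generator. The defaults
#' emulate the precursor statistics of the mussel mytilin family: a ~20 aa
#' hydrophobic signal peptide, a 32-38 aa cysteine-rich cationic mature
#' region with a canonical or alternative 8/9-cysteine array, and an anionic
#' C-terminal extension; transcripts embed back-translated precursors
#' between untranslated flanks.
#'
#' @param seed Integer seed; the same seed yields byte-identical output.
#' @param n_mytilins,n_decoys Cohort sizes (60 mytilins and 60 decoys by
#'   default: the model-evaluation experiments split the mytilins into 30
#'   training and 30 held-out sequences against the 60 decoys).
#' @param sp_length Signal-peptide length in residues.
#' @param mature_length Inclusive range the per-sequence mature length is
#'   drawn from.
#' @param target_mature_charge,target_ctail_charge Net-charge targets; the
#'   per-sequence target jitters by -2..2 around these and is then hit
#'   exactly by a deterministic adjustment pass.
#' @param ctail_length C-terminal extension length.
#' @param n_transcripts,utr_length,rev_fraction Transcript-corpus shape:
#'   total transcripts, untranslated flank length (nt), and the fraction of
#'   embedded precursors placed on the reverse strand.
#' @param mutation_rate Per-site substitution rate applied to filler
#'   positions when deriving a family member from its family ancestor.
#' @return A named list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_mytilins = 60L, n_decoys = 60L,
                         sp_length = 20L, mature_length = c(32L, 38L),
                         target_mature_charge = 7L,
                         target_ctail_charge = -6L,
                         ctail_length = 30L, n_transcripts = 60L,
                         utr_length = 60L, rev_fraction = 1 / 3,
                         mutation_rate = 0.3) {
  stopifnot(
    seed == as.integer(seed), n_mytilins >= 0, n_decoys >= 0,
    sp_length >= 15, length(mature_length) == 2,
    mature_length[1] <= mature_length[2], ctail_length >= 0,
    target_ctail_charge <= 0, rev_fraction >= 0, rev_fraction <= 1,
    mutation_rate >= 0, mutation_rate < 1
  )
  structure(
    list(
      seed = as.integer(seed), n_mytilins = as.integer(n_mytilins),
      n_decoys = as.integer(n_decoys), sp_length = as.integer(sp_length),
      mature_length = as.integer(mature_length),
      target_mature_charge = as.integer(target_mature_charge),
      target_ctail_charge = as.integer(target_ctail_charge),
      ctail_length = as.integer(ctail_length),
      n_transcripts = as.integer(n_transcripts),
      utr_length = as.integer(utr_length),
      rev_fraction = rev_fraction, mutation_rate = mutation_rate
    ),
    class = "synth_config"
  )
}

# Charge adjustment pass: replaces unprotected filler residues until the
# K/R-D/E net charge equals `target`. Replacement positions are drawn from
# the generator's RNG stream (uniform over candidates) rather than e.g.
# leftmost-first, which would stamp identical cationic hotspots onto every
# generated mature; deterministic under the cohort seed.
adjust_charge <- function(chars, target, protect = integer(0)) {
  free <- setdiff(seq_along(chars), protect)
  nc <- function() {
    sum(chars %in% c("K", "R")) - sum(chars %in% c("D", "E"))
  }
  pick <- function(cand) cand[sample.int(length(cand), 1L)]
  up <- c("K", "R")
  k <- 0L
  while (nc() < target) {
    cand <- free[chars[free] %in% c(FILLER_NEUTRAL, "D", "E")]
    if (!length(cand)) abort("infeasible charge/length combination")
    chars[pick(cand)] <- up[k %% 2L + 1L]
    k <- k + 1L
  }
  while (nc() > target) {
    cand <- free[chars[free] %in% c("K", "R")]
    if (length(cand)) {
      chars[pick(cand)] <- "S"
    } else {
      cand <- free[chars[free] %in% FILLER_NEUTRAL]
      if (!length(cand)) abort("infeasible charge/length combination")
      chars[pick(cand)] <- c("D", "E")[k %% 2L + 1L]
      k <- k + 1L
    }
  }
  chars
}

# Mature region builder. The three mytilin kinds share a scaffold-anchored
# segment layout so that homologous filler positions flank the same
# structural cysteines across kinds (the biology: arrays differ by the
# position of C5 inside the conserved C4..C6 span — 12 filler residues in
# both the canonical and the alternative array — and by the extra cysteine
# of the CCC triad replacing the C6-C7 loop residue). A `base` ancestor
# (character vector of filler residues, segment-sliced) plus
# `mutation_rate` gives family members positional homology; decoy kinds use
# a plain linear template. The net charge is driven exactly to `charge` by
# a deterministic adjustment pass over unprotected fillers.
build_mature <- function(kind, len, charge, base = NULL, mutation_rate = 0) {
  mytilin <- kind %in% c("canonical", "ccc", "alternative")
  if (mytilin) {
    # segment lengths drawn from the ancestor pool layout:
    # prefix(<=6) C1 l1 C2 l2(3) C3 l3(4) C4 big(12, C5 embedded) C6 l6 C7
    # l7(2) C8 suffix(<=1)
    core_len <- if (kind == "alternative") 32L else 33L
    if (len < core_len) {
      abort(sprintf(
        "infeasible charge/length combination: %s array needs >= %d residues",
        kind, core_len
      ))
    }
    extra <- len - core_len
    suffix_len <- min(extra, 1L)
    prefix_len <- extra - suffix_len
    if (prefix_len > 6L) abort("mature length too long for the scaffold")
    pool <- if (is.null(base)) {
      sample(names(MATURE_FILLER_PROBS), 32, replace = TRUE,
             prob = MATURE_FILLER_PROBS)
    } else {
      rep_len(base, 32)
    }
    seg <- list(
      prefix = pool[1:6], l1 = pool[7:9], l2 = pool[10:12], l3 = pool[13:16],
      big = pool[17:28], l6 = pool[29], l7 = pool[30:31], suffix = pool[32]
    )
    mut <- function(x) {
      if (!length(x) || is.null(base)) return(x)
      hit <- runif(length(x)) < mutation_rate
      x[hit] <- sample(names(MATURE_FILLER_PROBS), sum(hit), replace = TRUE,
                       prob = MATURE_FILLER_PROBS)
      x
    }
    l1 <- mut(if (kind == "alternative") seg$l1[1:2] else seg$l1)
    big <- mut(seg$big)
    c5_offset <- if (kind == "alternative") 4L else 11L
    big_block <- append(big, "C", after = c5_offset)
    l6 <- if (kind == "ccc") "C" else mut(seg$l6)
    chars <- c(
      if (prefix_len > 0) mut(tail(seg$prefix, prefix_len)),
      "C", l1, "C", mut(seg$l2), "C", mut(seg$l3), "C",
      big_block, "C", l6, "C", mut(seg$l7), "C",
      if (suffix_len > 0) mut(seg$suffix)
    )
    stopifnot(length(chars) == len)
  } else {
    gaps <- ARRAY_TEMPLATES[[kind]]
    core_len <- length(gaps) + 1L + sum(gaps)
    if (len < core_len) {
      abort(sprintf(
        "infeasible charge/length combination: %s array needs >= %d residues",
        kind, core_len
      ))
    }
    extra <- len - core_len
    suffix <- min(extra, 1L)
    prefix <- extra - suffix
    cys_rel <- cumsum(c(1L, gaps + 1L))
    cys_pos <- cys_rel + prefix
    chars <- rep(NA_character_, len)
    chars[cys_pos] <- "C"
    filler_idx <- which(is.na(chars))
    chars[filler_idx] <- draw_filler(length(filler_idx), MATURE_FILLER_PROBS,
                                     base, mutation_rate)
  }
  cys_pos <- which(chars == "C")
  if (sum(chars != "C") < abs(charge)) {
    abort("infeasible charge/length combination")
  }
  chars <- adjust_charge(chars, charge, protect = cys_pos)
  paste(chars, collapse = "")
}

draw_filler <- function(n, probs, base = NULL, mutation_rate = 0) {
  fresh <- sample(names(probs), n, replace = TRUE, prob = probs)
  if (is.null(base)) return(fresh)
  base <- rep_len(base, n)
  mutate <- runif(n) < mutation_rate
  ifelse(mutate, fresh, base)
}

# Signal peptide: M + polar n-region, a hydrophobic h-region at
# (len-12)..(len-3) drawn from {I,L,F,M,W} (A/V are avoided there so the
# small-residue cleavage bonuses stay unique to the true site), then the
# (-3, -1) motif: V at -3, polar at -2, small (A/G/S) at -1. Positions are
# drawn per residue class; a `base` ancestor with the same length is
# inherited position-wise within each class and mutated at `mutation_rate`.
build_sp <- function(len, base = NULL, mutation_rate = 0) {
  stopifnot(len >= 15)
  h_core <- c("I", "L", "F", "M", "W")
  polar <- c("Q", "N", "H", "T")
  class_of <- character(len)
  class_of[1] <- "M"
  if (len - 13L >= 2L) class_of[2:(len - 13L)] <- "n"
  class_of[(len - 12L):(len - 3L)] <- "h"
  class_of[len - 2L] <- "m3"
  class_of[len - 1L] <- "p"
  class_of[len] <- "m1"
  pool <- list(
    M = "M", n = c("K", "R", "N", "Q", "T", "S"), h = h_core,
    m3 = "V", p = polar, m1 = c("A", "G", "S")
  )
  chars <- vapply(seq_len(len), function(i) {
    p <- pool[[class_of[i]]]
    if (length(p) == 1) p else sample(p, 1)
  }, character(1))
  if (!is.null(base) && length(base) == len) {
    mutate <- runif(len) < mutation_rate
    for (i in which(!mutate)) {
      if (base[i] %in% pool[[class_of[i]]]) chars[i] <- base[i]
    }
  }
  paste(chars, collapse = "")
}

build_ctail <- function(len, charge, base = NULL, mutation_rate = 0) {
  if (len == 0L) {
    if (charge != 0) abort("infeasible charge/length combination")
    return("")
  }
  if (len < abs(charge)) abort("infeasible charge/length combination")
  chars <- draw_filler(len, CTAIL_FILLER_PROBS, base, mutation_rate)
  chars <- adjust_charge(chars, charge)
  paste(chars, collapse = "")
}

#' Generate one synthetic mytilin-like precursor with its true annotation
#'
#' Builds a tripartite precursor (hydrophobic signal peptide, cysteine-rich
#' cationic mature region with the requested array, anionic C-terminal
#' extension). The mature region matches the requested cysteine template
#' exactly (fillers are cysteine-free) and the mature/C-tail net charges
#' equal their targets after a deterministic adjustment pass. Uses the
#' current RNG state; seed via [synth_cohort()] or [withr::with_seed()].
#'
#' @param id Peptide id.
#' @param array_kind `"canonical"`, `"ccc"` or `"alternative"`.
#' @param sp_length,mature_length,ctail_length Segment lengths (residues).
#' @param mature_charge,ctail_charge Exact net-charge targets.
#' @param base Optional list with `sp`, `mature`, `ctail` filler templates
#'   (family ancestor) to derive from.
#' @param mutation_rate Per-site substitution rate applied against `base`.
#' @return A one-row tibble: `id`, `residues`, `provenance`, `array_kind`,
#'   plus the true annotation columns `sp_end`, `mature_start`,
#'   `mature_end`, `ctail_start`, `ctail_end`.
#' @export
make_precursor <- function(id, array_kind = c("canonical", "ccc",
                                              "alternative"),
                           sp_length = 20L, mature_length = 34L,
                           ctail_length = 30L, mature_charge = 7L,
                           ctail_charge = -6L, base = NULL,
                           mutation_rate = 0) {
  array_kind <- match.arg(array_kind)
  sp <- build_sp(sp_length, base$sp, mutation_rate)
  mature <- build_mature(array_kind, mature_length, mature_charge,
                         base$mature, mutation_rate)
  ctail <- build_ctail(ctail_length, ctail_charge, base$ctail, mutation_rate)
  tibble(
    id = id,
    residues = paste0(sp, mature, ctail),
    provenance = "synthetic",
    array_kind = array_kind,
    sp_end = sp_length,
    mature_start = sp_length + 1L,
    mature_end = sp_length + mature_length,
    ctail_start = if (ctail_length > 0) sp_length + mature_length + 1L
    else NA_integer_,
    ctail_end = if (ctail_length > 0) {
      sp_length + mature_length + ctail_length
    } else {
      NA_integer_
    }
  )
}

#' Generate a decoy peptide
#'
#' Three decoy kinds stand in for the non-mytilin sequences a real screen
#' must reject: `"shuffled"` permutes the residues of a given mytilin
#' (preserving composition), while `"myticin_like"` and `"defensin_like"`
#' carry fixed cysteine spacings distinct from both mytilin arrays.
#' Uses the current RNG state.
#'
#' @param id Peptide id.
#' @param kind Decoy kind.
#' @param source Mature mytilin sequence to permute (required for
#'   `"shuffled"`).
#' @param mature_length,mature_charge Size/charge of template decoys.
#' @return A one-row tibble `id`, `residues`, `provenance`, `kind`.
#' @export
make_decoy <- function(id, kind = c("shuffled", "myticin_like",
                                    "defensin_like"),
                       source = NULL, mature_length = 34L,
                       mature_charge = 4L) {
  kind <- match.arg(kind)
  residues <- if (kind == "shuffled") {
    if (is.null(source)) abort("shuffled decoys need a `source` sequence")
    chars <- strsplit(source, "")[[1]]
    paste(sample(chars), collapse = "")
  } else {
    gaps <- ARRAY_TEMPLATES[[kind]]
    core_len <- length(gaps) + 1L + sum(gaps)
    build_mature(kind, max(mature_length, core_len), mature_charge)
  }
  tibble(id = id, residues = residues, provenance = "synthetic", kind = kind)
}

#' Generate a decoy precursor (full tripartite structure, non-mytilin array)
#'
#' A complete precursor carrying a myticin-like or defensin-like mature
#' region between a genuine signal peptide and an anionic tail — the kind
#' of related CS-alpha-beta ORF an over-permissive screen would accept.
#'
#' @inheritParams make_precursor
#' @param kind `"myticin_like"` or `"defensin_like"`.
#' @return A one-row tibble as in [make_precursor()] (with `array_kind` set
#'   to the decoy kind).
#' @export
make_decoy_precursor <- function(id, kind = c("myticin_like",
                                              "defensin_like"),
                                 sp_length = 20L, mature_length = 35L,
                                 ctail_length = 30L, mature_charge = 4L,
                                 ctail_charge = -5L) {
  kind <- match.arg(kind)
  gaps <- ARRAY_TEMPLATES[[kind]]
  core_len <- length(gaps) + 1L + sum(gaps)
  mature_length <- max(mature_length, core_len)
  sp <- build_sp(sp_length)
  mature <- build_mature(kind, mature_length, mature_charge)
  ctail <- build_ctail(ctail_length, ctail_charge)
  tibble(
    id = id,
    residues = paste0(sp, mature, ctail),
    provenance = "synthetic",
    array_kind = kind,
    sp_end = sp_length,
    mature_start = sp_length + 1L,
    mature_end = sp_length + mature_length,
    ctail_start = sp_length + mature_length + 1L,
    ctail_end = sp_length + mature_length + ctail_length
  )
}

# Back-translate a peptide with the fixed codon table (stop codon appended).
back_translate <- function(residues) {
  chars <- strsplit(residues, "")[[1]]
  paste0(paste(CODON_TABLE[chars], collapse = ""), "TAA")
}

random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Untranslated flanks must not extend an embedded ORF upstream: strip every
# ATG (and CAT, its reverse complement) so the recorded ORF start is the
# true leftmost in-frame start on either strand.
sanitize_utr <- function(x) {
  repeat {
    y <- gsub("CAT", "CTT", gsub("ATG", "ACG", x), fixed = TRUE)
    if (identical(y, x)) return(y)
    x <- y
  }
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Embed precursors in a synthetic transcript corpus
#'
#' Back-translates each precursor with a fixed codon table into a complete
#' ATG..stop ORF, flanks it with random untranslated sequence, and places a
#' stated fraction on the reverse strand. Remaining transcripts are pure
#' random sequence. Uses the current RNG state.
#'
#' @param precursors Tibble with `id`, `residues` (precursors must start
#'   with M).
#' @param n_transcripts Total transcripts (>= `nrow(precursors)`).
#' @param utr_length Flank length (nt) on each side.
#' @param rev_fraction Fraction of embedded ORFs on the reverse strand.
#' @return A list: `transcripts` (tibble `id`, `nucleotides`, `description`)
#'   and `truth` (tibble `transcript_id`, `peptide_id`, `strand`, `frame`,
#'   `orf_start`, `orf_end`; forward-strand 1-based coordinates including
#'   the stop codon).
#' @export
make_transcripts <- function(precursors, n_transcripts = nrow(precursors),
                             utr_length = 60L, rev_fraction = 1 / 3) {
  n_emb <- nrow(precursors)
  stopifnot(n_transcripts >= n_emb)
  if (n_emb && any(substr(precursors$residues, 1, 1) != "M")) {
    abort("precursors must start with M to form complete ORFs")
  }
  n_rev <- floor(n_emb * rev_fraction)
  is_rev <- rep(c(TRUE, FALSE), c(n_rev, n_emb - n_rev))
  transcripts <- vector("list", n_transcripts)
  truth <- vector("list", n_emb)
  for (i in seq_len(n_emb)) {
    orf <- back_translate(precursors$residues[i])
    utr5 <- sanitize_utr(random_nt(utr_length))
    utr3 <- sanitize_utr(random_nt(utr_length))
    fwd <- paste0(utr5, orf, utr3)
    s <- utr_length + 1L
    e <- utr_length + nchar(orf)
    tid <- sprintf("tx_%03d", i)
    if (is_rev[i]) {
      seq <- revcomp(fwd)
      len <- nchar(seq)
      start <- len - e + 1L
      end <- len - s + 1L
      frame <- -(((len - end) %% 3L) + 1L)
      truth[[i]] <- tibble(
        transcript_id = tid, peptide_id = precursors$id[i],
        strand = "-", frame = frame, orf_start = start, orf_end = end
      )
      transcripts[[i]] <- tibble(
        id = tid, nucleotides = seq,
        description = paste0("embeds ", precursors$id[i], " (reverse)")
      )
    } else {
      frame <- ((s - 1L) %% 3L) + 1L
      truth[[i]] <- tibble(
        transcript_id = tid, peptide_id = precursors$id[i],
        strand = "+", frame = frame, orf_start = s, orf_end = e
      )
      transcripts[[i]] <- tibble(
        id = tid, nucleotides = fwd,
        description = paste0("embeds ", precursors$id[i])
      )
    }
  }
  for (i in seq_len(n_transcripts - n_emb)) {
    transcripts[[n_emb + i]] <- tibble(
      id = sprintf("tx_%03d", n_emb + i),
      nucleotides = random_nt(2L * utr_length + 300L),
      description = "background transcript"
    )
  }
  list(transcripts = bind_rows(transcripts), truth = bind_rows(truth))
}

#' Generate a chained-divergence screen corpus
#'
#' Builds a transcript corpus that exercises the point of *iterative*
#' screening: five close homologs share the seed's N-terminal mature block
#' (C1..C4) but carry freshly drawn C-terminal blocks, and three remote
#' homologs share a close homolog's C-terminal block but carry fresh
#' N-terminal blocks — so remotes have no significant similarity to the
#' seed itself and are reachable only through the close homologs. Decoy
#' precursors (myticin-like, defensin-like) and background transcripts are
#' added. Deterministic given `seed`.
#'
#' @param seed Integer seed.
#' @param n_close,n_remote Homolog counts (defaults 5 and 3).
#' @param n_decoys Number of embedded decoy precursor ORFs (default 4).
#' @param n_background Additional random transcripts (default 10).
#' @return A list: `seeds` (one annotated seed precursor), `transcripts`,
#'   `truth` (embedded ORF coordinates with a `tier` column:
#'   close/remote/decoy).
#' @export
synth_chained_corpus <- function(seed = 1L, n_close = 5L, n_remote = 3L,
                                 n_decoys = 4L, n_background = 10L) {
  stopifnot(n_remote <= n_close)
  withr::with_seed(seed, {
    sp_len <- 20L
    mat_len <- 34L
    split_at <- 15L # last residue of the C1..C4 block in a 34-aa mature
    n_block <- function(m) substr(m, 1, split_at)
    c_block <- function(m) substr(m, split_at + 1L, mat_len)
    assemble <- function(id, mature, sp = sp_len, tail_len = 30L) {
      tibble(
        id = id,
        residues = paste0(build_sp(sp), mature, build_ctail(tail_len, -6L)),
        provenance = "synthetic",
        sp_end = sp, mature_start = sp + 1L,
        mature_end = sp + nchar(mature)
      )
    }
    seed_mature <- build_mature("canonical", mat_len, 8L)
    seed_prec <- assemble("seed_mytilin", seed_mature)
    close <- purrr::map_dfr(seq_len(n_close), function(i) {
      donor <- build_mature("canonical", mat_len, 8L)
      assemble(sprintf("close_%d", i),
               paste0(n_block(seed_mature), c_block(donor)))
    })
    # Remote matures: the parent close homolog's C-terminal block behind a
    # freshly drawn N-terminal block with a shortened C3-C4 loop (2 aa, a
    # relaxed-canonical array as seen in T. hirsuta-like matures). The loop
    # change breaks the cysteine register against the seed, and different
    # signal-peptide/tail lengths break the precursor-wide register, so the
    # only strong similarity remotes retain is to their parent close
    # homolog.
    remote <- purrr::map_dfr(seq_len(n_remote), function(j) {
      fillers <- sample(names(MATURE_FILLER_PROBS), 9, replace = TRUE,
                        prob = MATURE_FILLER_PROBS)
      n_part <- paste0(
        fillers[1], "C", paste(fillers[2:4], collapse = ""), "C",
        paste(fillers[5:7], collapse = ""), "C",
        paste(fillers[8:9], collapse = ""), "C"
      )
      close_mature <- substr(close$residues[j], sp_len + 1L,
                             sp_len + mat_len)
      assemble(sprintf("remote_%d", j),
               paste0(n_part, c_block(close_mature)),
               sp = 18L, tail_len = 24L)
    })
    decoys <- purrr::map_dfr(seq_len(n_decoys), function(k) {
      kind <- c("myticin_like", "defensin_like")[(k - 1L) %% 2L + 1L]
      p <- make_decoy_precursor(sprintf("decoy_%d", k), kind)
      p[, c("id", "residues", "provenance", "sp_end", "mature_start",
            "mature_end")]
    })
    embedded <- bind_rows(close, remote, decoys)
    tx <- make_transcripts(
      embedded, n_transcripts = nrow(embedded) + n_background,
      utr_length = 60L, rev_fraction = 1 / 3
    )
    truth <- tx$truth %>%
      mutate(tier = dplyr::case_when(
        grepl("^close", .data$peptide_id) ~ "close",
        grepl("^remote", .data$peptide_id) ~ "remote",
        .default = "decoy"
      ))
    list(seeds = seed_prec, transcripts = tx$transcripts, truth = truth)
  })
}

#' Generate the full synthetic study cohort
#'
#' Deterministically (seeded from `config$seed`) generates two diverged
#' mytilin families — a *Mytilus*-like family (canonical-array-heavy,
#' strongly cationic matures) and a *Perna*-like family (alternative/CCC
#' arrays, weaker cationicity) — each derived from a family ancestor by
#' per-site filler mutation, plus decoys (one third each shuffled,
#' myticin-like, defensin-like) and a transcript corpus embedding the
#' mytilin precursors.
#'
#' @param config A [synth_config()].
#' @return A list: `precursors` (mytilin precursors with true annotations
#'   and `family`), `matures` (their mature regions), `decoys`,
#'   `transcripts`, `truth`.
#' @export
synth_cohort <- function(config = synth_config()) {
  withr::with_seed(config$seed, {
    n <- config$n_mytilins
    n_myt_family <- ceiling(n * 0.6)
    fam <- rep(c("mytilus", "perna"), c(n_myt_family, n - n_myt_family))
    kind_probs <- list(
      mytilus = c(canonical = 0.8, ccc = 0, alternative = 0.2),
      perna = c(canonical = 0.2, ccc = 0.4, alternative = 0.4)
    )
    # deterministic per-family kind allocation at the stated proportions,
    # interleaved so any contiguous or alternating subset sees every kind
    kind_of <- unlist(lapply(unique(fam), function(f) {
      nf <- sum(fam == f)
      p <- kind_probs[[f]]
      counts <- diff(round(cumsum(c(0, p)) * nf))
      kinds <- rep(names(p), counts)
      if (length(kinds) < nf) {
        kinds <- c(kinds, rep(names(p)[which.max(p)], nf - length(kinds)))
      }
      kinds[order(stats::ave(seq_len(nf), kinds, FUN = seq_along))]
    }), use.names = FALSE)
    charge_shift <- c(mytilus = 0L, perna = -4L)
    ancestors <- list(
      mytilus = list(
        sp = strsplit(build_sp(config$sp_length), "")[[1]],
        mature = sample(names(MATURE_FILLER_PROBS), 50, replace = TRUE,
                        prob = MATURE_FILLER_PROBS),
        ctail = sample(names(CTAIL_FILLER_PROBS), 50, replace = TRUE,
                       prob = CTAIL_FILLER_PROBS)
      ),
      perna = list(
        sp = strsplit(build_sp(config$sp_length), "")[[1]],
        mature = sample(names(MATURE_FILLER_PROBS), 50, replace = TRUE,
                        prob = MATURE_FILLER_PROBS),
        ctail = sample(names(CTAIL_FILLER_PROBS), 50, replace = TRUE,
                       prob = CTAIL_FILLER_PROBS)
      )
    )
    precursors <- purrr::map_dfr(seq_len(n), function(i) {
      f <- fam[i]
      kind <- kind_of[i]
      min_len <- length(ARRAY_TEMPLATES[[kind]]) + 1L +
        sum(ARRAY_TEMPLATES[[kind]])
      len_range <- max(config$mature_length[1], min_len):
        max(config$mature_length[2], min_len)
      len <- if (length(len_range) == 1L) len_range else sample(len_range, 1)
      q_mat <- config$target_mature_charge + charge_shift[[f]] +
        sample(-2:2, 1)
      q_ct <- min(config$target_ctail_charge + sample(-1:1, 1), 0L)
      p <- make_precursor(
        id = sprintf("myt_%03d", i), array_kind = kind,
        sp_length = config$sp_length, mature_length = len,
        ctail_length = config$ctail_length,
        mature_charge = q_mat, ctail_charge = q_ct,
        base = ancestors[[f]], mutation_rate = config$mutation_rate
      )
      p$family <- f
      p
    })
    matures <- tibble(
      id = precursors$id,
      residues = substring(precursors$residues, precursors$mature_start,
                           precursors$mature_end)
    )
    n_dec <- config$n_decoys
    kinds <- rep(c("shuffled", "myticin_like", "defensin_like"),
                 length.out = n_dec)
    decoys <- purrr::map_dfr(seq_len(n_dec), function(i) {
      src <- if (kinds[i] == "shuffled") {
        matures$residues[(i - 1L) %% nrow(matures) + 1L]
      }
      make_decoy(sprintf("dec_%03d", i), kinds[i], source = src,
                 mature_charge = 4L + sample(-2:2, 1))
    })
    tx <- make_transcripts(
      precursors, config$n_transcripts, config$utr_length,
      config$rev_fraction
    )
    list(
      precursors = precursors, matures = matures, decoys = decoys,
      transcripts = tx$transcripts, truth = tx$truth
    )
  })
}
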