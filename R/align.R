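# Single source of truth for alignment scoring: BLOSUM62 with affine gaps,
# a gap of length L costing GAP_OPEN + GAP_EXT * L (common BLAST defaults).
GAP_OPEN <- 11
GAP_EXT <- 1

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

pa_to_row <- function(pa, query_id, target_id, type) {
  aq <- as.character(Biostrings::alignedPattern(pa))
  at <- as.character(Biostrings::alignedSubject(pa))
  tibble(
    query_id = query_id, target_id = target_id,
    aligned_query = unname(aq), aligned_target = unname(at),
    score = Biostrings::score(pa),
    percent_identity = percent_identity(unname(aq), unname(at)),
    type = type
  )
}

#' Pairwise global (Needleman-Wunsch) alignment
#'
#' Optimal global alignment under BLOSUM62 with affine gap penalties
#' (open 11, extend 1). Backed by [Biostrings::pairwiseAlignment()]; the
#' score is the exhaustive optimum (verified against a brute-force
#' enumeration oracle in the test suite) and a single optimal traceback is
#' returned deterministically.
#'
#' @param a,b Peptide sequences (character scalars).
#' @param query_id,target_id Optional ids recorded in the result.
#' @param gap_open,gap_extend Affine gap penalties.
#' @return A one-row tibble: `query_id`, `target_id`, `aligned_query`,
#'   `aligned_target` (equal-length gapped strings that degap back to the
#'   inputs), `score`, `percent_identity`, `type`.
#' @examples
#' align_global("ACDE", "ACE")
#' @export
align_global <- function(a, b, query_id = "query", target_id = "target",
                         gap_open = GAP_OPEN, gap_extend = GAP_EXT) {
  stopifnot(nzchar(a), nzchar(b))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = blosum62(),
    gapOpening = gap_open, gapExtension = gap_extend, type = "global"
  )
  pa_to_row(pa, query_id, target_id, "global")
}

#' Pairwise local (Smith-Waterman) alignment
#'
#' As [align_global()] but with Smith-Waterman semantics: the score is the
#' best-scoring (possibly empty) local segment pair and is never negative.
#' For sequences with no positively scoring segment the alignment is empty
#' with score 0.
#'
#' @inheritParams align_global
#' @return A one-row tibble as in [align_global()]; `aligned_query` and
#'   `aligned_target` cover only the aligned segment.
#' @export
align_local <- function(a, b, query_id = "query", target_id = "target",
                        gap_open = GAP_OPEN, gap_extend = GAP_EXT) {
  stopifnot(nzchar(a), nzchar(b))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = blosum62(),
    gapOpening = gap_open, gapExtension = gap_extend, type = "local"
  )
  if (Biostrings::score(pa) <= 0) {
    return(tibble(
      query_id = query_id, target_id = target_id,
      aligned_query = "", aligned_target = "",
      score = 0, percent_identity = NA_real_, type = "local"
    ))
  }
  pa_to_row(pa, query_id, target_id, "local")
}

#' Percent identity of an alignment
#'
#' 100 * (identical columns) / (aligned columns); the denominator includes
#' gapped columns, a choice that is stated explicitly because reported
#' identity percentages rarely specify it.
#'
#' @param aligned_a,aligned_b Equal-length gapped strings.
#' @return Identity percentage in \[0, 100\].
#' @export
percent_identity <- function(aligned_a, aligned_b) {
  stopifnot(nchar(aligned_a) == nchar(aligned_b))
  if (!nchar(aligned_a)) return(NA_real_)
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  100 * sum(ca == cb & ca != "-") / length(ca)
}

# All-vs-all global alignment scores and identities, vectorized one subject
# at a time. Returns list(score=matrix, pid=matrix).
pairwise_global_stats <- function(seqs) {
  n <- length(seqs)
  S <- matrix(0, n, n)
  P <- matrix(100, n, n)
  set <- Biostrings::AAStringSet(seqs)
  for (j in seq_len(n)) {
    if (j == 1) next
    idx <- seq_len(j - 1L)
    pa <- Biostrings::pairwiseAlignment(
      set[idx], Biostrings::AAString(seqs[[j]]),
      substitutionMatrix = blosum62(),
      gapOpening = GAP_OPEN, gapExtension = GAP_EXT, type = "global"
    )
    S[idx, j] <- S[j, idx] <- Biostrings::score(pa)
    P[idx, j] <- P[j, idx] <- Biostrings::pid(pa, type = "PID1")
  }
  diag(S) <- vapply(
    seq_len(n),
    function(i) self_score(seqs[[i]]), numeric(1)
  )
  list(score = S, pid = P)
}

# Score of a sequence aligned to itself (no DP needed: sum of diagonal
# substitution scores).
self_score <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  B <- blosum62()
  sum(B[cbind(chars, chars)])
}

#' Progressive multiple sequence alignment
#'
#' Guide-tree progressive alignment: pairwise global-alignment identities
#' define distances, the guide tree is UPGMA (average-linkage) on those
#' distances, and profiles are merged leaf-to-root with an affine-gap
#' profile-profile Needleman-Wunsch (column score = average BLOSUM62 score
#' over residue pairs). Deterministic given the input order; no iterative
#' refinement, which is sufficient at the scale of tens of short peptides.
#'
#' @param peptides Tibble with columns `id` (unique) and `residues`.
#' @return A tibble with columns `id` and `aligned` (equal-length rows, in
#'   the input order); degapping any row recovers its input sequence.
#' @export
progressive_msa <- function(peptides) {
  ids <- peptides$id
  seqs <- peptides$residues
  if (anyDuplicated(ids)) abort("peptide ids must be unique")
  n <- length(seqs)
  if (n == 0) abort("no sequences to align")
  if (n == 1) return(tibble(id = ids, aligned = seqs))
  if (n == 2) {
    al <- align_global(seqs[1], seqs[2])
    return(tibble(id = ids, aligned = c(al$aligned_query, al$aligned_target)))
  }
  D <- 1 - pairwise_global_stats(seqs)$pid / 100
  hc <- hclust(as.dist(D), method = "average")
  profiles <- vector("list", n - 1)
  leaf_profile <- function(i) {
    list(ids = ids[i], rows = matrix(strsplit(seqs[i], "")[[1]], nrow = 1))
  }
  get_node <- function(k) if (k < 0) leaf_profile(-k) else profiles[[k]]
  for (k in seq_len(n - 1)) {
    a <- get_node(hc$merge[k, 1])
    b <- get_node(hc$merge[k, 2])
    profiles[[k]] <- profile_align(a, b)
  }
  final <- profiles[[n - 1]]
  ord <- match(ids, final$ids)
  tibble(
    id = ids,
    aligned = vapply(
      ord, function(i) paste(final$rows[i, ], collapse = ""), character(1)
    )
  )
}

# Profile-profile affine Needleman-Wunsch. A profile is a list(ids, rows)
# with rows a character matrix (sequences x columns, "-" for gaps).
profile_align <- function(pa, pb) {
  alph <- AA_ALPHABET
  S <- blosum62()[alph, alph]
  count_profile <- function(p) {
    cnt <- apply(p$rows, 2, function(col) {
      tab <- table(factor(col[col != "-"], levels = alph))
      as.numeric(tab)
    })
    matrix(cnt, nrow = length(alph))
  }
  CA <- count_profile(pa) # |alph| x LA
  CB <- count_profile(pb)
  LA <- ncol(CA)
  LB <- ncol(CB)
  nA <- nrow(pa$rows)
  nB <- nrow(pb$rows)
  colscore <- t(CA) %*% S %*% CB / (nA * nB)

  neg <- -1e18
  open <- GAP_OPEN + GAP_EXT
  M <- matrix(neg, LA + 1, LB + 1)
  X <- matrix(neg, LA + 1, LB + 1) # gap in B (consume A column)
  Y <- matrix(neg, LA + 1, LB + 1) # gap in A (consume B column)
  M[1, 1] <- 0
  for (i in seq_len(LA)) X[i + 1, 1] <- -(GAP_OPEN + GAP_EXT * i)
  for (j in seq_len(LB)) Y[1, j + 1] <- -(GAP_OPEN + GAP_EXT * j)
  for (i in seq_len(LA)) {
    for (j in seq_len(LB)) {
      M[i + 1, j + 1] <- colscore[i, j] + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - open, X[i, j + 1] - GAP_EXT,
                             Y[i, j + 1] - open)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open, X[i + 1, j] - open,
                             Y[i + 1, j] - GAP_EXT)
    }
  }
  # Traceback; ties resolved match > gap-in-B > gap-in-A for determinism.
  i <- LA
  j <- LB
  state <- c("M", "X", "Y")[which.max(c(M[i + 1, j + 1], X[i + 1, j + 1],
                                        Y[i + 1, j + 1]))]
  take_a <- logical(0)
  take_b <- logical(0)
  eps <- 1e-9
  while (i > 0 || j > 0) {
    if (state == "M") {
      take_a <- c(TRUE, take_a)
      take_b <- c(TRUE, take_b)
      prev <- M[i + 1, j + 1] - colscore[i, j]
      state <- if (abs(prev - M[i, j]) < eps) "M"
      else if (abs(prev - X[i, j]) < eps) "X" else "Y"
      i <- i - 1
      j <- j - 1
    } else if (state == "X") {
      take_a <- c(TRUE, take_a)
      take_b <- c(FALSE, take_b)
      cur <- X[i + 1, j + 1]
      state <- if (abs(cur - (M[i, j + 1] - open)) < eps) "M"
      else if (abs(cur - (X[i, j + 1] - GAP_EXT)) < eps) "X" else "Y"
      i <- i - 1
    } else {
      take_a <- c(FALSE, take_a)
      take_b <- c(TRUE, take_b)
      cur <- Y[i + 1, j + 1]
      state <- if (abs(cur - (M[i + 1, j] - open)) < eps) "M"
      else if (abs(cur - (X[i + 1, j] - open)) < eps) "X" else "Y"
      j <- j - 1
    }
  }
  L <- length(take_a)
  rows <- matrix("-", nA + nB, L)
  rows[seq_len(nA), take_a] <- pa$rows
  rows[nA + seq_len(nB), take_b] <- pb$rows
  list(ids = c(pa$ids, pb$ids), rows = rows)
}
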