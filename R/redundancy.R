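#' BLOSUM62 distance between two peptides
#'
#' `d(a, b) = 1 - S(a, b) / min(S(a, a), S(b, b))`, where `S` is the
#' affine-gap global alignment score, clipped to \[0, 1\]. Identical
#' sequences have distance 0 and the measure is symmetric; normalizing by
#' the smaller self-score keeps the ratio at most 1 for any pair.
#'
#' @param a,b Peptide sequences.
#' @return Distance in \[0, 1\].
#' @export
blosum_distance <- function(a, b) {
  s <- align_global(a, b)$score
  d <- 1 - s / min(self_score(a), self_score(b))
  min(max(d, 0), 1)
}

#' Build a pairwise BLOSUM62 distance graph
#'
#' Computes all pairwise [blosum_distance()] values for a sequence set; the
#' graph's edges are the pairs below `threshold` (the redundancy neighbors).
#'
#' @param peptides Tibble with columns `id` (unique) and `residues`.
#' @param threshold Distance below which two sequences count as redundant
#'   neighbors (default 0.1).
#' @return An object of class `distance_graph`: list with `ids`, symmetric
#'   matrix `d`, and `threshold`. Use [tidy()] for an edge-list tibble.
#' @export
distance_graph <- function(peptides, threshold = 0.1) {
  if (anyDuplicated(peptides$id)) abort("peptide ids must be unique")
  seqs <- peptides$residues
  n <- length(seqs)
  stats <- pairwise_global_stats(seqs)
  self <- diag(stats$score)
  D <- matrix(0, n, n, dimnames = list(peptides$id, peptides$id))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      D[i, j] <- min(max(1 - stats$score[i, j] / min(self[i], self[j]), 0), 1)
    }
  }
  structure(
    list(ids = peptides$id, d = D, threshold = threshold),
    class = "distance_graph"
  )
}

#' @export
print.distance_graph <- function(x, ...) {
  n_edges <- sum(x$d < x$threshold & upper.tri(x$d))
  cat(
    "<distance_graph> ", length(x$ids), " sequences, ",
    n_edges, " pair(s) below threshold ", x$threshold, "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname distance_graph
#' @param x A `distance_graph`.
#' @param ... Unused.
#' @export
tidy.distance_graph <- function(x, ...) {
  idx <- which(upper.tri(x$d), arr.ind = TRUE)
  tibble(
    from = x$ids[idx[, 1]],
    to = x$ids[idx[, 2]],
    distance = x$d[idx],
    neighbor = x$d[idx] < x$threshold
  )
}

#' Hobohm algorithm-2 redundancy reduction
#'
#' Greedy reduction of a redundant sequence set: while any pair sits below
#' the distance threshold, delete the vertex with the most sub-threshold
#' neighbors (ties broken by lexicographically greatest id, for
#' reproducibility) and repeat. The retained set contains no pair below the
#' threshold, which is asserted on every run.
#'
#' @param graph A [distance_graph()].
#' @return A tibble with one row per input sequence: `id`, `retained`,
#'   `n_neighbors_at_removal` (NA for retained sequences), `removal_order`.
#' @export
hobohm2_reduce <- function(graph) {
  ids <- graph$ids
  adj <- graph$d < graph$threshold
  diag(adj) <- FALSE
  alive <- rep(TRUE, length(ids))
  removed_n <- rep(NA_integer_, length(ids))
  removed_ord <- rep(NA_integer_, length(ids))
  step <- 0L
  repeat {
    deg <- rowSums(adj[, alive, drop = FALSE]) * alive
    if (!any(deg > 0)) break
    worst <- which(deg == max(deg))
    # lexicographically greatest id among the most-connected vertices
    victim <- worst[order(ids[worst], decreasing = TRUE)[1]]
    step <- step + 1L
    removed_n[victim] <- as.integer(deg[victim])
    removed_ord[victim] <- step
    alive[victim] <- FALSE
  }
  keep <- which(alive)
  sub <- graph$d[keep, keep, drop = FALSE]
  stopifnot(all(sub[upper.tri(sub)] >= graph$threshold))
  tibble(
    id = ids,
    retained = alive,
    n_neighbors_at_removal = removed_n,
    removal_order = removed_ord
  )
}
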