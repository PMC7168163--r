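#' Pairwise distances from a multiple sequence alignment
#'
#' p-distance (fraction of differing residues over columns where neither
#' row is gapped) or its Poisson correction `-ln(1 - p)`.
#'
#' @param msa Tibble with columns `id`, `aligned` (>= 3 rows for a
#'   downstream tree).
#' @param model `"p_distance"` or `"poisson"`.
#' @return A symmetric numeric matrix with the peptide ids as dimnames.
#'   Errors if a pair shares no comparable (mutually ungapped) column.
#' @export
msa_distance_matrix <- function(msa, model = c("p_distance", "poisson")) {
  model <- match.arg(model)
  rows <- strsplit(msa$aligned, "")
  if (length(unique(lengths(rows))) != 1) {
    abort("alignment rows differ in length")
  }
  mat <- do.call(rbind, rows)
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(msa$id, msa$id))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- mat[i, ] != "-" & mat[j, ] != "-"
      if (!any(ok)) {
        abort(sprintf(
          "no comparable columns between '%s' and '%s'",
          msa$id[i], msa$id[j]
        ))
      }
      p <- mean(mat[i, ok] != mat[j, ok])
      d <- if (model == "poisson") {
        if (p >= 1) abort("saturated pair (p = 1) under the Poisson model")
        -log(1 - p)
      } else {
        p
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration with a deterministic tie-break
#' (among minimal-Q pairs, the pair whose sorted cluster ids are smallest is
#' joined first). Additive distance matrices are reconstructed exactly.
#' Negative branch lengths are clamped to 0 with a message. The result is
#' an unrooted `phylo` tree (ape).
#'
#' @param d Symmetric distance matrix with taxon ids as dimnames (>= 3
#'   taxa, finite entries).
#' @return An object of class `phylo`.
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  ids <- rownames(d)
  stopifnot(n >= 3, !is.null(ids), all(is.finite(d)))
  fmt <- function(x) format(x, digits = 12, scientific = FALSE, trim = TRUE)
  clamp <- function(x) {
    if (x < 0) {
      inform(sprintf("negative branch length %.4g clamped to 0", x))
      0
    } else {
      x
    }
  }
  newick <- ids # growing newick fragment per cluster
  key <- ids # tie-break key: smallest member id
  D <- d
  eps <- 1e-12
  while (nrow(D) > 3) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < eps & upper.tri(Q), arr.ind = TRUE)
    pair_keys <- t(apply(cand, 1, function(idx) {
      sort(c(key[idx[1]], key[idx[2]]))
    }))
    pick <- order(pair_keys[, 1], pair_keys[, 2])[1]
    i <- cand[pick, 1]
    j <- cand[pick, 2]
    vi <- clamp(0.5 * D[i, j] + (R[i] - R[j]) / (2 * (r - 2)))
    vj <- clamp(D[i, j] - (0.5 * D[i, j] + (R[i] - R[j]) / (2 * (r - 2))))
    rest <- setdiff(seq_len(r), c(i, j))
    d_new <- 0.5 * (D[i, rest] + D[j, rest] - D[i, j])
    nw_new <- paste0("(", newick[i], ":", fmt(vi), ",",
                     newick[j], ":", fmt(vj), ")")
    key_new <- min(key[i], key[j])
    D <- rbind(cbind(D[rest, rest, drop = FALSE], d_new),
               c(d_new, 0))
    newick <- c(newick[rest], nw_new)
    key <- c(key[rest], key_new)
  }
  va <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  vb <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  vc <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  txt <- paste0("(", newick[1], ":", fmt(va), ",", newick[2], ":", fmt(vb),
                ",", newick[3], ":", fmt(vc), ");")
  ape::read.tree(text = txt)
}
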