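# Independent oracles used by the test suite. These deliberately do NOT
# share code with the package implementation: alignments are scored by
# exhaustive enumeration of all gapped alignments, profile-HMM scores by
# enumeration of all state paths, and isoelectric points by a fine pH grid
# scan.

oracle_blosum <- local({
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

# Exhaustive optimal global alignment score with affine gaps (a gap of
# length L costs open + ext * L). Pure recursion over move sequences; no
# dynamic-programming state sharing.
oracle_global_score <- function(a, b, open = 11, ext = 1) {
  B <- oracle_blosum()
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca)
  m <- length(cb)
  rec <- function(i, j, prev) {
    if (i == n && j == m) return(0)
    best <- -Inf
    if (i < n && j < m) {
      best <- max(best, B[ca[i + 1], cb[j + 1]] + rec(i + 1, j + 1, "M"))
    }
    if (i < n) {
      cost <- if (prev == "U") ext else open + ext
      best <- max(best, -cost + rec(i + 1, j, "U"))
    }
    if (j < m) {
      cost <- if (prev == "L") ext else open + ext
      best <- max(best, -cost + rec(i, j + 1, "L"))
    }
    best
  }
  rec(0, 0, "none")
}

# Exhaustive local score: best global score over all substring pairs, or 0.
oracle_local_score <- function(a, b, open = 11, ext = 1) {
  best <- 0
  na <- nchar(a)
  nb <- nchar(b)
  for (i1 in seq_len(na)) {
    for (i2 in i1:na) {
      sa <- substr(a, i1, i2)
      for (j1 in seq_len(nb)) {
        for (j2 in j1:nb) {
          best <- max(best, oracle_global_score(sa, substr(b, j1, j2),
                                                open, ext))
        }
      }
    }
  }
  best
}

random_peptide <- function(len, alphabet = c(
                             "A", "R", "N", "D", "C", "Q", "E", "G", "H",
                             "I", "L", "K", "M", "F", "P", "S", "T", "W",
                             "Y", "V"
                           )) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Path-enumeration oracle for profile-HMM scoring, mirroring the model's
# semantics: emission odds are e/background for match states and 1 for
# insert states; transition probabilities are taken from the model.
# Returns c(forward = sum over paths, viterbi = max over paths) in odds
# (not bits). mode "global" enumerates begin-to-end paths; mode "local"
# enumerates fragment paths entering any match state with probability
# 2 / (M * (M + 1)) and exiting after any match state.
oracle_hmm_paths <- function(hmm, sequence, mode = "global") {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  M <- hmm$M
  eo <- function(k, i) {
    r <- chars[i]
    if (r %in% colnames(hmm$match_emissions)) {
      hmm$match_emissions[k, r] / hmm$background[[r]]
    } else {
      1
    }
  }
  tr <- function(state, k, to) {
    switch(state,
      m = hmm$from_m[k + 1, to],
      i = hmm$from_i[k + 1, to],
      d = hmm$from_d[k + 1, to]
    )
  }
  sum_paths <- 0
  max_path <- -Inf
  if (mode == "global") {
    rec <- function(k, state, i, p) {
      if (k == M) {
        done <- p * tr(state, M, "m")
        if (i == L) {
          sum_paths <<- sum_paths + done
          max_path <<- max(max_path, done)
        }
        # fall through: other moves below may still be available
      }
      if (k < M && i < L) {
        rec(k + 1, "m", i + 1, p * tr(state, k, "m") * eo(k + 1, i + 1))
      }
      if (i < L) {
        rec(k, "i", i + 1, p * tr(state, k, "i"))
      }
      if (k < M) {
        rec(k + 1, "d", i, p * tr(state, k, "d"))
      }
    }
    rec(0, "m", 0, 1)
  } else {
    entry <- 2 / (M * (M + 1))
    rec <- function(k, state, i, p) {
      if (state == "m") {
        sum_paths <<- sum_paths + p
        max_path <<- max(max_path, p)
      }
      if (k < M && i < L) {
        rec(k + 1, "m", i + 1, p * tr(state, k, "m") * eo(k + 1, i + 1))
      }
      if (i < L) {
        rec(k, "i", i + 1, p * tr(state, k, "i"))
      }
      if (k < M) {
        rec(k + 1, "d", i, p * tr(state, k, "d"))
      }
    }
    for (i0 in seq_len(L)) {
      for (k0 in seq_len(M)) {
        rec(k0, "m", i0, entry * eo(k0, i0))
      }
    }
  }
  c(forward = unname(sum_paths), viterbi = unname(max_path))
}

# Fine-grid scan oracle for the isoelectric point.
oracle_pi <- function(seq, step = 1e-4) {
  grid <- seq(0, 14, by = step)
  q <- mytikit:::charge_at_ph(seq, grid)
  grid[which.min(abs(q))]
}

# Empirical AUC by pairwise comparison (Mann-Whitney statistic).
empirical_auc <- function(pos, neg) {
  mean(outer(pos, neg, ">")) + 0.5 * mean(outer(pos, neg, "=="))
}

# Independent replay of the Hobohm-2 greedy policy on a distance matrix,
# used to validate hobohm2_reduce decisions.
oracle_hobohm2 <- function(d, ids, threshold) {
  adj <- d < threshold
  diag(adj) <- FALSE
  alive <- rep(TRUE, length(ids))
  repeat {
    deg <- rowSums(adj[, alive, drop = FALSE]) * alive
    if (!any(deg > 0)) break
    worst <- which(deg == max(deg))
    victim <- worst[order(ids[worst], decreasing = TRUE)[1]]
    alive[victim] <- FALSE
  }
  ids[alive]
}
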