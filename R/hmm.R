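# Background amino-acid frequencies (Robinson & Robinson 1991), the null
# model against which log-odds scores are computed. Documented constant so
# an alternative composition can be swapped in one place.
BG_ROBINSON <- c(
  A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
  Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
  L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
  S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441
)

#' Build a profile hidden Markov model from a multiple sequence alignment
#'
#' Match columns are the alignment columns with gap fraction below 0.5.
#' Match emission counts use Henikoff position-based weighting applied per
#' column (each residue occurrence in a column with `r` distinct types, of
#' a type shared by `s` rows, contributes `1/(r*s)`, so every column's
#' observed counts sum to one and duplicated rows change nothing), plus a
#' background-proportional pseudocount. Transitions use the per-sequence
#' Henikoff weights (column contributions summed per row, normalized to
#' mean one) on per-row state paths through the match/insert/delete
#' architecture, Laplace-smoothed. Scores are log-odds against a fixed
#' background composition, in bits.
#'
#' @param msa Tibble with columns `id`, `aligned` (equal-length rows), as
#'   produced by [progressive_msa()].
#' @param pseudocount Total emission pseudocount mass per match state,
#'   distributed proportionally to the background (default 1).
#' @param background Named length-20 frequency vector.
#' @return An object of class `profile_hmm`: list with `M` (number of match
#'   states), `match_emissions` (M x 20 probability rows), `insert_emissions`
#'   (background row), transition matrices `from_m`, `from_i`, `from_d`
#'   (rows = nodes 0..M, columns `m`/`i`/`d`; row k of `from_m` holds
#'   M_k -> {M_(k+1), I_k, D_(k+1)}, with node M's `m` transition leading to
#'   the end state), `background`, `match_cols`, `n_training`, and `calibration`
#'   (NULL until [calibrate_hmm()] is run).
#' @export
build_profile_hmm <- function(msa, pseudocount = 1, background = BG_ROBINSON) {
  rows <- strsplit(msa$aligned, "")
  L <- unique(lengths(rows))
  if (length(L) != 1) abort("alignment rows differ in length")
  mat <- do.call(rbind, rows)
  nseq <- nrow(mat)
  gap_frac <- colMeans(mat == "-")
  match_cols <- which(gap_frac < 0.5)
  M <- length(match_cols)
  if (M == 0) abort("alignment has no match columns (all gap fractions >= 0.5)")

  w <- henikoff_weights(mat)
  w <- w / sum(w) * nseq # mean weight 1 so Laplace smoothing is scale-stable

  aa <- names(background)
  emis <- matrix(0, M, 20, dimnames = list(NULL, aa))
  for (k in seq_len(M)) {
    col <- mat[, match_cols[k]]
    keep <- col %in% aa # gaps and X carry no emission count
    if (any(keep)) {
      tab <- table(col[keep])
      r <- length(tab)
      obs <- intersect(names(tab), aa)
      emis[k, obs] <- 1 / r # position-based: each observed type equally
    }
  }
  emis <- emis + pseudocount * matrix(background, M, 20, byrow = TRUE)
  emis <- emis / rowSums(emis)

  # Transition counts from per-row state paths. Node 0 is the begin state
  # (treated as M_0), node M's outgoing "m" transition is to the end state.
  cnt <- list(
    m = matrix(0, M + 1, 3, dimnames = list(NULL, c("m", "i", "d"))),
    i = matrix(0, M + 1, 3, dimnames = list(NULL, c("m", "i", "d"))),
    d = matrix(0, M + 1, 3, dimnames = list(NULL, c("m", "i", "d")))
  )
  is_match_col <- seq_len(ncol(mat)) %in% match_cols
  node_of_col <- cumsum(is_match_col)
  for (r in seq_len(nseq)) {
    state <- "m"
    node <- 0L
    for (j in seq_len(ncol(mat))) {
      res <- mat[r, j] != "-"
      if (is_match_col[j]) {
        new_state <- if (res) "m" else "d"
        cnt[[state]][node + 1L, new_state] <-
          cnt[[state]][node + 1L, new_state] + w[r]
        state <- new_state
        node <- node_of_col[j]
      } else if (res) {
        cnt[[state]][node + 1L, "i"] <- cnt[[state]][node + 1L, "i"] + w[r]
        state <- "i"
      }
    }
    cnt[[state]][node + 1L, "m"] <- cnt[[state]][node + 1L, "m"] + w[r] # to end
  }
  norm <- function(x) {
    x <- x + 1 # Laplace
    x[M + 1, "d"] <- 0 # no D_(M+1)
    x / rowSums(x)
  }
  structure(
    list(
      M = M,
      match_emissions = emis,
      insert_emissions = background,
      from_m = norm(cnt$m), from_i = norm(cnt$i), from_d = norm(cnt$d),
      background = background,
      match_cols = match_cols,
      n_training = nseq,
      calibration = NULL
    ),
    class = "profile_hmm"
  )
}

# Henikoff & Henikoff position-based sequence weights: in each column a
# residue type shared by s sequences among r distinct types contributes
# 1/(r*s) to each of those sequences; gap characters contribute nothing.
henikoff_weights <- function(mat) {
  nseq <- nrow(mat)
  w <- rep(0, nseq)
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    keep <- col != "-"
    if (!any(keep)) next
    tab <- table(col[keep])
    r <- length(tab)
    w[keep] <- w[keep] + 1 / (r * as.numeric(tab[col[keep]]))
  }
  if (all(w == 0)) w <- rep(1, nseq)
  w
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("<profile_hmm> ", x$M, " match states, trained on ", x$n_training,
      " sequences", sep = "")
  if (!is.null(x$calibration)) {
    cat(sprintf(
      "; Gumbel mu=%.2f lambda=%.3f (n_null=%d)",
      x$calibration[["mu"]], x$calibration[["lambda"]],
      as.integer(x$calibration[["n_null"]])
    ))
  }
  cat("\n")
  invisible(x)
}

#' @rdname build_profile_hmm
#' @param x A `profile_hmm`.
#' @param ... Unused.
#' @export
tidy.profile_hmm <- function(x, ...) {
  emis <- as.data.frame(x$match_emissions)
  emis$state <- seq_len(x$M)
  emis$alignment_column <- x$match_cols
  tidyr::pivot_longer(
    tibble::as_tibble(emis),
    cols = -c("state", "alignment_column"),
    names_to = "residue", values_to = "probability"
  )
}

#' @rdname build_profile_hmm
#' @export
glance.profile_hmm <- function(x, ...) {
  tibble(
    match_states = x$M,
    n_training = x$n_training,
    calibrated = !is.null(x$calibration),
    mu = if (is.null(x$calibration)) NA_real_ else x$calibration[["mu"]],
    lambda = if (is.null(x$calibration)) NA_real_ else x$calibration[["lambda"]]
  )
}

# Log2 emission odds for a sequence against each match state: L x M matrix.
# X (unknown) emits at background odds (0 bits) in every state.
match_logodds <- function(hmm, chars) {
  lo <- log2(sweep(hmm$match_emissions, 2, hmm$background, "/"))
  out <- matrix(0, length(chars), hmm$M)
  known <- chars %in% colnames(lo)
  out[known, ] <- lo[, chars[known], drop = FALSE] |> t()
  out
}

#' Score a peptide against a profile HMM
#'
#' Viterbi or Forward scoring in bits: log2-odds of the sequence under the
#' model against the background null. Insert states emit at background
#' frequencies, so only transitions and match emissions contribute. Forward
#' is always at least Viterbi (it sums over all state paths rather than
#' maximizing).
#'
#' Two alignment modes are provided. `"local"` (the default, mirroring how
#' profile searches are run in practice) scores the best model
#' fragment against the best sequence fragment: a path may enter at any
#' match state (uniform entry probability `2 / (M * (M + 1))`) and exit
#' after any match state, and unaligned sequence flanks emit at background
#' odds. `"global"` requires a begin-to-end path through the whole model.
#' Local scoring is robust to sub-family architecture differences (a
#' displaced cysteine does not force the whole alignment to pay for it);
#' global scoring is the stricter whole-precursor statistic.
#'
#' @param hmm A [build_profile_hmm()] model.
#' @param sequence Peptide sequence (character scalar).
#' @param algorithm `"viterbi"` or `"forward"`.
#' @param mode `"local"` or `"global"`.
#' @return Bit score (numeric scalar).
#' @export
hmm_score <- function(hmm, sequence, algorithm = c("viterbi", "forward"),
                      mode = c("local", "global")) {
  algorithm <- match.arg(algorithm)
  mode <- match.arg(mode)
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  M <- hmm$M
  lt <- lapply(list(m = hmm$from_m, i = hmm$from_i, d = hmm$from_d), log2)
  E <- match_logodds(hmm, chars)
  neg <- -Inf
  combine <- if (algorithm == "viterbi") {
    function(a, b, c) pmax(a, b, c)
  } else {
    function(a, b, c) {
      m <- pmax(a, b, c)
      ifelse(
        is.finite(m),
        m + log2(
          ifelse(is.finite(a), 2^(a - m), 0) +
            ifelse(is.finite(b), 2^(b - m), 0) +
            ifelse(is.finite(c), 2^(c - m), 0)
        ),
        neg
      )
    }
  }
  # Node-indexed vectors over k = 1..M; vm[k] = best/total log-odds ending
  # in M_k having emitted the current prefix. D-chains along k are resolved
  # with an explicit scan.
  tmm <- lt$m[, "m"]; tmi <- lt$m[, "i"]; tmd <- lt$m[, "d"]
  tim <- lt$i[, "m"]; tii <- lt$i[, "i"]; tid <- lt$i[, "d"]
  tdm <- lt$d[, "m"]; tdi <- lt$d[, "i"]; tdd <- lt$d[, "d"]
  d_chain <- function(vm_prev_nodes, vi_prev_nodes) {
    # entry into D_k from M_(k-1)/I_(k-1) at the same sequence position,
    # then D_(k-1) -> D_k propagation
    entry <- combine(
      vm_prev_nodes + tmd[seq_len(M)],
      vi_prev_nodes + tid[seq_len(M)],
      rep(neg, M)
    )
    vd <- rep(neg, M)
    vd[1] <- entry[1]
    for (k in seq_len(M - 1)) {
      vd[k + 1] <- combine(entry[k + 1], vd[k] + tdd[k + 1], neg)
    }
    vd
  }
  reduce_vec <- if (algorithm == "viterbi") {
    function(x) max(x)
  } else {
    function(x) {
      m <- max(x)
      if (!is.finite(m)) return(neg)
      m + log2(sum(2^(x - m)))
    }
  }
  entry <- if (mode == "local") log2(2 / (M * (M + 1))) else neg
  # position 0: only deletions possible (global mode)
  vm <- rep(neg, M + 1) # index k+1 = node k, node 0 = begin
  vi <- rep(neg, M + 1)
  if (mode == "global") vm[1] <- 0 # local paths enter only at match states
  vd <- d_chain(vm[seq_len(M)], vi[seq_len(M)])
  acc <- neg # local-mode accumulator over all exit points
  for (pos in seq_len(L)) {
    prev_m <- vm
    prev_i <- vi
    prev_d <- vd
    new_m <- rep(neg, M + 1)
    inner <- combine(
      prev_m[seq_len(M)] + tmm[seq_len(M)],
      prev_i[seq_len(M)] + tim[seq_len(M)],
      c(neg, prev_d[seq_len(M - 1)] + tdm[1 + seq_len(M - 1)])
    )
    if (mode == "local") {
      inner <- combine(inner, rep(entry, M), rep(neg, M))
    }
    new_m[1 + seq_len(M)] <- E[pos, ] + inner
    new_i <- combine(
      prev_m + tmi,
      prev_i + tii,
      c(neg, prev_d) + tdi
    )
    vm <- new_m
    vi <- new_i
    vd <- d_chain(vm[seq_len(M)], vi[seq_len(M)])
    if (mode == "local") {
      acc <- combine(acc, reduce_vec(vm[1 + seq_len(M)]), neg)
    }
  }
  if (mode == "local") {
    acc
  } else {
    combine(
      vm[M + 1] + tmm[M + 1],
      vi[M + 1] + tim[M + 1],
      vd[M] + tdm[M + 1]
    )
  }
}

#' Calibrate a profile HMM against a null score distribution
#'
#' Fits a Gumbel (type-I extreme value) distribution by moment matching to
#' the Viterbi scores of `n_null` random sequences drawn from the model's
#' background composition, with lengths resampled from the training-row
#' lengths. E-values are then
#' `E(s) = n_db * (1 - exp(-exp(-lambda * (s - mu))))`.
#'
#' @param hmm A `profile_hmm`.
#' @param training_lengths Integer vector of training sequence lengths to
#'   resample null lengths from.
#' @param n_null Number of null sequences (default 1000).
#' @param seed Integer seed; calibration is deterministic given the seed.
#' @return The model with `calibration = c(mu, lambda, n_null)` filled in.
#' @export
calibrate_hmm <- function(hmm, training_lengths, n_null = 1000, seed = 1) {
  stopifnot(length(training_lengths) >= 1, all(training_lengths >= 1))
  aa <- names(hmm$background)
  scores <- withr::with_seed(seed, {
    lens <- sample(training_lengths, n_null, replace = TRUE)
    vapply(lens, function(len) {
      s <- paste(sample(aa, len, replace = TRUE, prob = hmm$background),
                 collapse = "")
      hmm_score(hmm, s, "viterbi")
    }, numeric(1))
  })
  s <- sd(scores)
  if (!is.finite(s) || s < 1e-9) abort("degenerate null score variance")
  lambda <- pi / (s * sqrt(6))
  mu <- mean(scores) - 0.5772156649 / lambda
  hmm$calibration <- c(mu = mu, lambda = lambda, n_null = n_null)
  hmm
}

#' E-value of a bit score under a calibrated model
#'
#' @param hmm A calibrated `profile_hmm`.
#' @param score Numeric vector of bit scores.
#' @param n_db Database size (number of sequences scanned).
#' @return Numeric vector of E-values (>= 0, monotone decreasing in score).
#' @export
hmm_evalue <- function(hmm, score, n_db) {
  if (is.null(hmm$calibration)) abort("model is not calibrated")
  mu <- hmm$calibration[["mu"]]
  lambda <- hmm$calibration[["lambda"]]
  # -expm1(-t) = 1 - exp(-t) without catastrophic cancellation for tiny t,
  # keeping E-values strictly monotone far into the significant tail
  n_db * (-expm1(-exp(-lambda * (score - mu))))
}

#' Paired two-model screening (mytilin vs myticin discrimination)
#'
#' Scores every peptide against two calibrated profile HMMs and labels it by
#' the model with the lower E-value among those below the threshold, or
#' `"none"` if neither passes. Screening a mytilin model alone can pick up
#' structurally related CS-alpha-beta peptides near the significance
#' threshold; pairing it with a second family-specific model restores
#' discrimination.
#'
#' @param peptides Tibble with columns `id`, `residues`.
#' @param hmm_a,hmm_b Calibrated models; `labels` names them.
#' @param e_threshold Significance threshold on E-values (default 0.05).
#' @param labels Character vector of length 2 naming the two models.
#' @param n_db Database size used for E-values (defaults to `nrow(peptides)`).
#' @return A tibble: `peptide_id`, `score_a`, `score_b`, `evalue_a`,
#'   `evalue_b`, `best_model` (one of the two labels or `"none"`).
#' @export
dual_screen <- function(peptides, hmm_a, hmm_b, e_threshold = 0.05,
                        labels = c("mytilin", "myticin"),
                        n_db = nrow(peptides)) {
  if (!nrow(peptides)) {
    return(tibble(
      peptide_id = character(0), score_a = numeric(0), score_b = numeric(0),
      evalue_a = numeric(0), evalue_b = numeric(0), best_model = character(0)
    ))
  }
  sa <- vapply(peptides$residues, function(s) hmm_score(hmm_a, s, "viterbi"),
               numeric(1), USE.NAMES = FALSE)
  sb <- vapply(peptides$residues, function(s) hmm_score(hmm_b, s, "viterbi"),
               numeric(1), USE.NAMES = FALSE)
  ea <- hmm_evalue(hmm_a, sa, n_db)
  eb <- hmm_evalue(hmm_b, sb, n_db)
  best <- dplyr::case_when(
    ea < e_threshold & (ea <= eb | eb >= e_threshold) ~ labels[1],
    eb < e_threshold ~ labels[2],
    .default = "none"
  )
  tibble(
    peptide_id = peptides$id,
    score_a = sa, score_b = sb,
    evalue_a = ea, evalue_b = eb,
    best_model = best
  )
}

#' Serialize a profile HMM to plain text
#'
#' Writes a simple documented format: a header with the model length,
#' alphabet, training size and calibration, then per-node emission and
#' transition lines. [read_hmm()] restores the model exactly (values are
#' printed at full precision).
#'
#' @param hmm A `profile_hmm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hmm <- function(hmm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) format(x, digits = 17, scientific = TRUE)
  cat("MYTIKIT-HMM 1\n", file = con)
  cat("M", hmm$M, "\n", file = con)
  cat("ALPHABET", paste(names(hmm$background), collapse = " "), "\n",
      file = con)
  cat("NSEQ", hmm$n_training, "\n", file = con)
  cat("MATCHCOLS", paste(hmm$match_cols, collapse = " "), "\n", file = con)
  if (!is.null(hmm$calibration)) {
    cat("CALIBRATION", num(hmm$calibration[["mu"]]),
        num(hmm$calibration[["lambda"]]),
        as.integer(hmm$calibration[["n_null"]]), "\n", file = con)
  }
  cat("BACKGROUND", paste(num(hmm$background), collapse = " "), "\n",
      file = con)
  for (k in seq_len(hmm$M)) {
    cat("EMIT", k, paste(num(hmm$match_emissions[k, ]), collapse = " "),
        "\n", file = con)
  }
  for (k in 0:hmm$M) {
    cat("TRANS", k,
        paste(num(c(hmm$from_m[k + 1, ], hmm$from_i[k + 1, ],
                    hmm$from_d[k + 1, ])), collapse = " "),
        "\n", file = con)
  }
  invisible(path)
}

#' @rdname write_hmm
#' @export
read_hmm <- function(path) {
  lines <- readLines(path)
  if (!identical(lines[1], "MYTIKIT-HMM 1")) abort("not a mytikit HMM file")
  fields <- strsplit(lines, "\\s+")
  get1 <- function(key) fields[[which(vapply(fields, `[`, character(1), 1) == key)[1]]][-1]
  M <- as.integer(get1("M"))
  aa <- get1("ALPHABET")
  bg <- setNames(as.numeric(get1("BACKGROUND")), aa)
  emis <- matrix(0, M, length(aa), dimnames = list(NULL, aa))
  from_m <- from_i <- from_d <-
    matrix(0, M + 1, 3, dimnames = list(NULL, c("m", "i", "d")))
  for (f in fields) {
    if (f[1] == "EMIT") {
      emis[as.integer(f[2]), ] <- as.numeric(f[-(1:2)])
    } else if (f[1] == "TRANS") {
      k <- as.integer(f[2]) + 1L
      v <- as.numeric(f[-(1:2)])
      from_m[k, ] <- v[1:3]
      from_i[k, ] <- v[4:6]
      from_d[k, ] <- v[7:9]
    }
  }
  calib <- NULL
  has_cal <- vapply(fields, `[`, character(1), 1) == "CALIBRATION"
  if (any(has_cal)) {
    v <- as.numeric(fields[[which(has_cal)[1]]][-1])
    calib <- c(mu = v[1], lambda = v[2], n_null = v[3])
  }
  structure(
    list(
      M = M, match_emissions = emis, insert_emissions = bg,
      from_m = from_m, from_i = from_i, from_d = from_d,
      background = bg, match_cols = as.integer(get1("MATCHCOLS")),
      n_training = as.integer(get1("NSEQ")), calibration = calib
    ),
    class = "profile_hmm"
  )
}
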