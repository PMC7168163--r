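test_that("model building matches hand-computed counts on a toy alignment", {
  msa <- tibble::tibble(id = c("a", "b"), aligned = c("AC", "AD"))
  h <- build_profile_hmm(msa)
  expect_equal(h$M, 2L)

  bg <- mytikit:::BG_ROBINSON
  # column 1: a single observed type (A) carries the whole unit count;
  # plus the background pseudocount of total mass one
  expect_equal(unname(h$match_emissions[1, "A"]), (1 + bg[["A"]]) / 2)
  # column 2: two observed types (C, D) split the unit count equally
  expect_equal(unname(h$match_emissions[2, "C"]), (0.5 + bg[["C"]]) / 2)
  expect_equal(unname(h$match_emissions[2, "D"]), (0.5 + bg[["D"]]) / 2)

  # both rows walk B->M1->M2->E: counts 2 everywhere on the M->M chain,
  # Laplace-smoothed over {m,i,d} ({m,i} at the last node)
  expect_equal(unname(h$from_m[1, ]), c(3, 1, 1) / 5)
  expect_equal(unname(h$from_m[2, ]), c(3, 1, 1) / 5)
  expect_equal(unname(h$from_m[3, ]), c(3, 1, 0) / 4)
})

test_that("model probabilities normalize and degenerate cases work", {
  msa1 <- tibble::tibble(id = "only", aligned = "SCKYR")
  h1 <- build_profile_hmm(msa1)
  expect_equal(h1$M, 5L)
  for (k in 1:5) {
    res <- substr("SCKYR", k, k)
    expect_equal(unname(which.max(h1$match_emissions[k, ])),
                 which(colnames(h1$match_emissions) == res))
  }

  co <- synth_cohort(synth_config(seed = 89, n_mytilins = 8, n_decoys = 0,
                                  n_transcripts = 8))
  h <- build_profile_hmm(progressive_msa(co$matures))
  expect_true(all(abs(rowSums(h$match_emissions) - 1) < 1e-9))
  expect_true(all(abs(rowSums(h$from_m) - 1) < 1e-9))
  expect_true(all(abs(rowSums(h$from_i) - 1) < 1e-9))
  expect_true(all(abs(rowSums(h$from_d[-1, ]) - 1) < 1e-9))

  expect_error(build_profile_hmm(tibble::tibble(id = c("a", "b"),
                                                aligned = c("-", "-"))),
               "match columns")
})

test_that("duplicating a row leaves Henikoff-weighted emissions unchanged", {
  msa <- tibble::tibble(id = c("a", "b"), aligned = c("ACDY", "AQDW"))
  msa_dup <- dplyr::bind_rows(msa, tibble::tibble(id = "b2",
                                                  aligned = "AQDW"))
  h1 <- build_profile_hmm(msa)
  h2 <- build_profile_hmm(msa_dup)
  expect_equal(h2$match_emissions, h1$match_emissions, tolerance = 1e-12)
})

test_that("forward and viterbi equal the path-enumeration oracle", {
  withr::local_seed(97)
  msas <- list(
    tibble::tibble(id = c("a", "b"), aligned = c("AC", "AD")),
    tibble::tibble(id = c("a", "b", "c"), aligned = c("KCY", "K-Y", "RCY")),
    tibble::tibble(id = c("a", "b"), aligned = c("WC", "WC"))
  )
  for (msa in msas) {
    h <- build_profile_hmm(msa)
    for (len in 1:4) {
      s <- random_peptide(len)
      for (mode in c("global", "local")) {
        oracle <- oracle_hmm_paths(h, s, mode = mode)
        expect_equal(hmm_score(h, s, "forward", mode = mode),
                     log2(oracle[["forward"]]), tolerance = 1e-8,
                     label = paste(mode, "forward", s))
        expect_equal(hmm_score(h, s, "viterbi", mode = mode),
                     log2(oracle[["viterbi"]]), tolerance = 1e-8,
                     label = paste(mode, "viterbi", s))
      }
    }
  }
})

test_that("forward dominates viterbi and training beats shuffling", {
  withr::local_seed(101)
  co <- synth_cohort(synth_config(seed = 101, n_mytilins = 10, n_decoys = 0,
                                  n_transcripts = 10))
  h <- build_profile_hmm(progressive_msa(co$matures))
  for (rep in 1:20) {
    s <- random_peptide(sample(5:40, 1))
    for (mode in c("global", "local")) {
      expect_gte(hmm_score(h, s, "forward", mode = mode) + 1e-9,
                 hmm_score(h, s, "viterbi", mode = mode))
    }
  }
  train <- co$matures$residues[1]
  shuf <- paste(sample(strsplit(train, "")[[1]]), collapse = "")
  expect_gt(hmm_score(h, train), hmm_score(h, shuf))
})

test_that("calibration is deterministic and E-values behave", {
  co <- synth_cohort(synth_config(seed = 103, n_mytilins = 10, n_decoys = 0,
                                  n_transcripts = 10))
  h <- build_profile_hmm(progressive_msa(co$matures))
  lens <- nchar(co$matures$residues)
  h1 <- calibrate_hmm(h, lens, n_null = 200, seed = 9)
  h2 <- calibrate_hmm(h, lens, n_null = 200, seed = 9)
  expect_identical(h1$calibration, h2$calibration)

  # monotone decreasing in score; saturates at n_db for hopeless scores
  sc <- seq(-20, 60, by = 5)
  ev <- hmm_evalue(h1, sc, n_db = 100)
  expect_true(all(diff(ev) <= 0))
  expect_true(all(diff(ev[ev < 100]) < 0)) # strict below saturation
  expect_true(all(ev >= 0 & ev <= 100))

  # the median null score should sit near E = n_db / 2
  null_scores <- withr::with_seed(9, {
    ls <- sample(lens, 200, replace = TRUE)
    vapply(ls, function(l) {
      s <- paste(sample(names(h$background), l, replace = TRUE,
                        prob = h$background), collapse = "")
      hmm_score(h, s, "viterbi")
    }, numeric(1))
  })
  ev_med <- hmm_evalue(h1, stats::median(null_scores), n_db = 100)
  expect_lt(abs(ev_med - 50) / 50, 0.1)

  expect_error(hmm_evalue(h, 10, 100), "not calibrated")
})

test_that("the paired screen discriminates mytilins from myticin decoys", {
  co <- synth_cohort(synth_config(seed = 107))
  train_idx <- seq(1, 60, by = 2)
  held_out <- co$matures[seq(2, 60, by = 2), ]
  myticins <- dplyr::filter(co$decoys, kind == "myticin_like")

  h_myt <- build_profile_hmm(progressive_msa(co$matures[train_idx, ]))
  h_mtc <- build_profile_hmm(progressive_msa(myticins))
  h_myt <- calibrate_hmm(h_myt, nchar(co$matures$residues[train_idx]),
                         n_null = 300, seed = 107)
  h_mtc <- calibrate_hmm(h_mtc, nchar(myticins$residues),
                         n_null = 300, seed = 107)

  hits <- dual_screen(held_out, h_myt, h_mtc)
  expect_true(all(hits$best_model == "mytilin"))

  dec <- dual_screen(dplyr::select(myticins, id, residues), h_myt, h_mtc)
  expect_false(any(dec$best_model == "mytilin"))

  empty <- dual_screen(held_out[0, ], h_myt, h_mtc)
  expect_equal(nrow(empty), 0L)
})

test_that("models serialize to text and back without score drift", {
  co <- synth_cohort(synth_config(seed = 109, n_mytilins = 6, n_decoys = 0,
                                  n_transcripts = 6))
  h <- build_profile_hmm(progressive_msa(co$matures))
  h <- calibrate_hmm(h, nchar(co$matures$residues), n_null = 100, seed = 2)
  tmp <- withr::local_tempfile(fileext = ".hmm")
  write_hmm(h, tmp)
  h2 <- read_hmm(tmp)
  s <- co$matures$residues[1]
  expect_equal(hmm_score(h2, s), hmm_score(h, s), tolerance = 1e-12)
  expect_equal(h2$calibration[["mu"]], h$calibration[["mu"]])
  expect_equal(glance(h2)$match_states, h$M)
})
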