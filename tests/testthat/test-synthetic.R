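test_that("the generator is byte-deterministic under a seed", {
  cfg <- synth_config(seed = 61, n_mytilins = 8, n_decoys = 6,
                      n_transcripts = 10)
  a <- synth_cohort(cfg)
  b <- synth_cohort(cfg)
  expect_identical(a, b)
  tmp1 <- withr::local_tempfile(fileext = ".faa")
  tmp2 <- withr::local_tempfile(fileext = ".faa")
  write_fasta(a$precursors, tmp1)
  write_fasta(b$precursors, tmp2)
  expect_identical(readLines(tmp1), readLines(tmp2))
})

test_that("generated matures satisfy their requested cysteine array exactly", {
  withr::local_seed(67)
  canonical_regex <-
    "C.{3}C.{3}C.{4}C.{11}C.C.C.{2}C"
  m_can <- make_precursor("c", "canonical", mature_length = 34L)
  mature <- substring(m_can$residues, m_can$mature_start, m_can$mature_end)
  expect_true(grepl(canonical_regex, mature))

  m_ccc <- make_precursor("x", "ccc", mature_length = 34L)
  mat_ccc <- substring(m_ccc$residues, m_ccc$mature_start, m_ccc$mature_end)
  expect_equal(stringr::str_count(mat_ccc, "C"), 9)
  expect_equal(length(gregexpr("CCC", mat_ccc)[[1]]), 1L)

  co <- synth_cohort(synth_config(seed = 67, n_mytilins = 30, n_decoys = 0,
                                  n_transcripts = 30))
  arr <- detect_cysteine_arrays(co$matures)
  kind <- co$precursors$array_kind
  expect_true(all(arr$array_class[kind == "canonical"] == "canonical"))
  expect_true(all(arr$array_class[kind == "ccc"] == "canonical"))
  expect_true(all(arr$has_ccc[kind == "ccc"]))
  expect_true(all(arr$array_class[kind == "alternative"] == "alternative"))
  expect_true(all(
    grepl(canonical_regex,
          co$matures$residues[kind == "canonical"])
  ))
})

test_that("net charges hit their targets by construction", {
  withr::local_seed(71)
  p <- make_precursor("p", "canonical", mature_charge = 9L,
                      ctail_charge = -7L)
  expect_equal(net_charge(substring(p$residues, p$mature_start,
                                    p$mature_end)), 9L)
  expect_equal(net_charge(substring(p$residues, p$ctail_start,
                                    p$ctail_end)), -7L)
  expect_error(make_precursor("bad", "canonical", mature_length = 33L,
                              mature_charge = 30L),
               "infeasible")
})

test_that("the cohort shows the mature/C-tail charge separation", {
  co <- synth_cohort(synth_config(seed = 73))
  ct <- extract_segment(
    dplyr::select(co$precursors, id, residues),
    dplyr::rename(co$precursors, peptide_id = id),
    "ctail"
  )
  expect_gt(mean(net_charge(co$matures$residues)), 0)
  expect_lt(mean(net_charge(ct$residues)), 0)
})

test_that("decoys are composition-preserving or array-distinct", {
  withr::local_seed(79)
  src <- "SCASRCKYRCRARRCRYYVSVRYGWFCYCRCLHC"
  sh <- make_decoy("d", "shuffled", source = src)
  expect_equal(sort(strsplit(sh$residues, "")[[1]]),
               sort(strsplit(src, "")[[1]]))
  expect_false(identical(sh$residues, src))

  canonical_regex <- "C.{3}C.{3}C.{4}C.{11}C.C.C.{2}C"
  for (k in c("myticin_like", "defensin_like")) {
    for (rep in 1:5) {
      d <- make_decoy(paste0(k, rep), k)
      expect_false(grepl(canonical_regex, d$residues))
      arr <- detect_cysteine_arrays(d)
      expect_equal(arr$array_class, "noncanonical")
    }
  }
})

test_that("transcripts embed back-translated ORFs recoverable from truth", {
  cfg <- synth_config(seed = 83, n_mytilins = 3, n_decoys = 0,
                      n_transcripts = 10)
  co <- synth_cohort(cfg)
  expect_equal(nrow(co$truth), 3L)
  expect_equal(nrow(co$transcripts), 10L)
  for (i in seq_len(nrow(co$truth))) {
    tr <- co$truth[i, ]
    nt <- co$transcripts$nucleotides[co$transcripts$id == tr$transcript_id]
    orf <- substr(nt, tr$orf_start, tr$orf_end)
    if (tr$strand == "-") orf <- mytikit:::revcomp(orf)
    aa <- mytikit:::translate_nt(orf)
    expect_equal(sub("\\*$", "", aa),
                 co$precursors$residues[co$precursors$id == tr$peptide_id])
  }
  expect_true(any(co$truth$strand == "-"))
  expect_true(all(co$truth$frame[co$truth$strand == "-"] < 0))
})
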