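test_that("signal-peptide prediction recovers synthetic cleavage sites", {
  co <- synth_cohort(synth_config(seed = 19, n_mytilins = 20, n_decoys = 0,
                                  n_transcripts = 20))
  calls <- predict_signal_cleavage(co$precursors$residues)
  expect_true(all(abs(calls - co$precursors$sp_end) <= 2))
})

test_that("signal-peptide prediction rejects sequences without a core", {
  expect_error(predict_signal_cleavage(strrep("K", 30)))
  expect_error(predict_signal_cleavage(strrep("K", 45)),
               "no plausible signal peptide")
})

test_that("shifting the hydrophobic core shifts the call accordingly", {
  withr::local_seed(43)
  p18 <- make_precursor("p18", "canonical", sp_length = 18L)
  p21 <- make_precursor("p21", "canonical", sp_length = 21L)
  expect_equal(predict_signal_cleavage(p18$residues), 18L)
  expect_equal(predict_signal_cleavage(p21$residues), 21L)
})

test_that("alignment segmentation maps reference boundaries", {
  withr::local_seed(47)
  ref <- make_precursor("ref", "canonical")
  ann <- list(sp_end = ref$sp_end, mature_end = ref$mature_end)

  # a precursor aligned to itself reproduces the reference annotation
  seg <- segment_by_alignment(ref$residues, ref$residues, ann)
  expect_equal(seg$sp_end, ref$sp_end)
  expect_equal(seg$mature_end, ref$mature_end)
  expect_equal(seg$ctail_start, ref$ctail_start)

  # synthetic cohort: exact boundary recovery against a family reference
  co <- synth_cohort(synth_config(seed = 47, n_mytilins = 12, n_decoys = 0,
                                  n_transcripts = 12))
  fam <- co$precursors[co$precursors$family == "mytilus", ]
  refp <- fam[1, ]
  out <- annotate_precursors(
    dplyr::select(fam, id, residues)[-1, ], refp$residues,
    list(sp_end = refp$sp_end, mature_end = refp$mature_end),
    sp_method = "heuristic"
  )
  truth <- fam[-1, ]
  expect_true(all(abs(out$sp_end - truth$sp_end) <= 1))
  expect_true(all(abs(out$mature_end - truth$mature_end) <= 1))

  # distant reference is refused
  expect_error(
    segment_by_alignment(strrep("GN", 30), ref$residues, ann),
    "reference too distant"
  )
})

test_that("boundaries in reference-gap columns snap towards the mature region", {
  # reference: 10-aa "signal" + 6-aa mature; query carries an insertion at
  # the boundary so the reference has a gap column there
  ref <- "MLLLLLLVNAWCDKYC"
  ann <- list(sp_end = 10L, mature_end = 16L)
  query <- "MLLLLLLVNAQQWCDKYC" # 2-residue insertion after the SP
  seg <- segment_by_alignment(query, ref, ann)
  # the mapped mature must still start at/inside the homologous mature
  expect_equal(substring(query, seg$mature_start, seg$mature_end), "WCDKYC")
})

test_that("segmentation is idempotent", {
  withr::local_seed(53)
  ref <- make_precursor("ref", "canonical")
  ann <- list(sp_end = ref$sp_end, mature_end = ref$mature_end)
  # a family relative of the reference (15% substitution at fillers)
  chars <- strsplit(ref$residues, "")[[1]]
  free <- which(chars != "C" & chars != "M")
  hit <- sample(free, length(free) %/% 7)
  chars[hit] <- sample(c("S", "G", "Q", "N", "T", "Y"), length(hit),
                       replace = TRUE)
  q <- tibble::tibble(residues = paste(chars, collapse = ""))
  s1 <- segment_by_alignment(q$residues, ref$residues, ann)
  s2 <- segment_by_alignment(
    q$residues, q$residues,
    list(sp_end = s1$sp_end, mature_end = s1$mature_end)
  )
  expect_equal(s2$sp_end, s1$sp_end)
  expect_equal(s2$mature_end, s1$mature_end)
})

test_that("segment extraction returns the annotated sub-sequences", {
  withr::local_seed(59)
  p <- make_precursor("p", "canonical")
  ann <- tibble::tibble(
    peptide_id = "p", sp_end = p$sp_end, mature_start = p$mature_start,
    mature_end = p$mature_end, ctail_start = p$ctail_start,
    ctail_end = p$ctail_end
  )
  peps <- tibble::tibble(id = "p", residues = p$residues)
  expect_equal(nchar(extract_segment(peps, ann, "sp")$residues), p$sp_end)
  mat <- extract_segment(peps, ann, "mature")$residues
  expect_equal(nchar(mat), p$mature_end - p$mature_start + 1L)
  expect_equal(net_charge(extract_segment(peps, ann, "ctail")$residues), -6L)
})
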