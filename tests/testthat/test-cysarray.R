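t1_peptides <- function() {
  t1 <- mytilin_matures()
  tibble::tibble(id = t1$name, residues = t1$residues)
}

test_that("array detection classifies the reference matures correctly", {
  arr <- detect_cysteine_arrays(t1_peptides())

  mcal1 <- arr[arr$peptide_id == "Mcal mytilin 1", ]
  expect_equal(mcal1$array_class, "canonical")
  expect_equal(mcal1$n_cys, 8L)
  expect_false(mcal1$has_ccc)

  mgal_l <- arr[arr$peptide_id == "Mgal mytilin L", ]
  expect_equal(mgal_l$array_class, "alternative")
  expect_equal(mgal_l$c1_c2_loop_len, 7L)

  pcan1 <- arr[arr$peptide_id == "Pcan mytilin 1", ]
  expect_true(pcan1$has_ccc)
  expect_equal(pcan1$n_cys, 9L)

  # the one P. viridis mature lacking C8 is flagged, not an error
  pvir1 <- arr[arr$peptide_id == "Pvir mytilin 1", ]
  expect_equal(pvir1$array_class, "noncanonical")
  expect_true(pvir1$missing_c8)
})

test_that("every 8-cysteine Mytilus/Trichomya mature classifies canonical", {
  t1 <- mytilin_matures()
  keep <- grepl("^(Mcal|Mcor|Thir)", t1$name) & !grepl("PM", t1$name)
  arr <- detect_cysteine_arrays(
    tibble::tibble(id = t1$name[keep], residues = t1$residues[keep])
  )
  expect_true(all(arr$array_class == "canonical"))
})

test_that("CCC census matches the reference counts", {
  t1 <- mytilin_matures()
  perna <- dplyr::filter(t1, grepl("^P", name))
  expect_equal(nrow(perna), 15L)
  expect_equal(count_ccc(perna), 13L)
  expect_equal(count_ccc(perna[0, ]), 0L)

  co <- synth_cohort(synth_config(seed = 4, n_mytilins = 10, n_decoys = 0,
                                  n_transcripts = 10))
  canon <- co$matures[co$precursors$array_kind == "canonical", ]
  expect_equal(count_ccc(canon), 0L)
})

test_that("disulfide assignment pairs C1-C5/C2-C6/C3-C7/C4-C8", {
  arr <- detect_cysteine_arrays(t1_peptides())
  ok <- arr[arr$array_class != "noncanonical", ]
  bonds <- assign_disulfides(ok)

  # canonical 8-cysteine case: four bonds, nothing unpaired
  m1 <- bonds[bonds$peptide_id == "Mcal mytilin 1", ]
  expect_equal(nrow(m1), 4L)
  expect_equal(m1$bond, c("C1-C5", "C2-C6", "C3-C7", "C4-C8"))
  expect_equal(unlist(ok$unpaired[ok$peptide_id == "Mcal mytilin 1"]),
               integer(0))

  # CCC case: the middle cysteine of the triad stays unpaired
  p1 <- ok[ok$peptide_id == "Pcan mytilin 1", ]
  expect_equal(length(unlist(p1$unpaired)), 1L)
  mid <- unlist(p1$cys_positions)[unlist(p1$unpaired)]
  expect_equal(substr(t1_peptides()$residues[13], mid - 1, mid + 1), "CCC")

  # perfect matching: within each pairing every structural index once
  for (pid in unique(bonds$peptide_id)) {
    sub <- bonds[bonds$peptide_id == pid, ]
    for (v in unique(sub$pairing)) {
      idx <- c(sub$cys_from[sub$pairing == v], sub$cys_to[sub$pairing == v])
      expect_equal(length(idx), length(unique(idx)))
      expect_equal(length(idx), 8L)
    }
  }

  expect_error(
    assign_disulfides(detect_cysteine_arrays(
      tibble::tibble(id = "bad", residues = "AAAA")
    )),
    "topology undefined"
  )
})

test_that("nine-cysteine non-CCC arrays report two C5 pairings", {
  # mytilin-K-like synthetic: alternative skeleton with a second plausible
  # C5 inside the C4..C6 span
  seq <- "SCAKCSSRCYNKGCRYCAYCSTRLRKSYCKCFVC"
  arr <- detect_cysteine_arrays(tibble::tibble(id = "k_like", residues = seq))
  expect_equal(arr$array_class, "alternative")
  expect_equal(arr$n_cys, 9L)
  expect_false(arr$has_ccc)
  expect_equal(length(unlist(arr$c5_candidates)), 2L)
  bonds <- assign_disulfides(arr)
  expect_equal(sort(unique(bonds$pairing)), c(1L, 2L))
  expect_equal(sum(bonds$bond == "C1-C5"), 2L)
})

test_that("classification is invariant to spacing-preserving substitutions", {
  withr::local_seed(31)
  arr0 <- detect_cysteine_arrays(t1_peptides())
  for (rep in 1:5) {
    mutated <- vapply(t1_peptides()$residues, function(s) {
      chars <- strsplit(s, "")[[1]]
      free <- which(chars != "C")
      hit <- sample(free, max(1, length(free) %/% 4))
      chars[hit] <- sample(setdiff(LETTERS[LETTERS %in% c(
        "A", "R", "N", "D", "Q", "E", "G", "H", "I", "L", "K", "M", "F",
        "P", "S", "T", "W", "Y", "V"
      )], "C"), length(hit), replace = TRUE)
      paste(chars, collapse = "")
    }, character(1), USE.NAMES = FALSE)
    arr1 <- detect_cysteine_arrays(
      tibble::tibble(id = arr0$peptide_id, residues = mutated)
    )
    expect_equal(arr1$array_class, arr0$array_class)
    expect_equal(arr1$has_ccc, arr0$has_ccc)
  }
})
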