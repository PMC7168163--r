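test_that("six-frame ORF enumeration recovers embedded precursors", {
  co <- synth_cohort(synth_config(seed = 113, n_mytilins = 6, n_decoys = 0,
                                  n_transcripts = 8))
  orfs <- purrr::map_dfr(seq_len(nrow(co$transcripts)), function(i) {
    six_frame_orfs(co$transcripts[i, ])
  })
  hit <- dplyr::inner_join(
    co$truth, orfs,
    by = c("transcript_id", "frame", "orf_start", "orf_end")
  )
  expect_equal(nrow(hit), nrow(co$truth))
  prec <- co$precursors$residues[match(hit$peptide_id, co$precursors$id)]
  expect_equal(hit$protein, prec)
  # reverse-strand embeddings carry negative frames
  expect_true(all(hit$frame[hit$strand == "-"] < 0))
})

test_that("degenerate transcripts yield no ORFs", {
  allN <- tibble::tibble(id = "n", nucleotides = strrep("N", 400))
  expect_equal(nrow(six_frame_orfs(allN)), 0L)
  short <- tibble::tibble(id = "s", nucleotides = "ATGTAA")
  expect_equal(nrow(six_frame_orfs(short)), 0L)
})

test_that("the e-value estimate is monotone in score and lengths", {
  sc <- seq(0, 200, by = 10)
  ev <- evalue_like(sc, m = 34, n = 2000)
  expect_true(all(diff(ev) < 0))
  expect_gt(evalue_like(50, 100, 2000), evalue_like(50, 34, 2000))
})

test_that("the iterative screen needs iteration to reach remote homologs", {
  corp <- synth_chained_corpus(seed = 1)
  hits <- iterative_screen(corp$seeds, corp$transcripts)
  joined <- dplyr::left_join(
    hits, corp$truth,
    by = c("transcript_id", "frame", "orf_start", "orf_end")
  )
  mytilins <- corp$truth$peptide_id[corp$truth$tier != "decoy"]
  expect_setequal(joined$peptide_id, mytilins) # recall and precision 100%
  expect_equal(max(hits$iteration_found), 2L)
  # remote homologs only enter at the second pass, via close-homolog seeds
  remote <- joined[grepl("^remote", joined$peptide_id), ]
  expect_true(all(remote$iteration_found == 2L))
  # remotes were reached through accepted hits, never the original seed
  expect_true(all(remote$best_seed_id != corp$seeds$id))

  single <- suppressWarnings(
    iterative_screen(corp$seeds, corp$transcripts, max_iter = 1)
  )
  expect_lt(nrow(single), length(mytilins))
  expect_equal(nrow(single), 5L)
})

test_that("the screen terminates empty on corpora without mytilins", {
  withr::local_seed(127)
  seeds <- make_precursor("seed", "canonical")
  empty_tx <- make_transcripts(seeds[0, ], n_transcripts = 4,
                               utr_length = 40)$transcripts
  hits <- iterative_screen(seeds, empty_tx)
  expect_equal(nrow(hits), 0L)

  # decoy-only corpus: ORFs align to nothing or fail the array gate
  decoys <- dplyr::bind_rows(
    make_decoy_precursor("d1", "myticin_like"),
    make_decoy_precursor("d2", "defensin_like")
  )
  tx <- make_transcripts(decoys, n_transcripts = 4, utr_length = 40)
  hits2 <- iterative_screen(seeds, tx$transcripts)
  expect_equal(nrow(hits2), 0L)
})

test_that("the novelty filter applies a strict 95% identity cutoff", {
  withr::local_seed(131)
  known <- tibble::tibble(id = "k", residues = random_peptide(40))
  hits <- tibble::tibble(precursor = known$residues)
  expect_false(novelty_filter(hits, known)$novel)

  # exactly at the cutoff: 19/20 identity = 95.0 is NOT novel
  a <- strrep("A", 20)
  b <- paste0(strrep("A", 19), "W")
  out <- novelty_filter(tibble::tibble(precursor = b),
                        tibble::tibble(id = "k", residues = a))
  expect_equal(out$max_identity, 95)
  expect_false(out$novel)

  # mutate 10% of residues -> novel
  chars <- strsplit(known$residues, "")[[1]]
  chars[seq(1, 40, by = 10)] <- "W"
  out2 <- novelty_filter(
    tibble::tibble(precursor = paste(chars, collapse = "")), known
  )
  expect_true(out2$novel)
})
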