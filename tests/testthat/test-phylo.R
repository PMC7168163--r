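test_that("alignment distances follow the p-distance definition", {
  msa <- tibble::tibble(
    id = c("a", "b", "c"),
    aligned = c("ACDE", "ACDA", "AC-E")
  )
  D <- msa_distance_matrix(msa)
  expect_equal(D["a", "a"], 0)
  expect_equal(D["a", "b"], 0.25) # 1 of 4 comparable columns differs
  expect_equal(D["a", "c"], 0) # 3 comparable columns, all equal

  P <- msa_distance_matrix(msa, model = "poisson")
  expect_true(all(P >= D))
  expect_equal(P["a", "b"], -log(1 - 0.25))

  bad <- tibble::tibble(id = c("x", "y"), aligned = c("A-", "-A"))
  expect_error(msa_distance_matrix(bad), "no comparable columns")
})

test_that("neighbor joining solves the three-taxon case in closed form", {
  D <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- neighbor_joining(D)
  expect_equal(sort(tree$tip.label), c("a", "b", "c"))
  cd <- cophenetic(tree)
  expect_equal(cd["a", "b"], 3)
  expect_equal(cd["a", "c"], 5)
  expect_equal(cd["b", "c"], 6)
})

test_that("neighbor joining reconstructs random additive trees exactly", {
  withr::local_seed(137)
  for (rep in 1:12) {
    n <- sample(4:6, 1)
    tree <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 1))
    D <- stats::cophenetic(tree)
    ids <- sort(rownames(D))
    D <- D[ids, ids]
    rec <- neighbor_joining(D)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tree), rec)), 0)
    expect_equal(unname(stats::cophenetic(rec)[ids, ids]), unname(D),
                 tolerance = 1e-8)
  }
})

test_that("our agglomeration agrees with the reference NJ implementation", {
  withr::local_seed(139)
  for (rep in 1:5) {
    n <- 7
    M <- matrix(stats::runif(n * n, 0.2, 1), n, n)
    M <- (M + t(M)) / 2
    diag(M) <- 0
    dimnames(M) <- list(letters[1:n], letters[1:n])
    ours <- suppressMessages(neighbor_joining(M))
    apes <- ape::nj(M)
    expect_equal(as.numeric(ape::dist.topo(ours, apes)), 0)
  }
})

test_that("trees round-trip through Newick and keep all leaves", {
  withr::local_seed(149)
  co <- synth_cohort(synth_config(seed = 149, n_mytilins = 8, n_decoys = 0,
                                  n_transcripts = 8))
  tree <- neighbor_joining(msa_distance_matrix(progressive_msa(co$matures)))
  expect_setequal(tree$tip.label, co$matures$id)
  tmp <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, tmp)
  back <- read_newick(tmp)
  expect_equal(as.numeric(ape::dist.topo(tree, back)), 0)
  expect_true(all(back$edge.length >= 0))
})

test_that("two diverged synthetic families form disjoint clades", {
  co <- synth_cohort(synth_config(seed = 151, n_mytilins = 20, n_decoys = 0,
                                  n_transcripts = 20))
  tree <- neighbor_joining(msa_distance_matrix(progressive_msa(co$matures)))
  perna <- co$precursors$id[co$precursors$family == "perna"]
  mytilus <- setdiff(co$precursors$id, perna)
  rooted <- ape::root(tree, outgroup = mytilus[1], resolve.root = TRUE)
  expect_true(ape::is.monophyletic(rooted, perna))
  rooted2 <- ape::root(tree, outgroup = perna[1], resolve.root = TRUE)
  expect_true(ape::is.monophyletic(rooted2, mytilus))
})
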