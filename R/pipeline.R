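#' Run the full discovery-and-characterization pipeline on a synthetic corpus
#'
#' Generates a seeded synthetic corpus, screens its transcripts with the
#' iterative homology search, segments and profiles the accepted
#' precursors, classifies cysteine arrays, reduces redundancy, builds and
#' calibrates the family profile HMM, and emits a neighbor-joining tree —
#' writing every artifact plus a JSON run manifest (configuration,
#' package version, md5 checksums) to `out_dir`. Deterministic given the
#' configuration seed; any stage failure aborts with the stage name.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory (created if missing).
#' @param n_seeds Number of synthetic precursors used as initial screen
#'   seeds (default 3).
#' @param e_threshold Screen significance threshold (default 1e-3).
#' @param redundancy_threshold Hobohm-2 distance threshold (default 0.1).
#' @param window Sliding-pI window in residues (default 15).
#' @return Invisibly, a tibble of written artifacts (`artifact`, `path`,
#'   `md5`).
#' @export
run_pipeline <- function(config = synth_config(), out_dir,
                         n_seeds = 3L, e_threshold = 1e-3,
                         redundancy_threshold = 0.1, window = 15L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  paths <- c(
    precursors = "precursors.faa", transcripts = "transcripts.fna",
    truth = "truth.tsv", hits = "hits.tsv", annotations = "annotations.tsv",
    physchem = "physchem.tsv", cysarray = "cysarray.tsv",
    reduced = "reduced.tsv", hmm = "mytilin.hmm", tree = "tree.nwk",
    manifest = "manifest.json"
  )
  paths <- setNames(file.path(out_dir, paths), names(paths))

  cohort <- stage("synth", synth_cohort(config))
  write_fasta(cohort$precursors, paths[["precursors"]])
  write_fasta(cohort$transcripts, paths[["transcripts"]])
  write_tsv_report(cohort$truth, paths[["truth"]])

  seeds <- head(cohort$precursors, n_seeds)
  hits <- stage("screen", iterative_screen(
    seeds, cohort$transcripts, e_threshold = e_threshold
  ))
  hits <- stage("novelty", novelty_filter(hits, seeds))
  write_tsv_report(hits, paths[["hits"]])

  peptides <- tibble(
    id = paste0(hits$transcript_id, "|", hits$frame, "|", hits$orf_start),
    residues = hits$precursor
  )
  annotations <- tibble(
    peptide_id = peptides$id,
    sp_end = hits$sp_end,
    mature_start = hits$mature_start,
    mature_end = hits$mature_end,
    ctail_start = ifelse(hits$mature_end < nchar(hits$precursor),
                         hits$mature_end + 1L, NA_integer_),
    ctail_end = ifelse(hits$mature_end < nchar(hits$precursor),
                       nchar(hits$precursor), NA_integer_),
    method = "by_alignment",
    note = NA_character_
  )
  write_tsv_report(annotations, paths[["annotations"]])

  profile <- stage("physchem", sliding_pi_profile(peptides, window = window))
  write_tsv_report(profile, paths[["physchem"]])

  matures <- stage("segment", extract_segment(peptides, annotations, "mature"))
  arrays <- stage("cysarray", detect_cysteine_arrays(matures))
  write_tsv_report(arrays, paths[["cysarray"]])

  graph <- stage("reduce", distance_graph(matures, redundancy_threshold))
  reduced <- stage("reduce", hobohm2_reduce(graph))
  write_tsv_report(reduced, paths[["reduced"]])

  retained <- matures[matures$id %in% reduced$id[reduced$retained], ]
  msa <- stage("align", progressive_msa(retained))
  hmm <- stage("hmm", {
    h <- build_profile_hmm(msa)
    calibrate_hmm(h, nchar(retained$residues), seed = config$seed)
  })
  write_hmm(hmm, paths[["hmm"]])

  tree <- stage("tree", {
    if (nrow(msa) < 3) abort("need >= 3 retained sequences for a tree")
    neighbor_joining(msa_distance_matrix(msa))
  })
  write_newick(tree, paths[["tree"]])

  artifact_paths <- paths[names(paths) != "manifest"]
  manifest <- list(
    package = "mytikit",
    version = as.character(utils::packageVersion("mytikit")),
    config = unclass(config),
    thresholds = list(
      screen_evalue = e_threshold,
      redundancy = redundancy_threshold,
      pi_window = window
    ),
    n_hits = nrow(hits),
    n_retained = sum(reduced$retained),
    checksums = as.list(tools::md5sum(unname(artifact_paths)))
  )
  jsonlite::write_json(manifest, paths[["manifest"]],
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(tibble(
    artifact = names(artifact_paths),
    path = unname(artifact_paths),
    md5 = unname(tools::md5sum(unname(artifact_paths)))
  ))
}
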