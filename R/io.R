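#' Read sequences from a FASTA file
#'
#' Reads plain (ungapped) protein or nucleotide FASTA into a tibble, one row
#' per record. Wrapped sequence lines are joined, record order is preserved,
#' and the sequence alphabet is validated strictly: protein records may use
#' the 20 standard one-letter codes plus `X`, nucleotide records `A/C/G/T/N`.
#' Lowercase input is uppercased with a warning. Duplicate ids and illegal
#' characters are hard errors.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @param provenance Provenance label attached to protein records, one of
#'   `"fixture"`, `"synthetic"`, `"screened"`.
#' @return A tibble with columns `id`, `residues` (or `nucleotides`),
#'   `description`, and for proteins `provenance`.
#' @examples
#' faa <- system.file("extdata", "mytilin_matures.faa", package = "mytikit")
#' read_fasta(faa)
#' @export
read_fasta <- function(path,
                       alphabet = c("protein", "nucleotide"),
                       provenance = c("fixture", "synthetic", "screened")) {
  alphabet <- match.arg(alphabet)
  provenance <- match.arg(provenance)
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    abort(paste0(
      "duplicate record id(s) in ", path, ": ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  seqs <- as.character(set)
  if (any(grepl("[a-z]", seqs))) {
    warn("lowercase residues found; sequences uppercased")
    seqs <- toupper(seqs)
  }
  allowed <- if (alphabet == "protein") AA_ALPHABET else NT_ALPHABET
  for (i in seq_along(seqs)) {
    check_alphabet(seqs[[i]], allowed, ids[[i]])
  }
  if (alphabet == "protein") {
    tibble(
      id = ids, residues = unname(seqs),
      description = unname(desc), provenance = provenance
    )
  } else {
    tibble(id = ids, nucleotides = unname(seqs), description = unname(desc))
  }
}

# Errors naming the record and the 1-based position of the first bad character.
check_alphabet <- function(seq, allowed, id) {
  if (!nzchar(seq)) {
    abort(paste0("record '", id, "' has an empty sequence"))
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% allowed)
  if (length(bad)) {
    abort(paste0(
      "illegal character '", chars[bad[1]], "' in record '", id,
      "' at position ", bad[1]
    ))
  }
  invisible(TRUE)
}

#' Write sequences to a FASTA file
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(x, path))` recovers the
#' ids, descriptions and sequences exactly.
#'
#' @param x Tibble with an `id` column and a `residues` or `nucleotides`
#'   column (and optionally `description`).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  seq_col <- intersect(c("residues", "nucleotides", "aligned"), names(x))[1]
  if (is.na(seq_col)) {
    abort("no sequence column (residues/nucleotides/aligned) in `x`")
  }
  desc <- if ("description" %in% names(x)) x$description else rep("", nrow(x))
  desc[is.na(desc)] <- ""
  hdr <- ifelse(nzchar(desc), paste(x$id, desc), x$id)
  set <- Biostrings::BStringSet(setNames(x[[seq_col]], hdr))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Write a multiple sequence alignment in Stockholm 1.0 format
#'
#' @param msa Tibble with columns `id` and `aligned` (equal-length gapped
#'   rows, as produced by [progressive_msa()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stockholm <- function(msa, path) {
  stopifnot(all(c("id", "aligned") %in% names(msa)))
  if (length(unique(nchar(msa$aligned))) != 1L) {
    abort("alignment rows differ in length")
  }
  ids <- gsub("\\s", "_", msa$id)
  pad <- max(nchar(ids)) + 2L
  lines <- c(
    "# STOCKHOLM 1.0",
    sprintf(paste0("%-", pad, "s%s"), ids, msa$aligned),
    "//"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a Stockholm 1.0 alignment
#'
#' Minimal reader for the single-block dialect written by
#' [write_stockholm()]; `#=GF`/`#=GC` annotation lines are ignored.
#'
#' @param path Path to a Stockholm file.
#' @return A tibble with columns `id` and `aligned`.
#' @export
read_stockholm <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^# STOCKHOLM", lines[1])) {
    abort("not a Stockholm 1.0 file")
  }
  body <- lines[!grepl("^#", lines) & !grepl("^//", lines) & nzchar(trimws(lines))]
  parts <- strsplit(trimws(body), "\\s+")
  ids <- vapply(parts, `[`, character(1), 1L)
  seqs <- vapply(parts, function(p) paste(p[-1], collapse = ""), character(1))
  agg <- tapply(seqs, factor(ids, levels = unique(ids)), paste, collapse = "")
  tibble(id = names(agg), aligned = unname(as.character(agg)))
}

#' Read and write Newick trees
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] so the
#' pipeline's tree artifacts round-trip through plain text.
#'
#' @param tree An object of class `phylo`.
#' @param path File path.
#' @return `read_newick()` returns a `phylo`; `write_newick()` returns
#'   `path` invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Write a tabular report as TSV
#'
#' List columns (cysteine positions, disulfide pairs, ...) are collapsed to
#' comma-joined strings so every report is a plain-text table with a header
#' row. All coordinates in reports are 1-based inclusive.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(x, path) {
  flat <- dplyr::mutate(x, dplyr::across(
    dplyr::where(is.list),
    ~ vapply(.x, function(v) paste(unlist(v), collapse = ","), character(1))
  ))
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}
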