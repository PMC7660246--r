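#' Read a FASTA file
#'
#' Reads protein or nucleotide FASTA into a named character vector of
#' upper-cased sequences.  Record ids are the first whitespace-delimited
#' token of each header and must be unique.  For proteins, terminal stop
#' characters (`*`) are stripped; an internal `*` is an error (it usually
#' indicates a frameshift or pseudogene).  Illegal characters are reported
#' with their position.
#'
#' @param path Path to an existing FASTA file.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @return Named character vector of sequences, in file order.
#' @examples
#' f <- tempfile(fileext = ".faa")
#' write_fasta(c(p1 = "MKV"), f)
#' read_fasta(f, "protein")
#' @export
read_fasta <- function(path, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(paste0("empty FASTA file: ", path))
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    abort(sprintf("duplicate sequence id '%s' in %s", dup, path))
  }
  names(seqs) <- ids
  if (any(!nzchar(seqs))) {
    abort(sprintf("empty sequence for id '%s' in %s",
                  ids[!nzchar(seqs)][1], path))
  }
  if (alphabet == "protein") {
    seqs <- vapply(seqs, function(s) gsub("^\\*+|\\*+$", "", s),
                   character(1))
    if (any(!nzchar(seqs))) {
      abort(sprintf("sequence '%s' is empty after stripping terminal stops",
                    ids[!nzchar(seqs)][1]))
    }
    internal <- grepl("\\*", seqs)
    if (any(internal)) {
      abort(sprintf("internal stop character in sequence '%s'",
                    ids[internal][1]))
    }
  }
  # validate characters (errors carry the offending id and position)
  for (i in seq_along(seqs)) encode_seq(seqs[[i]], alphabet, ids[i])
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width in characters.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  stopifnot(length(seqs) > 0, !is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    n <- nchar(s)
    starts <- seq(1, n, by = width)
    writeLines(c(paste0(">", names(seqs)[i]),
                 substring(s, starts, pmin(starts + width - 1, n))), con)
  }
  invisible(path)
}

#' G+C content of an assembly
#'
#' Percentage of G+C over all contigs; `N` bases are excluded from the
#' denominator.
#'
#' @param contigs Named or unnamed character vector of nucleotide sequences.
#' @return G+C percentage.
#' @examples
#' gc_content("GGCC")  # 100
#' @export
gc_content <- function(contigs) {
  stopifnot(length(contigs) >= 1)
  s <- toupper(paste(contigs, collapse = ""))
  counts <- table(factor(strsplit(s, "", fixed = TRUE)[[1]],
                         levels = NT_LETTERS))
  acgt <- sum(counts[c("A", "C", "G", "T")])
  if (acgt == 0) abort("gc_content undefined: no unambiguous bases")
  100 * sum(counts[c("G", "C")]) / acgt
}

#' Construct a genome record
#'
#' Bundles one genome's id, proteome and optional assembly contigs.
#'
#' @param genome_id Unique genome label.
#' @param proteome Named character vector of protein sequences.
#' @param contigs Optional named character vector of nucleotide contigs.
#' @param is_outgroup Whether this genome is the tree-rooting outgroup.
#' @return A `genome_record` object.
#' @export
genome_record <- function(genome_id, proteome, contigs = NULL,
                          is_outgroup = FALSE) {
  stopifnot(is.character(genome_id), length(genome_id) == 1, nzchar(genome_id),
            length(proteome) > 0, !is.null(names(proteome)))
  if (anyDuplicated(names(proteome)))
    abort(sprintf("duplicate protein id in genome '%s'", genome_id))
  structure(list(genome_id = genome_id, proteome = proteome,
                 contigs = contigs, is_outgroup = isTRUE(is_outgroup)),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d proteins%s%s\n", x$genome_id,
              length(x$proteome),
              if (!is.null(x$contigs))
                sprintf(", %d contigs (%.0f bp)", length(x$contigs),
                        sum(nchar(x$contigs))) else "",
              if (x$is_outgroup) " [outgroup]" else ""))
  invisible(x)
}

as_proteome <- function(x) {
  if (inherits(x, "genome_record")) x$proteome
  else if (is.character(x) && !is.null(names(x))) x
  else abort("expected a genome_record or a named character vector of proteins")
}

as_contigs <- function(x) {
  if (inherits(x, "genome_record")) {
    if (is.null(x$contigs))
      abort(sprintf("genome '%s' has no nucleotide contigs", x$genome_id))
    x$contigs
  } else if (is.character(x) && length(x) >= 1) {
    if (is.null(names(x))) names(x) <- paste0("contig", seq_along(x))
    x
  } else abort("expected a genome_record with contigs or a character vector")
}

#' Read / write a genome manifest
#'
#' The manifest is a tab-separated table with columns `genome_id`,
#' `proteome` (FASTA path), `contigs` (FASTA path or empty) and `outgroup`
#' (0/1).  At most one genome may be flagged as outgroup.
#'
#' @param path Manifest path.
#' @return A tibble with one row per genome.
#' @export
read_manifest <- function(path) {
  m <- readr::read_tsv(path, col_types = readr::cols(
    genome_id = readr::col_character(),
    proteome = readr::col_character(),
    contigs = readr::col_character(),
    outgroup = readr::col_integer()))
  if (anyDuplicated(m$genome_id))
    abort("duplicate genome_id in manifest")
  if (sum(m$outgroup, na.rm = TRUE) > 1)
    abort("at most one outgroup entry is allowed")
  m
}

#' @rdname read_manifest
#' @param manifest Tibble as returned by [read_manifest()].
#' @export
write_manifest <- function(manifest, path) {
  readr::write_tsv(manifest, path)
  invisible(path)
}

#' Load all genomes listed in a manifest
#'
#' @param manifest Manifest tibble or path to a manifest file.
#' @param base_dir Directory that relative FASTA paths are resolved against.
#' @return Named list of [genome_record()] objects.
#' @export
load_genomes <- function(manifest, base_dir = ".") {
  if (is.character(manifest)) {
    base_dir <- dirname(manifest)
    manifest <- read_manifest(manifest)
  }
  resolve <- function(p) {
    ifelse(grepl("^/", p), p, file.path(base_dir, p))
  }
  recs <- purrr::pmap(manifest, function(genome_id, proteome, contigs,
                                         outgroup, ...) {
    ctg <- if (!is.na(contigs) && nzchar(contigs))
      read_fasta(resolve(contigs), "nucleotide") else NULL
    genome_record(genome_id, read_fasta(resolve(proteome), "protein"),
                  contigs = ctg,
                  is_outgroup = isTRUE(outgroup == 1L))
  })
  names(recs) <- manifest$genome_id
  recs
}

#' Read / write Newick trees
#'
#' Thin wrappers around \pkg{ape} with the validation this pipeline needs:
#' trees must have leaves; missing branch lengths default to 0 with a
#' warning; round trips preserve leaf sets and branch lengths.
#'
#' @param path Newick file path.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) abort(paste0("Newick file not found: ", path))
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) abort(paste0("cannot parse Newick: ",
                                                  conditionMessage(e))))
  if (is.null(tr) || is.null(tr$tip.label) || length(tr$tip.label) == 0)
    abort("Newick tree has no leaves")
  if (is.null(tr$edge.length)) {
    warn("tree has no branch lengths; defaulting to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    warn("tree has missing branch lengths; defaulting to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  tr
}

#' @rdname read_newick
#' @param tree An `ape::phylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Read / write a labelled similarity matrix as TSV
#'
#' Row and column headers are genome ids; the first column is named
#' `genome_id`.
#'
#' @param m Symmetric labelled matrix.
#' @param path Output path.
#' @param metric Optional metric label recorded on read.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- as.data.frame(m)
  df <- cbind(genome_id = rownames(m), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path, metric = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    genome_id = readr::col_character(), .default = readr::col_double()))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$genome_id
  similarity_matrix(m, metric = metric %||% "UNKNOWN")
}
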