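# Residue alphabets, integer encodings and scoring matrices.
#
# Proteins use the 20 standard residues plus the ambiguity codes B, Z, X;
# a terminal stop '*' is stripped on input.  Nucleotides use ACGTN.
# Ambiguity codes are retained in alignments but never count as identity
# matches, and N always scores as a mismatch: identity stays conservative.

AA_LETTERS <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                "R","S","T","V","W","Y","B","Z","X")
AA_STANDARD <- AA_LETTERS[1:20]
NT_LETTERS <- c("A","C","G","T","N")

# byte-indexed code lookup (1-based codes; NA = illegal character)
.make_lookup <- function(letters) {
  lk <- rep(NA_integer_, 127L)
  lk[utf8ToInt(paste(letters, collapse = ""))] <- seq_along(letters)
  lk
}

.alphabet <- function(type = c("protein", "nucleotide")) {
  type <- match.arg(type)
  if (is.null(the$alpha)) {
    the$alpha <- list(
      protein = list(
        letters = AA_LETTERS,
        lookup = .make_lookup(AA_LETTERS),
        match_ok = as.integer(AA_LETTERS %in% AA_STANDARD)
      ),
      nucleotide = list(
        letters = NT_LETTERS,
        lookup = .make_lookup(NT_LETTERS),
        match_ok = as.integer(NT_LETTERS != "N")
      )
    )
  }
  the$alpha[[type]]
}

# BLOSUM62 restricted to our protein alphabet, 0-based-code order,
# sourced from the matrix shipped with Biostrings.
blosum62_matrix <- function() {
  if (is.null(the$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62[AA_LETTERS, AA_LETTERS]
    storage.mode(m) <- "integer"
    the$blosum62 <- m
  }
  the$blosum62
}

nucleotide_matrix <- function(match = 1L, mismatch = -2L) {
  n <- length(NT_LETTERS)
  m <- matrix(as.integer(mismatch), n, n, dimnames = list(NT_LETTERS, NT_LETTERS))
  diag(m) <- as.integer(match)
  m["N", "N"] <- as.integer(mismatch)  # N never self-matches
  m
}

# Karlin-Altschul parameters per scoring scheme (gapped search).
ka_params <- function(scoring = c("blosum62", "nucleotide")) {
  scoring <- match.arg(scoring)
  switch(scoring,
    blosum62   = list(lambda = 0.267, K = 0.041),
    nucleotide = list(lambda = 1.28,  K = 0.46))
}

# Encode an upper-case sequence string into 0-based integer codes.
encode_seq <- function(s, type = c("protein", "nucleotide"), id = NULL) {
  type <- match.arg(type)
  al <- .alphabet(type)
  bytes <- utf8ToInt(s)
  bad <- bytes > 126L | bytes < 1L
  codes <- rep(NA_integer_, length(bytes))
  codes[!bad] <- al$lookup[bytes[!bad]]
  if (anyNA(codes)) {
    pos <- which(is.na(codes))[1]
    abort(sprintf("illegal %s character '%s' at position %d%s",
                  type, substr(s, pos, pos), pos,
                  if (!is.null(id)) paste0(" in sequence '", id, "'") else ""))
  }
  codes - 1L
}

encode_seqs <- function(seqs, type) {
  out <- vector("list", length(seqs))
  ids <- names(seqs)
  for (i in seq_along(seqs)) out[[i]] <- encode_seq(seqs[[i]], type, ids[i])
  names(out) <- ids
  out
}

reverse_complement <- function(s) {
  vapply(s, function(x) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                                   collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}
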