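#' Validated RNA sequence
#'
#' Constructs an `rna_sequence`: an identifier plus a residue string over the
#' alphabet A, C, G, U. DNA input is accepted (T is normalised to U) and
#' lowercase letters are uppercased before validation; any other character —
#' including IUPAC ambiguity codes — is rejected with an error naming the
#' offending symbols.
#'
#' @param residues Character scalar, the sequence (RNA or DNA spelling).
#' @param id Character scalar identifier (default `"seq"`).
#' @return An object of class `rna_sequence`: a list with elements `id`,
#'   `residues` (normalised string) and `n` (length in nucleotides).
#' @examples
#' rna_sequence("gattaca", id = "x")   # T -> U, uppercased
#' @export
rna_sequence <- function(residues, id = "seq") {
  stopifnot(is.character(residues), length(residues) == 1L, !is.na(residues))
  stopifnot(is.character(id), length(id) == 1L)
  r <- chartr("tT", "uU", residues)
  r <- toupper(r)
  if (nchar(r) < 1L) stop("sequence must contain at least one residue")
  bad <- setdiff(unique(strsplit(r, "")[[1L]]), c("A", "C", "G", "U"))
  if (length(bad) > 0L) {
    stop(sprintf("invalid residues in '%s': %s (only A/C/G/U/T accepted; ambiguity codes are rejected)",
                 id, paste(bad, collapse = ", ")))
  }
  structure(list(id = id, residues = r, n = nchar(r)), class = "rna_sequence")
}

#' @export
print.rna_sequence <- function(x, ...) {
  shown <- if (x$n > 60L) paste0(substr(x$residues, 1L, 57L), "...") else x$residues
  cat(sprintf("<rna_sequence> %s (%d nt)\n%s\n", x$id, x$n, shown))
  invisible(x)
}

as_rna_sequence <- function(x, id = "seq") {
  if (inherits(x, "rna_sequence")) x else rna_sequence(x, id = id)
}

#' Read RNA sequences from a FASTA file
#'
#' Reads a (multi-record) FASTA file via Biostrings and returns a list of
#' validated [rna_sequence()] objects. T is normalised to U; records carrying
#' ambiguity codes raise an error naming the record.
#'
#' @param path Path to a FASTA file.
#' @return Named list of `rna_sequence` objects (names are record ids).
#' @export
read_rna_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop(sprintf("no FASTA records found in '%s'", path))
  ids <- sub("\\s.*$", "", names(ss))
  out <- lapply(seq_along(ss), function(i) rna_sequence(as.character(ss[[i]]), id = ids[i]))
  names(out) <- ids
  out
}

#' Write RNA sequences to a FASTA file
#'
#' @param seqs A single `rna_sequence` or a list of them.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_rna_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "rna_sequence")) seqs <- list(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    writeLines(paste0(">", s$id), con)
    starts <- seq(1L, s$n, by = width)
    writeLines(substring(s$residues, starts, pmin(starts + width - 1L, s$n)), con)
  }
  invisible(path)
}

#' Reverse complement of an RNA sequence
#'
#' @param x An `rna_sequence` or character scalar.
#' @return Character scalar, the reverse complement (RNA alphabet).
#' @export
reverse_complement <- function(x) {
  r <- if (inherits(x, "rna_sequence")) x$residues else as_rna_sequence(x)$residues
  as.character(Biostrings::reverseComplement(Biostrings::RNAString(r)))
}
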