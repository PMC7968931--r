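#' Count AU-rich elements (canonical AUUUA pentamer)
#'
#' Scans for the canonical ARE pentamer AUUUA. Input is case-normalised and T
#' is treated as U, so DNA spellings count identically. Overlapping
#' occurrences (e.g. the two in AUUUAUUUA) are counted by default; set
#' `overlapping = FALSE` to consume matched bases.
#'
#' @param seq An `rna_sequence` or character string.
#' @param overlapping Count overlapping matches (default TRUE).
#' @return Integer count of AUUUA occurrences.
#' @examples
#' count_ares("AUUUAUUUA")           # 2
#' count_ares("AUUUAUUUA", overlapping = FALSE)  # 1
#' @export
count_ares <- function(seq, overlapping = TRUE) {
  seq <- as_rna_sequence(seq)
  if (overlapping) {
    hits <- gregexpr("(?=AUUUA)", seq$residues, perl = TRUE)[[1L]]
  } else {
    hits <- gregexpr("AUUUA", seq$residues, fixed = TRUE)[[1L]]
  }
  if (hits[1L] == -1L) 0L else length(hits)
}

#' GC content
#'
#' @param seq An `rna_sequence` or character string.
#' @return Fraction of G + C residues in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  seq <- as_rna_sequence(seq)
  res <- strsplit(seq$residues, "")[[1L]]
  sum(res %in% c("G", "C")) / seq$n
}

#' Sequence feature table for a set of RNAs
#'
#' @param seqs List of `rna_sequence` objects (e.g. from [read_rna_fasta()]).
#' @param overlapping Passed to [count_ares()].
#' @return data.frame with columns `id`, `length`, `n_are`, `gc_frac`.
#' @export
feature_table <- function(seqs, overlapping = TRUE) {
  if (inherits(seqs, "rna_sequence")) seqs <- list(seqs)
  data.frame(
    id = vapply(seqs, `[[`, character(1), "id"),
    length = vapply(seqs, `[[`, integer(1), "n"),
    n_are = vapply(seqs, count_ares, integer(1), overlapping = overlapping),
    gc_frac = vapply(seqs, gc_content, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

AVOGADRO <- 6.02214e23

#' Convert RNA copy number per cell to molar concentration
#'
#' Treats the cell as a well-mixed compartment of the given volume. With the
#' conventional HeLa volume of 2000 um^3, 10 copies correspond to about 8 pM
#' and 10,000 copies to about 8 nM.
#'
#' @param copies Copy number per cell (>= 0).
#' @param volume Cell volume in cubic micrometres (default 2000).
#' @return Concentration in mol/L.
#' @examples
#' copies_to_molar(10)      # ~8.3e-12 M
#' copies_to_molar(10000)   # ~8.3e-9 M
#' @export
copies_to_molar <- function(copies, volume = 2000) {
  stopifnot(all(copies >= 0))
  if (any(volume <= 0)) stop("cell volume must be positive")
  copies / (AVOGADRO * volume * 1e-15)
}

#' Molecular weight of an RNA from its length
#'
#' Uses a flat per-nucleotide mass; the default of 330 Da reproduces the
#' conventional 3500 nt ~ 1155 kDa equivalence for an average mRNA.
#'
#' @param length Length in nucleotides (>= 1).
#' @param per_nt_mass Average nucleotide mass in Da (default 330).
#' @return Molecular weight in Da.
#' @export
rna_molecular_weight <- function(length, per_nt_mass = 330) {
  stopifnot(all(length >= 1))
  length * per_nt_mass
}

#' Convert molar RNA concentration to mass concentration
#'
#' @param molar Concentration in mol/L.
#' @param length RNA length in nt.
#' @param per_nt_mass Average nucleotide mass in Da (default 330).
#' @return Mass concentration in g/L; multiply by 1000 for ng/ul (= mg/L).
#' @export
molar_to_mass <- function(molar, length, per_nt_mass = 330) {
  molar * rna_molecular_weight(length, per_nt_mass)
}
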