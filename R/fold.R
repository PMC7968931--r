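seq_codes <- function(seq) {
  match(strsplit(seq$residues, "")[[1L]], c("A", "C", "G", "U")) - 1L
}

check_fold_length <- function(seq, model) {
  if (seq$n > model$max_length) {
    stop(sprintf("sequence '%s' has %d nt, above the folding limit of %d nt (set max_length to override)",
                 seq$id, seq$n, model$max_length))
  }
}

call_engine <- function(seq, model, want_bppm = TRUE) {
  fold_engine_cpp(seq_codes(seq), ifelse(model$kind == "pairsum", 0L, 1L),
                  model$RT, model$min_hairpin, model$max_interior,
                  unname(model$pair_energy), unname(model$stack_energy),
                  model$hairpin_a, model$hairpin_b,
                  model$interior_a, model$interior_b, model$interior_asym,
                  want_bppm)
}

#' Fold an RNA into its thermodynamic ensemble summary
#'
#' Runs the inside-outside dynamic program and returns the full ensemble
#' summary: partition sum, ensemble free energy, base-pair probability
#' matrix, MFE and centroid structures, ensemble diversity, NED and the
#' per-position unpaired profile.
#'
#' Ensemble diversity is the expected base-pair distance between two
#' independent draws from the Boltzmann ensemble, `2 * sum p_ij (1 - p_ij)`
#' over `i < j`; NED divides it by the sequence length in nucleotides, so a
#' sequence locked into a single structure has NED near 0 and a maximally
#' undecided one approaches (but never exceeds) 1.
#'
#' @param seq An `rna_sequence` (or character string).
#' @param model An [energy_model()] (default: stacking model at 310.15 K).
#' @return Object of class `rna_ensemble` with elements `id`, `n`, `log_Zq`,
#'   `Zq`, `ensemble_free_energy`, `bppm`, `mfe` (a `secondary_structure`),
#'   `mfe_energy`, `centroid`, `ensemble_diversity`, `ned`,
#'   `unpaired_profile`, `model`.
#' @examples
#' fe <- fold_ensemble("GGGAAAACCC", energy_model("pairsum"))
#' fe$ned
#' @export
fold_ensemble <- function(seq, model = energy_model()) {
  seq <- as_rna_sequence(seq)
  check_fold_length(seq, model)
  res <- call_engine(seq, model, want_bppm = TRUE)
  bppm <- res$bppm
  mfe <- secondary_structure(cbind(res$mfe_i, res$mfe_j), n = seq$n)
  div <- ensemble_diversity(bppm)
  structure(list(
    id = seq$id, n = seq$n,
    residues = seq$residues,
    log_Zq = res$log_Z,
    Zq = exp(res$log_Z),
    ensemble_free_energy = -model$RT * res$log_Z,
    bppm = bppm,
    mfe = mfe,
    mfe_energy = res$mfe_energy,
    centroid = centroid_structure(bppm),
    ensemble_diversity = div,
    ned = div / seq$n,
    unpaired_profile = unpaired_profile(bppm),
    model = model
  ), class = "rna_ensemble")
}

#' @export
print.rna_ensemble <- function(x, ...) {
  cat(sprintf("<rna_ensemble> %s (%d nt, %s model)\n", x$id, x$n, x$model$kind))
  cat(sprintf("  ensemble free energy  %10.3f kcal/mol\n", x$ensemble_free_energy))
  cat(sprintf("  MFE                   %10.3f kcal/mol  %s\n",
              x$mfe_energy, structure_to_dotbracket(x$mfe)))
  cat(sprintf("  centroid              %21s %s\n", "", structure_to_dotbracket(x$centroid)))
  cat(sprintf("  ensemble diversity    %10.3f bp\n", x$ensemble_diversity))
  cat(sprintf("  NED                   %10.5f\n", x$ned))
  invisible(x)
}

#' @export
#' @method summary rna_ensemble
summary.rna_ensemble <- function(object, tau = 0.5, min_ldr_length = 30L, ...) {
  ldrs <- find_ldrs(object$unpaired_profile, tau = tau, min_ldr_length = min_ldr_length)
  out <- data.frame(
    id = object$id, length = object$n,
    mfe_kcal_mol = object$mfe_energy,
    ensemble_free_energy = object$ensemble_free_energy,
    ensemble_diversity = object$ensemble_diversity,
    ned = object$ned,
    n_ldrs = nrow(ldrs),
    stringsAsFactors = FALSE
  )
  attr(out, "ldrs") <- ldrs
  out
}

#' @export
#' @method plot rna_ensemble
plot.rna_ensemble <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(seq_len(x$n), seq_len(x$n), t(x$bppm)[, x$n:1],
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "position j", ylab = "position i",
                  main = sprintf("%s: base-pair probabilities", x$id), ...)
  graphics::plot(seq_len(x$n), x$unpaired_profile, type = "l",
                 ylim = c(0, 1), xlab = "position", ylab = "P(unpaired)",
                 main = "unpaired profile")
  graphics::abline(h = 0.5, lty = 2, col = "grey40")
  invisible(x)
}

#' Partition function of the structure ensemble
#'
#' @inheritParams fold_ensemble
#' @return List with `Zq` (the Boltzmann sum; the open chain contributes
#'   weight 1, so `Zq >= 1`), `log_Zq`, and `ensemble_free_energy` in
#'   kcal/mol.
#' @export
partition_function <- function(seq, model = energy_model()) {
  seq <- as_rna_sequence(seq)
  check_fold_length(seq, model)
  res <- call_engine(seq, model, want_bppm = FALSE)
  list(Zq = exp(res$log_Z), log_Zq = res$log_Z,
       ensemble_free_energy = -model$RT * res$log_Z)
}

#' Base-pair probability matrix
#'
#' @inheritParams fold_ensemble
#' @return Symmetric `n x n` matrix of pairing probabilities; entries within
#'   `min_hairpin` of the diagonal are structurally zero.
#' @export
pair_probabilities <- function(seq, model = energy_model()) {
  seq <- as_rna_sequence(seq)
  check_fold_length(seq, model)
  call_engine(seq, model, want_bppm = TRUE)$bppm
}

#' Minimum free energy structure
#'
#' Deterministic traceback (at equal energy the leftmost position is left
#' unpaired before being paired).
#'
#' @inheritParams fold_ensemble
#' @return List with `structure` (a `secondary_structure`) and `energy`
#'   (kcal/mol; 0 for the open chain).
#' @export
mfe_fold <- function(seq, model = energy_model()) {
  seq <- as_rna_sequence(seq)
  check_fold_length(seq, model)
  res <- call_engine(seq, model, want_bppm = FALSE)
  list(structure = secondary_structure(cbind(res$mfe_i, res$mfe_j), n = seq$n),
       energy = res$mfe_energy)
}

#' Centroid structure from a base-pair probability matrix
#'
#' The centroid minimises the expected base-pair distance to the ensemble;
#' for the distance used here it is exactly the set of pairs with probability
#' above 1/2. Two conflicting pairs cannot both exceed 1/2, so the result is
#' always a valid structure without any repair step.
#'
#' @param bppm Symmetric base-pair probability matrix.
#' @return A `secondary_structure`.
#' @export
centroid_structure <- function(bppm) {
  n <- nrow(bppm)
  idx <- which(upper.tri(bppm) & bppm > 0.5, arr.ind = TRUE)
  secondary_structure(cbind(idx[, 1L] - 1L, idx[, 2L] - 1L), n = n)
}

#' Ensemble diversity (expected base-pair distance)
#'
#' @param bppm Symmetric base-pair probability matrix.
#' @return `2 * sum_{i<j} p_ij (1 - p_ij)`, in base pairs: the expected
#'   symmetric-difference distance between two independent Boltzmann draws.
#' @export
ensemble_diversity <- function(bppm) {
  p <- bppm[upper.tri(bppm)]
  2 * sum(p * (1 - p))
}

#' Normalized ensemble diversity (NED)
#'
#' Ensemble diversity divided by the sequence length in nucleotides. Refuses
#' sequences above the model's `max_length` (default 7500 nt).
#'
#' @inheritParams fold_ensemble
#' @return NED, a dimensionless value in `[0, 1]`.
#' @export
ned <- function(seq, model = energy_model()) {
  seq <- as_rna_sequence(seq)
  check_fold_length(seq, model)
  ensemble_diversity(pair_probabilities(seq, model)) / seq$n
}

#' Per-position unpaired probability profile
#'
#' @param bppm Symmetric base-pair probability matrix.
#' @return Numeric vector `q` with `q_i = 1 - sum_j p_ij`, clipped to `[0, 1]`.
#' @export
unpaired_profile <- function(bppm) {
  pmin(pmax(1 - rowSums(bppm), 0), 1)
}

#' Call large disordered regions (LDRs) from an unpaired profile
#'
#' Maximal runs of positions whose unpaired probability exceeds `tau`, kept
#' when at least `min_ldr_length` nt long. "Large" is not quantified in the
#' condensate literature; both thresholds are explicit parameters.
#'
#' @param profile Per-position unpaired probabilities.
#' @param tau Threshold in (0, 1) (default 0.5).
#' @param min_ldr_length Minimum run length in nt (default 30).
#' @return data.frame with 0-based half-open `start`, `end`, and
#'   `mean_unpaired`; zero rows when no run qualifies.
#' @export
find_ldrs <- function(profile, tau = 0.5, min_ldr_length = 30L) {
  stopifnot(tau > 0, tau < 1, min_ldr_length >= 1L)
  above <- profile > tau
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_ldr_length
  out <- data.frame(
    start = starts[keep] - 1L,
    end = ends[keep],
    mean_unpaired = vapply(which(keep), function(k) {
      mean(profile[starts[k]:ends[k]])
    }, numeric(1))
  )
  rownames(out) <- NULL
  out
}
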