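#' Nearest-neighbour energy models for secondary-structure ensembles
#'
#' Two deliberately small, fully documented energy models drive the folding
#' engine. Both permit the six canonical/wobble pair types (AU, UA, CG, GC,
#' GU, UG) and enforce a minimum hairpin loop of `min_hairpin` unpaired
#' nucleotides.
#'
#' * `"pairsum"` — pair-additive: the energy of a structure is the sum of a
#'   per-pair-type energy over its base pairs (defaults GC/CG -3.0, AU/UA
#'   -2.0, GU/UG -1.0 kcal/mol). Loops are free. Every example is
#'   hand-checkable, which makes this the model of choice for exact tests.
#' * `"stacking"` — nearest-neighbour: helically stacked pair duples score a
#'   stack energy; hairpin and internal/bulge loops pay logarithmic
#'   Jacobson-Stockmayer-style penalties; multibranch and exterior loops are
#'   free. Pairs carry no intrinsic energy — stability comes from stacking.
#'   Internal/bulge loops with more than `max_interior` unpaired nucleotides
#'   in total are disallowed (infinite energy), a standard loop-span cap that
#'   is part of the model definition.
#'
#' The default stack table is built from per-pair strengths w(GC) = 3, w(AU)
#' = 2, w(GU) = 1 kcal/mol as `-( (w_outer + w_inner)/2 + 0.5 )`, giving e.g.
#' -3.5 for GC/GC and -2.5 for AU/AU. Loop penalties are
#' `hairpin(L) = 5.0 + 1.08 * log(L/3)` and
#' `interior(a, b) = 2.0 + 1.08 * log(a + b) + 0.4 * |a - b|` kcal/mol.
#' These are not the Turner 2004 parameters and the engine does not aim at
#' ViennaRNA parity; absolute ensemble-diversity values are model-specific.
#'
#' @param kind `"stacking"` (default for analyses) or `"pairsum"`.
#' @param temperature Temperature in Kelvin (default 310.15).
#' @param min_hairpin Minimum unpaired nucleotides in a hairpin loop (>= 3).
#' @param max_length Maximum sequence length accepted by the folding engine
#'   (default 7500 nt, mirroring the length limit under which 3'UTRs were
#'   analysed; refusals are explicit).
#' @param max_interior Cap on total unpaired nucleotides in an internal/bulge
#'   loop (stacking kind only; default 30).
#' @param pair_energy Named numeric vector over `c("AU","UA","CG","GC","GU","UG")`
#'   (pairsum kind).
#' @param stack_energy 6x6 numeric matrix, rows = outer pair type, cols =
#'   inner pair type, in the order AU, UA, CG, GC, GU, UG (stacking kind).
#' @param hairpin_a,hairpin_b Hairpin penalty parameters (kcal/mol).
#' @param interior_a,interior_b,interior_asym Internal/bulge penalty
#'   parameters (kcal/mol).
#' @return An object of class `energy_model`.
#' @examples
#' energy_model("pairsum")
#' energy_model("stacking", temperature = 298.15)
#' @export
energy_model <- function(kind = c("stacking", "pairsum"),
                         temperature = 310.15,
                         min_hairpin = 3L,
                         max_length = 7500L,
                         max_interior = 30L,
                         pair_energy = NULL,
                         stack_energy = NULL,
                         hairpin_a = 5.0, hairpin_b = 1.08,
                         interior_a = 2.0, interior_b = 1.08,
                         interior_asym = 0.4) {
  kind <- match.arg(kind)
  stopifnot(temperature > 0, min_hairpin >= 3L, max_length >= 1L, max_interior >= 0L)
  ptypes <- c("AU", "UA", "CG", "GC", "GU", "UG")
  if (is.null(pair_energy)) {
    pair_energy <- c(AU = -2.0, UA = -2.0, CG = -3.0, GC = -3.0, GU = -1.0, UG = -1.0)
  }
  if (!all(ptypes %in% names(pair_energy)) || any(!is.finite(pair_energy[ptypes]))) {
    stop("pair_energy must be finite and named over the six pair types AU, UA, CG, GC, GU, UG")
  }
  pair_energy <- pair_energy[ptypes]
  if (is.null(stack_energy)) {
    w <- c(AU = 2, UA = 2, CG = 3, GC = 3, GU = 1, UG = 1)
    stack_energy <- -(outer(w, w, `+`) / 2 + 0.5)
    dimnames(stack_energy) <- list(ptypes, ptypes)
  }
  stopifnot(is.matrix(stack_energy), dim(stack_energy) == c(6L, 6L), all(is.finite(stack_energy)))
  structure(list(
    kind = kind,
    temperature = temperature,
    RT = 0.0019872 * temperature,
    min_hairpin = as.integer(min_hairpin),
    max_length = as.integer(max_length),
    max_interior = as.integer(max_interior),
    pair_energy = pair_energy,
    stack_energy = stack_energy,
    hairpin_a = hairpin_a, hairpin_b = hairpin_b,
    interior_a = interior_a, interior_b = interior_b,
    interior_asym = interior_asym
  ), class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf("<energy_model> kind=%s  T=%.2f K  RT=%.5f kcal/mol\n",
              x$kind, x$temperature, x$RT))
  cat(sprintf("  min_hairpin=%d  max_length=%d  max_interior=%d\n",
              x$min_hairpin, x$max_length, x$max_interior))
  if (x$kind == "pairsum") {
    cat("  pair energies (kcal/mol):\n")
    print(x$pair_energy)
  } else {
    cat("  stack energies (kcal/mol), outer x inner pair type:\n")
    print(round(x$stack_energy, 2))
    cat(sprintf("  hairpin(L) = %.2f + %.2f log(L/3); interior(a,b) = %.2f + %.2f log(a+b) + %.2f |a-b|\n",
                x$hairpin_a, x$hairpin_b, x$interior_a, x$interior_b, x$interior_asym))
  }
  invisible(x)
}

# pair-type index for residues a, b (characters); 0 if not pairable.
# Order matches energy_model: AU=1, UA=2, CG=3, GC=4, GU=5, UG=6.
pair_type <- function(a, b) {
  key <- paste0(a, b)
  idx <- match(key, c("AU", "UA", "CG", "GC", "GU", "UG"))
  ifelse(is.na(idx), 0L, idx)
}

hairpin_penalty <- function(model, L) {
  model$hairpin_a + model$hairpin_b * log(L / 3)
}

interior_penalty <- function(model, a, b) {
  if (a + b == 0L) stop("interior loop with no unpaired residues is a stack, not a loop")
  if (a + b > model$max_interior) return(Inf)
  model$interior_a + model$interior_b * log(a + b) + model$interior_asym * abs(a - b)
}
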