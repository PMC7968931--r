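#' Secondary structure as a set of base pairs
#'
#' A nested (pseudoknot-free) secondary structure over a sequence of length
#' `n`, stored as a two-column integer matrix of 0-based pairs `(i, j)` with
#' `i < j`. Validation checks that no position pairs twice, that no two pairs
#' cross, and — when a sequence and model are supplied — that every pair is an
#' allowed pair type and encloses at least `min_hairpin` unpaired residues.
#'
#' @param pairs Two-column matrix (or empty) of 0-based pair indices.
#' @param n Sequence length.
#' @param seq Optional `rna_sequence` to validate pair types against.
#' @param model Optional `energy_model` supplying `min_hairpin` and allowed
#'   pairs (defaults to the package default model).
#' @return Object of class `secondary_structure` with fields `pairs` (matrix,
#'   rows sorted by `i`) and `n`.
#' @export
secondary_structure <- function(pairs, n, seq = NULL, model = NULL) {
  n <- as.integer(n)
  if (is.null(pairs) || length(pairs) == 0L) {
    pairs <- matrix(integer(0), ncol = 2L)
  }
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  colnames(pairs) <- c("i", "j")
  if (nrow(pairs) > 0L) {
    if (any(pairs[, 1L] >= pairs[, 2L])) stop("pairs must satisfy i < j")
    if (any(pairs < 0L) || any(pairs >= n)) stop("pair index out of range [0, n)")
    pos <- c(pairs[, 1L], pairs[, 2L])
    if (anyDuplicated(pos)) stop("a position occurs in more than one pair")
    pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
    # crossing check: for pairs sorted by i, any later pair starting inside
    # (i, j) must also end inside it
    if (nrow(pairs) > 1L) {
      for (a in seq_len(nrow(pairs) - 1L)) {
        inside <- pairs[, 1L] > pairs[a, 1L] & pairs[, 1L] < pairs[a, 2L]
        if (any(inside & pairs[, 2L] > pairs[a, 2L])) {
          stop("crossing base pairs (pseudoknots are not represented)")
        }
      }
    }
  }
  if (!is.null(seq) || !is.null(model)) {
    if (is.null(model)) model <- energy_model()
    if (!is.null(seq) && nrow(pairs) > 0L) {
      seq <- as_rna_sequence(seq)
      res <- strsplit(seq$residues, "")[[1L]]
      pt <- pair_type(res[pairs[, 1L] + 1L], res[pairs[, 2L] + 1L])
      if (any(pt == 0L)) {
        bad <- which(pt == 0L)[1L]
        stop(sprintf("pair (%d, %d) is not an allowed pair type (%s-%s)",
                     pairs[bad, 1L], pairs[bad, 2L],
                     res[pairs[bad, 1L] + 1L], res[pairs[bad, 2L] + 1L]))
      }
    }
    if (nrow(pairs) > 0L && any(pairs[, 2L] - pairs[, 1L] - 1L < model$min_hairpin)) {
      stop(sprintf("a pair encloses fewer than min_hairpin = %d residues", model$min_hairpin))
    }
  }
  structure(list(pairs = pairs, n = n), class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("<secondary_structure> n=%d, %d pairs\n%s\n",
              x$n, nrow(x$pairs), structure_to_dotbracket(x)))
  invisible(x)
}

#' Convert a secondary structure to dot-bracket notation
#'
#' @param s A `secondary_structure`.
#' @return Character scalar of length `s$n` over `.()`.
#' @export
structure_to_dotbracket <- function(s) {
  db <- rep(".", s$n)
  if (nrow(s$pairs) > 0L) {
    db[s$pairs[, 1L] + 1L] <- "("
    db[s$pairs[, 2L] + 1L] <- ")"
  }
  paste(db, collapse = "")
}

#' Parse dot-bracket notation into a secondary structure
#'
#' @param db Character scalar over `.()`.
#' @param seq,model Optional validation inputs, see [secondary_structure()].
#' @return A `secondary_structure`.
#' @export
dotbracket_to_structure <- function(db, seq = NULL, model = NULL) {
  ch <- strsplit(db, "")[[1L]]
  bad <- setdiff(unique(ch), c(".", "(", ")"))
  if (length(bad) > 0L) stop("dot-bracket string may only contain '.', '(' and ')'")
  open <- integer(0)
  pairs <- NULL
  for (k in seq_along(ch)) {
    if (ch[k] == "(") {
      open <- c(open, k - 1L)
    } else if (ch[k] == ")") {
      if (length(open) == 0L) stop(sprintf("unbalanced ')' at position %d", k))
      pairs <- rbind(pairs, c(open[length(open)], k - 1L))
      open <- open[-length(open)]
    }
  }
  if (length(open) > 0L) stop("unbalanced '(' in dot-bracket string")
  secondary_structure(pairs, n = length(ch), seq = seq, model = model)
}

#' Energy of a secondary structure under an energy model
#'
#' For the pairsum model the energy is the sum of per-pair-type energies. For
#' the stacking model the structure is decomposed into loops: each pair whose
#' enclosed region contains exactly one directly nested pair contributes a
#' stack energy (when the pairs are helically adjacent) or an internal/bulge
#' penalty; pairs closing hairpins pay the hairpin penalty; multibranch and
#' exterior loops are free. The open structure has energy 0.
#'
#' @param seq An `rna_sequence` (or string).
#' @param s A `secondary_structure` (validated against `seq` and `model`).
#' @param model An `energy_model`.
#' @return Energy in kcal/mol (`Inf` for interior loops over the model's cap).
#' @export
structure_energy <- function(seq, s, model = energy_model()) {
  seq <- as_rna_sequence(seq)
  s <- secondary_structure(s$pairs, s$n, seq = seq, model = model)
  if (s$n != seq$n) stop("structure length does not match sequence length")
  if (nrow(s$pairs) == 0L) return(0)
  res <- strsplit(seq$residues, "")[[1L]]
  pt <- pair_type(res[s$pairs[, 1L] + 1L], res[s$pairs[, 2L] + 1L])
  if (model$kind == "pairsum") {
    return(unname(sum(model$pair_energy[pt])))
  }
  # stacking: loop decomposition over each closing pair
  e <- 0
  paired_at <- rep(NA_integer_, s$n)          # 0-based partner or NA
  paired_at[s$pairs[, 1L] + 1L] <- s$pairs[, 2L]
  paired_at[s$pairs[, 2L] + 1L] <- s$pairs[, 1L]
  for (r in seq_len(nrow(s$pairs))) {
    i <- s$pairs[r, 1L]; j <- s$pairs[r, 2L]
    # walk the loop closed by (i, j): directly nested branches
    branches <- NULL
    k <- i + 1L
    while (k < j) {
      p <- paired_at[k + 1L]
      if (!is.na(p) && p > k) {
        branches <- rbind(branches, c(k, p))
        k <- p + 1L
      } else {
        k <- k + 1L
      }
    }
    nb <- if (is.null(branches)) 0L else nrow(branches)
    if (nb == 0L) {
      e <- e + hairpin_penalty(model, j - i - 1L)
    } else if (nb == 1L) {
      k <- branches[1L, 1L]; l <- branches[1L, 2L]
      a <- k - i - 1L; b <- j - l - 1L
      if (a == 0L && b == 0L) {
        e <- e + model$stack_energy[pt[r], pair_type(res[k + 1L], res[l + 1L])]
      } else {
        e <- e + interior_penalty(model, a, b)
      }
    }
    # nb >= 2: multibranch loop, free
  }
  unname(e)
}
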