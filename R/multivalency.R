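# Seed hygiene: run seeded code without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Declare RNA dimerization element types
#'
#' Each element type hybridises with exactly one partner type; homotypic
#' elements are their own partner. Partnerships must be symmetric.
#'
#' @param name Character vector of element names.
#' @param partner Character vector of the same length: the element each one
#'   hybridises with.
#' @return data.frame of class `dimer_elements`.
#' @examples
#' dimer_elements(c("D1a", "D1b", "D2"), c("D1b", "D1a", "D2"))
#' @export
dimer_elements <- function(name, partner) {
  stopifnot(length(name) == length(partner), !anyDuplicated(name))
  df <- data.frame(name = name, partner = partner, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(df))) {
    p <- df$partner[k]
    row <- which(df$name == p)
    if (length(row) != 1L || df$partner[row] != df$name[k]) {
      stop(sprintf("partnership is not symmetric for element '%s' (partner '%s')",
                   df$name[k], p))
    }
  }
  class(df) <- c("dimer_elements", "data.frame")
  df
}

#' Stochastic site-matching simulation of a multivalent RNA pool
#'
#' Models a pool of RNA molecules, each carrying an ordered list of
#' dimerization-element sites. Free compatible site pairs (matching element
#' partnership, on distinct molecules) are drawn uniformly at random and
#' matched irreversibly until no compatible pair remains. Because each
#' element type only ever pairs with its declared partner, the process
#' factorises over partnership classes and is simulated per class. The
#' resulting molecule-interaction graph distinguishes valency-1 pools (which
#' can only dimerise) from valency->=2 pools (which percolate into large
#' networks).
#'
#' @param constructs Named list: construct name -> character vector of site
#'   element names (may be empty for an inert core).
#' @param copies Named integer vector of copy numbers per construct.
#' @param elements A [dimer_elements()] declaration covering every site.
#' @param seed Integer seed; identical seed and pool give identical results.
#' @return Object of class `match_result`: `nodes` (molecule, construct),
#'   `edges` (mol_a, mol_b, element_a, element_b), `component_sizes`,
#'   `largest`, `fraction_in_largest`.
#' @examples
#' el <- dimer_elements("D", "D")
#' match_sites(list(mono = "D"), c(mono = 10), el, seed = 1)
#' @export
match_sites <- function(constructs, copies, elements, seed = 1L) {
  stopifnot(is.list(constructs), !is.null(names(constructs)))
  copies <- copies[names(constructs)]
  if (anyNA(copies)) stop("copies must be named for every construct")
  used <- unique(unlist(constructs))
  undeclared <- setdiff(used, elements$name)
  if (length(undeclared) > 0L) {
    stop(sprintf("undeclared dimerization element(s): %s", paste(undeclared, collapse = ", ")))
  }
  n_mol <- sum(copies)
  mol_construct <- rep(names(constructs), times = copies)
  mol_id <- seq_len(n_mol)
  # one row per site: owning molecule and element type
  sites_per <- lengths(constructs)
  site_mol <- unlist(mapply(function(cname, cp) {
    rep(mol_id[mol_construct == cname], each = sites_per[[cname]])
  }, names(constructs), copies, SIMPLIFY = FALSE), use.names = FALSE)
  site_el <- unlist(mapply(function(cname, cp) {
    rep(constructs[[cname]], times = cp)
  }, names(constructs), copies, SIMPLIFY = FALSE), use.names = FALSE)

  edges <- list()
  with_seed(seed, {
    # partnership classes: unordered pairs {el, partner(el)}
    cls <- unique(t(apply(cbind(elements$name, elements$partner), 1L, sort)))
    for (r in seq_len(nrow(cls))) {
      a <- cls[r, 1L]; b <- cls[r, 2L]
      if (a == b) {
        free <- which(site_el == a)
        repeat {
          mols <- site_mol[free]
          if (length(free) < 2L || length(unique(mols)) < 2L) break
          repeat {
            pick <- sample(length(free), 2L)
            if (mols[pick[1L]] != mols[pick[2L]]) break
          }
          s1 <- free[pick[1L]]; s2 <- free[pick[2L]]
          edges[[length(edges) + 1L]] <- c(site_mol[s1], site_mol[s2], a, a)
          free <- free[-pick]
        }
      } else {
        fa <- which(site_el == a); fb <- which(site_el == b)
        repeat {
          if (length(fa) == 0L || length(fb) == 0L) break
          ma <- site_mol[fa]; mb <- site_mol[fb]
          # a compatible pair needs distinct molecules
          if (length(unique(c(ma, mb))) == 1L) break
          repeat {
            ia <- sample(length(fa), 1L); ib <- sample(length(fb), 1L)
            if (ma[ia] != mb[ib]) break
          }
          edges[[length(edges) + 1L]] <- c(ma[ia], mb[ib], a, b)
          fa <- fa[-ia]; fb <- fb[-ib]
        }
      }
    }
  })
  edf <- if (length(edges) == 0L) {
    data.frame(mol_a = integer(0), mol_b = integer(0),
               element_a = character(0), element_b = character(0),
               stringsAsFactors = FALSE)
  } else {
    m <- do.call(rbind, edges)
    data.frame(mol_a = as.integer(m[, 1L]), mol_b = as.integer(m[, 2L]),
               element_a = m[, 3L], element_b = m[, 4L], stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    edf[, c("mol_a", "mol_b")],
    directed = FALSE,
    vertices = data.frame(name = as.character(mol_id))
  )
  comp <- igraph::components(g)
  sizes <- sort(as.integer(comp$csize), decreasing = TRUE)
  structure(list(
    nodes = data.frame(molecule = mol_id, construct = mol_construct,
                       stringsAsFactors = FALSE),
    edges = edf,
    component_sizes = sizes,
    largest = if (length(sizes)) sizes[1L] else 0L,
    fraction_in_largest = if (n_mol > 0L) sizes[1L] / n_mol else NA_real_
  ), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d molecules, %d matched site pairs\n",
              nrow(x$nodes), nrow(x$edges)))
  cat(sprintf("  largest component %d (%.1f%% of pool); %d components\n",
              x$largest, 100 * x$fraction_in_largest, length(x$component_sizes)))
  invisible(x)
}

#' Component-size summary of a match result
#'
#' @param result A `match_result` from [match_sites()].
#' @return List with `histogram` (named count vector: size -> number of
#'   components), `largest`, `mean_size`, `n_molecules`.
#' @export
component_stats <- function(result) {
  stopifnot(inherits(result, "match_result"))
  h <- table(result$component_sizes)
  list(histogram = h,
       largest = result$largest,
       mean_size = mean(result$component_sizes),
       n_molecules = nrow(result$nodes))
}

#' Scan two RNAs for their best contiguous antiparallel duplex
#'
#' Considers every run of consecutive allowed pairs between `a` (5'->3') and
#' `b` (3'->5') and returns the minimum-energy run of at least `min_len`
#' pairs. Under the pairsum model the run energy is the sum of pair
#' energies; under the stacking model it is the sum of stack energies along
#' the run. Interior loops are not modelled — the scan is contiguous only.
#' Ties are broken towards the smallest `(start_a, start_b)`.
#'
#' @param a,b `rna_sequence` objects (or strings).
#' @param model An [energy_model()].
#' @param min_len Minimum duplex length in bp (>= 2).
#' @return List with `start_a`, `start_b` (0-based starts of the paired
#'   blocks), `length`, `energy`; or `NULL` when no qualifying run exists.
#' @examples
#' duplex_scan("GGGG", "CCCC", energy_model("pairsum"), min_len = 4)
#' @export
duplex_scan <- function(a, b, model = energy_model("pairsum"), min_len = 2L) {
  stopifnot(min_len >= 2L)
  a <- as_rna_sequence(a, "a"); b <- as_rna_sequence(b, "b")
  ra <- strsplit(a$residues, "")[[1L]]
  rb <- strsplit(b$residues, "")[[1L]]
  best <- NULL
  # run starting with pair (a[i], b[k]), extending (i+1, k-1), 1-based here
  for (i in seq_len(a$n)) {
    for (k in seq_len(b$n)) {
      # only run starts: predecessor (i-1, k+1) must not extend the run
      if (i > 1L && k < b$n && pair_type(ra[i - 1L], rb[k + 1L]) > 0L) next
      if (pair_type(ra[i], rb[k]) == 0L) next
      L <- 1L
      while (i + L <= a$n && k - L >= 1L && pair_type(ra[i + L], rb[k - L]) > 0L) L <- L + 1L
      if (L < min_len) next
      pts <- pair_type(ra[i:(i + L - 1L)], rb[k:(k - L + 1L)])
      step_e <- if (model$kind == "pairsum") {
        unname(model$pair_energy[pts])
      } else {
        # stacking: energy attaches to consecutive pair duples
        if (L < 2L) next
        model$stack_energy[cbind(pts[-L], pts[-1L])]
      }
      # all sub-runs of length >= min_len within this maximal run
      ne <- length(step_e)
      need <- if (model$kind == "pairsum") min_len else min_len - 1L
      for (s in seq_len(ne - need + 1L)) {
        for (e in seq.int(s + need - 1L, ne)) {
          en <- sum(step_e[s:e])
          len <- if (model$kind == "pairsum") e - s + 1L else e - s + 2L
          sa <- i + s - 1L           # 1-based start in a
          kb <- k - (s - 1L)         # 1-based position in b of first pair
          sb <- kb - len + 1L        # 1-based start of b's paired block
          cand <- list(start_a = sa - 1L, start_b = sb - 1L, length = len, energy = en)
          if (is.null(best) ||
              en < best$energy - 1e-12 ||
              (abs(en - best$energy) <= 1e-12 &&
               (cand$start_a < best$start_a ||
                (cand$start_a == best$start_a && cand$start_b < best$start_b)))) {
            best <- cand
          }
        }
      }
    }
  }
  best
}

#' Read a construct-pool specification from TSV
#'
#' Expected columns: `construct`, `sites` (comma-separated element names;
#' empty for an inert core), `copies`.
#'
#' @param path Path to the pool TSV.
#' @return List with `constructs` (named list of site vectors) and `copies`.
#' @export
read_pool_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("construct", "sites", "copies")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop(sprintf("pool TSV lacks column(s): %s", paste(missing, collapse = ", ")))
  constructs <- lapply(df$sites, function(s) {
    if (is.na(s) || !nzchar(s)) character(0) else trimws(strsplit(s, ",")[[1L]])
  })
  names(constructs) <- df$construct
  list(constructs = constructs,
       copies = stats::setNames(as.integer(df$copies), df$construct))
}

#' Read dimerization-element declarations from TSV
#'
#' Expected columns: `name`, `partner`.
#'
#' @param path Path to the element TSV.
#' @return A [dimer_elements()] table.
#' @export
read_elements_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "partner")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop(sprintf("element TSV lacks column(s): %s", paste(missing, collapse = ", ")))
  dimer_elements(df$name, df$partner)
}
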