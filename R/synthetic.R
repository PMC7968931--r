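#' Generate a perfect-hairpin RNA
#'
#' Draws a random stem of the requested GC fraction and returns
#' `stem + loop + reverse-complement(stem)`: a sequence locked into one
#' strong local structure, emulating a predominantly structured 3'UTR. The
#' loop is filled with A.
#'
#' @param stem_len Stem length in nt (0 gives a pure loop).
#' @param loop_len Loop length in nt (>= 3).
#' @param gc_frac Fraction of G/C in the stem (default 1).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @return An `rna_sequence` of length `2 * stem_len + loop_len`.
#' @export
gen_hairpin <- function(stem_len, loop_len = 4L, gc_frac = 1, seed = 1L) {
  stopifnot(stem_len >= 0L, loop_len >= 3L, gc_frac >= 0, gc_frac <= 1)
  with_seed(seed, {
    stem <- if (stem_len > 0L) {
      paste(sample(c("G", "C", "A", "U"), stem_len, replace = TRUE,
                   prob = c(gc_frac / 2, gc_frac / 2, (1 - gc_frac) / 2, (1 - gc_frac) / 2)),
            collapse = "")
    } else ""
    loop <- paste(rep("A", loop_len), collapse = "")
    rc <- if (stem_len > 0L) reverse_complement(stem) else ""
    rna_sequence(paste0(stem, loop, rc),
                 id = sprintf("hairpin_s%d_l%d_seed%d", stem_len, loop_len, seed))
  })
}

#' Generate an unstructured AU-rich random RNA
#'
#' I.i.d. residues with `P(A) = P(U) = au_frac / 2` and the remainder split
#' between G and C — emulating the AU-rich, weakly structured 3'UTRs that
#' drive mesh-like condensate formation.
#'
#' @param length Length in nt.
#' @param au_frac Total A+U fraction in `[0, 1]` (default 0.8).
#' @param seed Integer seed.
#' @return An `rna_sequence`.
#' @export
gen_unstructured <- function(length, au_frac = 0.8, seed = 1L) {
  stopifnot(length >= 1L, au_frac >= 0, au_frac <= 1)
  with_seed(seed, {
    r <- sample(c("A", "U", "G", "C"), length, replace = TRUE,
                prob = c(au_frac / 2, au_frac / 2, (1 - au_frac) / 2, (1 - au_frac) / 2))
    rna_sequence(paste(r, collapse = ""),
                 id = sprintf("unstructured_n%d_seed%d", length, seed))
  })
}

ares_spanning <- function(residues, from, to) {
  # AUUUA occurrences overlapping positions [from, to] (1-based, inclusive)
  hits <- gregexpr("(?=AUUUA)", residues, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) return(integer(0))
  hits[hits <= to & hits + 4L >= from]
}

#' Insert antisense copies of upstream windows into an RNA
#'
#' Reproduces the logic of a structure-stabilising mutant: for each copy, a
#' donor window of `insert_len` nt is read from the sequence and its reverse
#' complement is inserted downstream, creating a perfect local duplex that
#' strengthens secondary structure and lowers NED. Insertions must neither
#' split an existing AUUUA element nor change the total ARE count (the
#' inserted antisense segment could otherwise introduce new AUUUA matches);
#' violations raise an error listing the conflicting positions. Use
#' [plan_antisense_insertion()] to find compliant coordinates automatically.
#'
#' @param seq An `rna_sequence` (or string).
#' @param donor_start 0-based start(s) of the donor window(s); a scalar is
#'   expanded to `copies` consecutive windows.
#' @param insert_pos 0-based position(s) at which to insert (the insert goes
#'   before this position, in original coordinates); must lie downstream of
#'   the corresponding donor window. A scalar is expanded.
#' @param insert_len Window length in nt (default 15).
#' @param copies Number of inserted oligos (default 2).
#' @return An `rna_sequence` of length `seq$n + copies * insert_len` with
#'   unchanged ARE count.
#' @export
insert_antisense <- function(seq, donor_start, insert_pos,
                             insert_len = 15L, copies = 2L) {
  seq <- as_rna_sequence(seq)
  stopifnot(insert_len >= 0L, copies >= 1L)
  if (insert_len == 0L) return(seq)
  if (length(donor_start) == 1L) donor_start <- donor_start + (seq_len(copies) - 1L) * insert_len
  if (length(insert_pos) == 1L) insert_pos <- rep(insert_pos, copies)
  stopifnot(length(donor_start) == copies, length(insert_pos) == copies)
  if (any(donor_start < 0L) || any(donor_start + insert_len > seq$n)) {
    stop("donor window out of bounds")
  }
  if (any(insert_pos < donor_start + insert_len) || any(insert_pos > seq$n)) {
    stop("insert position must lie downstream of its donor window and within the sequence")
  }
  n_are_before <- count_ares(seq)
  res <- seq$residues
  shift <- 0L
  for (k in order(insert_pos)) {
    donor <- substr(seq$residues, donor_start[k] + 1L, donor_start[k] + insert_len)
    ins <- reverse_complement(donor)
    p <- insert_pos[k] + shift            # current-coordinate insertion point
    conflicts <- ares_spanning(res, p - 3L, p)  # motif starting here spans the cut
    conflicts <- conflicts[conflicts <= p & conflicts + 4L > p]
    if (length(conflicts) > 0L) {
      stop(sprintf("insertion at position %d would split AUUUA element(s) starting at %s (0-based %s)",
                   insert_pos[k], paste(conflicts, collapse = ", "),
                   paste(conflicts - 1L, collapse = ", ")))
    }
    res <- paste0(substr(res, 1L, p), ins, substr(res, p + 1L, nchar(res)))
    shift <- shift + insert_len
  }
  out <- rna_sequence(res, id = paste0(seq$id, "_antisense"))
  n_are_after <- count_ares(out)
  if (n_are_after != n_are_before) {
    stop(sprintf("insertion changes the ARE count (%d -> %d); choose donor windows whose antisense copies do not contain or create AUUUA",
                 n_are_before, n_are_after))
  }
  out
}

#' Find insertion coordinates that leave AU-rich elements intact
#'
#' Deterministically plans `copies` sequential donor/insertion blocks: each
#' antisense oligo goes a short gap downstream of its own donor window, so
#' every oligo zips into a local hairpin with its donor (sequential stems
#' that cannot cross each other). Candidates are scanned left to right and
#' the first combination for which [insert_antisense()] succeeds — no AUUUA
#' element split, total ARE count unchanged — is returned.
#'
#' @param seq An `rna_sequence` (or string).
#' @param insert_len Window length in nt (default 15).
#' @param copies Number of inserted oligos (default 2).
#' @param gap Unpaired nt left between a donor window and its antisense
#'   insertion point, the future hairpin loop (default 4).
#' @return List with `donor_start` and `insert_pos` (both 0-based vectors of
#'   length `copies`), or an error when no compliant plan exists.
#' @export
plan_antisense_insertion <- function(seq, insert_len = 15L, copies = 2L, gap = 4L) {
  seq <- as_rna_sequence(seq)
  block <- insert_len + gap
  if (seq$n < copies * block + insert_len) {
    stop("sequence too short for the requested insertions")
  }
  step <- max(1L, insert_len %/% 3L)
  plan_from <- function(starts) {
    donors <- integer(copies); pos <- integer(copies)
    for (k in seq_len(copies)) {
      donors[k] <- starts[k]
      pos[k] <- starts[k] + block
    }
    ok <- tryCatch({
      insert_antisense(seq, donors, pos, insert_len, copies)
      TRUE
    }, error = function(e) FALSE)
    if (ok) list(donor_start = donors, insert_pos = pos) else NULL
  }
  # first block start a1, subsequent blocks packed behind with slack
  for (a1 in seq.int(0L, seq$n - copies * block, by = step)) {
    # each later donor may slide independently a few steps
    offsets <- if (copies > 1L) seq.int(0L, 4L * step, by = step) else 0L
    for (off in offsets) {
      starts <- a1 + (seq_len(copies) - 1L) * (block + off)
      if (starts[copies] + block > seq$n) next
      p <- plan_from(starts)
      if (!is.null(p)) return(p)
    }
  }
  stop("no insertion plan preserves the AU-rich elements of this sequence")
}

#' Specification for a synthetic two-group cohort
#'
#' Describes the statistical structure of a per-RNA source-data table: group
#' sizes, NED means/SD (truncated-normal on `[0, 1]`), log-normal length
#' parameters, and a Poisson ARE rate per kb. Defaults mirror a 47-RNA
#' screen (19 sphere + 28 network formers) with NED centres 0.24 / 0.31 and
#' lengths around 1.2 / 1.8 kb, bracketing the observed NED range
#' 0.18-0.38 and lengths 500-3000 nt.
#'
#' @param n_sphere,n_network Group sizes.
#' @param ned_mean_sphere,ned_mean_network,ned_sd NED distribution per group.
#' @param length_logmean_sphere,length_logmean_network,length_logsd Length
#'   distribution (log-nt).
#' @param are_rate AU-rich elements per kb.
#' @param seed Integer seed.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_sphere = 19L, n_network = 28L,
                        ned_mean_sphere = 0.24, ned_mean_network = 0.31,
                        ned_sd = 0.03,
                        length_logmean_sphere = log(1200),
                        length_logmean_network = log(1800),
                        length_logsd = 0.45,
                        are_rate = 5, seed = 1L) {
  stopifnot(n_sphere >= 1L, n_network >= 1L, ned_sd > 0, length_logsd > 0, are_rate >= 0)
  structure(as.list(environment()), class = "cohort_spec")
}

rtruncnorm01 <- function(n, mean, sd) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0L) {
    draw <- stats::rnorm(length(todo), mean, sd)
    ok <- draw >= 0 & draw <= 1
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

#' Generate a synthetic per-RNA source-data table
#'
#' Draws a two-group cohort according to a [cohort_spec()]: NED from a
#' truncated normal per group, lengths log-normal, ARE counts Poisson with
#' rate proportional to length, GC fraction mildly anti-correlated with NED.
#' Observed morphology equals the generating group, so the table behaves
#' like a screen in which morphology tracks NED up to the group overlap.
#'
#' @param spec A [cohort_spec()].
#' @param cohort Label written to the `cohort` column (default "initial").
#' @return data.frame with columns `gene`, `cohort`, `observed`,
#'   `length_nt`, `n_are`, `gc_frac`, `ned`.
#' @export
gen_cohort <- function(spec = cohort_spec(), cohort = "initial") {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_sphere + spec$n_network
    grp <- rep(c("sphere", "network"), c(spec$n_sphere, spec$n_network))
    nedv <- c(rtruncnorm01(spec$n_sphere, spec$ned_mean_sphere, spec$ned_sd),
              rtruncnorm01(spec$n_network, spec$ned_mean_network, spec$ned_sd))
    len <- pmax(50L, round(stats::rlnorm(n,
      ifelse(grp == "sphere", spec$length_logmean_sphere, spec$length_logmean_network),
      spec$length_logsd)))
    n_are <- stats::rpois(n, spec$are_rate * len / 1000)
    gc <- pmin(0.9, pmax(0.1, 0.62 - nedv + stats::rnorm(n, 0, 0.05)))
    data.frame(
      gene = sprintf("SYN%03d", seq_len(n)),
      cohort = cohort,
      observed = grp,
      length_nt = as.integer(len),
      n_are = as.integer(n_are),
      gc_frac = round(gc, 4),
      ned = round(nedv, 4),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate synthetic 3'UTR and CLIP-peak BED tracks
#'
#' Lays `n_utrs` UTRs along a synthetic chromosome and scatters Poisson
#' peaks over them in each of `n_datasets` CLIP datasets. A chosen fraction
#' of UTRs is enriched: its peak rate is multiplied by `enrichment_factor`.
#' Truth labels are returned so recovery can be scored.
#'
#' @param n_utrs Number of UTRs.
#' @param utr_len_range Length range in nt (uniform draw).
#' @param n_datasets Number of CLIP datasets (default 2).
#' @param background_rate Peaks per kb per dataset for background UTRs
#'   (default 0.5: nonspecific binding leaves most non-target UTRs with no
#'   more than a couple of tags, while a 10-fold enriched target collects
#'   several).
#' @param enriched_fraction Fraction of UTRs that are enriched.
#' @param enrichment_factor Rate multiplier for enriched UTRs.
#' @param seed Integer seed.
#' @return List with `utrs` (GRanges), `peaks` (list of GRanges, one per
#'   dataset), `truth` (logical vector per UTR).
#' @export
gen_clip_tracks <- function(n_utrs = 100L, utr_len_range = c(500L, 3000L),
                            n_datasets = 2L, background_rate = 0.5,
                            enriched_fraction = 0.2, enrichment_factor = 10,
                            seed = 1L) {
  stopifnot(background_rate > 0, enrichment_factor > 0,
            enriched_fraction >= 0, enriched_fraction <= 1)
  with_seed(seed, {
    lens <- sample(seq(utr_len_range[1L], utr_len_range[2L]), n_utrs, replace = TRUE)
    gap <- 1000L
    starts <- cumsum(c(1L, utils::head(lens, -1L) + gap))
    strands <- sample(c("+", "-"), n_utrs, replace = TRUE)
    utrs <- GenomicRanges::GRanges(
      seqnames = "chrS",
      ranges = IRanges::IRanges(start = starts, width = lens),
      strand = strands
    )
    S4Vectors::mcols(utrs)$name <- sprintf("utr%03d", seq_len(n_utrs))
    truth <- seq_len(n_utrs) <= round(enriched_fraction * n_utrs)
    truth <- sample(truth)   # shuffle which UTRs are enriched
    rate <- background_rate * ifelse(truth, enrichment_factor, 1) * lens / 1000
    peaks <- lapply(seq_len(n_datasets), function(d) {
      counts <- stats::rpois(n_utrs, rate)
      rows <- which(counts > 0L)
      if (length(rows) == 0L) {
        return(GenomicRanges::GRanges(seqnames = character(0),
                                      ranges = IRanges::IRanges()))
      }
      pk <- do.call(c, lapply(rows, function(i) {
        w <- sample(20:40, counts[i], replace = TRUE)
        s <- starts[i] + sample.int(max(1L, lens[i] - max(w)), counts[i], replace = TRUE) - 1L
        GenomicRanges::GRanges("chrS", IRanges::IRanges(start = s, width = w),
                               strand = strands[i])
      }))
      S4Vectors::mcols(pk)$name <- sprintf("pk_d%d_%04d", d, seq_along(pk))
      S4Vectors::mcols(pk)$dataset <- sprintf("dataset%d", d)
      pk
    })
    names(peaks) <- sprintf("dataset%d", seq_len(n_datasets))
    list(utrs = utrs, peaks = peaks, truth = truth)
  })
}
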