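#' Read a BED3/BED6 file into a GRanges
#'
#' Parses stranded, 0-based half-open BED intervals with per-line validation:
#' malformed lines are reported with their line numbers. BED3 rows get strand
#' `"*"`; BED6 strand `"."` is mapped to `"*"`.
#'
#' @param path Path to a BED file.
#' @param dataset Label stored in the `dataset` metadata column (defaults to
#'   the file name).
#' @return A `GRanges` with metadata columns `name` and `dataset`.
#' @export
read_bed <- function(path, dataset = basename(path)) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) stop(sprintf("no intervals found in '%s'", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("BED parse error in '%s': fewer than 3 fields at line(s) %s",
                 path, paste(which(nf < 3L), collapse = ", ")))
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0L | start >= end)
  if (length(bad) > 0L) {
    stop(sprintf("BED parse error in '%s': invalid coordinates (need 0 <= start < end) at line(s) %s",
                 path, paste(bad, collapse = ", ")))
  }
  name <- ifelse(nf >= 4L, vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else ".", character(1)),
                 paste0("iv", seq_along(fields)))
  strand <- ifelse(nf >= 6L, vapply(fields, function(f) if (length(f) >= 6L) f[[6L]] else ".", character(1)), ".")
  badstr <- which(!strand %in% c("+", "-", "."))
  if (length(badstr) > 0L) {
    stop(sprintf("BED parse error in '%s': invalid strand at line(s) %s",
                 path, paste(badstr, collapse = ", ")))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),  # BED -> 1-based closed
    strand = ifelse(strand == ".", "*", strand)
  )
  S4Vectors::mcols(gr)$name <- name
  S4Vectors::mcols(gr)$dataset <- dataset
  gr
}

#' Write a GRanges as BED6
#'
#' @param gr A `GRanges` (metadata column `name` used if present).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm)) nm <- paste0("iv", seq_along(gr))
  st <- as.character(BiocGenerics::strand(gr))
  st[st == "*"] <- "."
  lines <- paste(as.character(GenomicRanges::seqnames(gr)),
                 BiocGenerics::start(gr) - 1L, BiocGenerics::end(gr),
                 nm, 0L, st, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Count CLIP peaks falling into 3'UTRs, per dataset and in union
#'
#' A peak "falls into" a UTR when they overlap by at least `min_overlap`
#' base pairs (and lie on the same strand under `strand_mode = "aware"`).
#' Following the union-of-tags convention, the union count per UTR is the
#' maximum across datasets — a tag counted if it was detected in at least
#' one dataset. Alternatively, `union_mode = "merge"` pools all datasets'
#' peaks, merges overlapping ones, and counts merged peaks.
#'
#' @param utrs `GRanges` of 3'UTRs (must carry a `name` metadata column).
#' @param peak_sets List of `GRanges`, one per CLIP dataset; names label the
#'   output columns.
#' @param strand_mode `"aware"` (default; PAR-CLIP is stranded) or `"ignore"`.
#' @param min_overlap Minimum overlap in bp (default 1).
#' @param union_mode `"max"` (default) or `"merge"`.
#' @return data.frame: `utr_name`, one count column per dataset, `union_count`.
#' @export
count_tags <- function(utrs, peak_sets, strand_mode = c("aware", "ignore"),
                       min_overlap = 1L, union_mode = c("max", "merge")) {
  strand_mode <- match.arg(strand_mode)
  union_mode <- match.arg(union_mode)
  if (!is.list(peak_sets)) peak_sets <- list(peaks = peak_sets)
  if (is.null(names(peak_sets)) || any(!nzchar(names(peak_sets)))) {
    names(peak_sets) <- paste0("dataset", seq_along(peak_sets))
  }
  ig <- strand_mode == "ignore"
  counts <- vapply(peak_sets, function(p) {
    GenomicRanges::countOverlaps(utrs, p, minoverlap = min_overlap, ignore.strand = ig)
  }, integer(length(utrs)))
  counts <- matrix(counts, nrow = length(utrs),
                   dimnames = list(NULL, names(peak_sets)))
  union_count <- if (union_mode == "max") {
    apply(counts, 1L, max)
  } else {
    merged <- GenomicRanges::reduce(do.call(c, unname(peak_sets)), ignore.strand = ig)
    GenomicRanges::countOverlaps(utrs, merged, minoverlap = min_overlap, ignore.strand = ig)
  }
  nm <- S4Vectors::mcols(utrs)$name
  if (is.null(nm)) nm <- paste0("utr", seq_along(utrs))
  out <- data.frame(utr_name = nm, counts, union_count = union_count,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Group UTRs into bins by their union CLIP-tag count
#'
#' @param counts data.frame from [count_tags()] (uses `union_count`).
#' @param bins Named list of integer ranges, e.g.
#'   `list("0" = 0, "1-4" = 1:4, ">=5" = c(5, Inf))`; a length-2 vector whose
#'   second element is `Inf` denotes an open-ended bin. Bins must be disjoint
#'   and cover every observed count.
#' @return `counts` with an added factor column `bin`.
#' @export
group_by_count <- function(counts,
                           bins = list("0" = 0, "1-4" = 1:4, ">=5" = c(5, Inf))) {
  expand <- lapply(bins, function(b) {
    if (length(b) == 2L && is.infinite(b[2L])) b else as.integer(b)
  })
  finite <- unlist(expand[!vapply(expand, function(b) any(is.infinite(b)), logical(1))])
  if (anyDuplicated(finite)) stop("bins overlap")
  open <- which(vapply(expand, function(b) any(is.infinite(b)), logical(1)))
  if (length(open) > 1L) stop("at most one open-ended bin is allowed")
  if (length(open) == 1L && any(finite >= expand[[open]][1L])) stop("bins overlap")
  assign_bin <- function(x) {
    for (k in seq_along(expand)) {
      b <- expand[[k]]
      hit <- if (any(is.infinite(b))) x >= b[1L] else x %in% b
      if (hit) return(names(bins)[k])
    }
    NA_character_
  }
  lab <- vapply(counts$union_count, assign_bin, character(1))
  if (anyNA(lab)) {
    stop(sprintf("count(s) %s fall outside every bin",
                 paste(unique(counts$union_count[is.na(lab)]), collapse = ", ")))
  }
  counts$bin <- factor(lab, levels = names(bins))
  counts
}
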