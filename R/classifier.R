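#' Dual NED thresholds for condensate-morphology classification
#'
#' RNAs with NED above `hi` are called network (mesh) formers; below `lo`,
#' sphere formers. The interval `[lo, hi]` is a gap in which the observed
#' cohorts overlap: `gap_rule = "nearest"` assigns a gap value to the closer
#' threshold (the midpoint going to network), while `"indeterminate"` reports
#' an explicit third label.
#'
#' @param hi Upper threshold (default 0.280).
#' @param lo Lower threshold (default 0.265).
#' @param gap_rule `"nearest"` (default) or `"indeterminate"`.
#' @return Object of class `ned_thresholds`.
#' @export
ned_thresholds <- function(hi = 0.280, lo = 0.265,
                           gap_rule = c("nearest", "indeterminate")) {
  gap_rule <- match.arg(gap_rule)
  stopifnot(lo <= hi, lo >= 0)
  structure(list(hi = hi, lo = lo, gap_rule = gap_rule), class = "ned_thresholds")
}

#' @export
print.ned_thresholds <- function(x, ...) {
  cat(sprintf("<ned_thresholds> network if NED > %.3f, sphere if NED < %.3f, gap rule: %s\n",
              x$hi, x$lo, x$gap_rule))
  invisible(x)
}

#' Classify RNAs as sphere- or network-forming by NED
#'
#' @param ned Numeric vector of NED values (>= 0).
#' @param thresholds A [ned_thresholds()] object.
#' @return Character vector over `c("network", "sphere")` (plus
#'   `"indeterminate"` under that gap rule).
#' @examples
#' classify_ned(c(0.30, 0.20, 0.2725))
#' @export
classify_ned <- function(ned, thresholds = ned_thresholds()) {
  stopifnot(all(ned >= 0))
  t <- thresholds
  out <- rep(NA_character_, length(ned))
  out[ned > t$hi] <- "network"
  out[ned < t$lo] <- "sphere"
  gap <- is.na(out)
  if (any(gap)) {
    if (t$gap_rule == "nearest") {
      mid <- (t$lo + t$hi) / 2
      out[gap] <- ifelse(ned[gap] >= mid, "network", "sphere")
    } else {
      out[gap] <- "indeterminate"
    }
  }
  out
}

#' Read a per-RNA source-data table
#'
#' Loads a TSV with one row per tested RNA: gene, cohort (initial /
#' validation), observed morphology (sphere / network), length, ARE count, GC
#' fraction, and NED. Alternative column spellings can be mapped via
#' `col_map` (a named character vector, names = canonical, values = as found
#' in the file).
#'
#' @param path Path to a tab-separated file with a header row.
#' @param col_map Optional named character vector mapping canonical names
#'   (`gene`, `cohort`, `observed`, `length_nt`, `n_are`, `gc_frac`, `ned`)
#'   to the file's column names.
#' @return data.frame with canonical columns; morphology and cohort values
#'   are validated against their closed vocabularies.
#' @export
read_source_data <- function(path, col_map = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  canonical <- c("gene", "cohort", "observed", "length_nt", "n_are", "gc_frac", "ned")
  if (!is.null(col_map)) {
    for (k in names(col_map)) {
      if (col_map[[k]] %in% names(df)) names(df)[names(df) == col_map[[k]]] <- k
    }
  }
  missing <- setdiff(canonical, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("source-data table lacks required column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  df <- df[canonical]
  bad <- setdiff(unique(df$observed), c("sphere", "network"))
  if (length(bad) > 0L) stop(sprintf("unknown morphology label(s): %s", paste(bad, collapse = ", ")))
  bad <- setdiff(unique(df$cohort), c("initial", "validation"))
  if (length(bad) > 0L) stop(sprintf("unknown cohort label(s): %s", paste(bad, collapse = ", ")))
  if (any(df$ned < 0)) stop("NED values must be non-negative")
  df
}

#' Evaluate NED-based morphology predictions against observations
#'
#' @param records data.frame with at least `observed` and `ned` columns
#'   (see [read_source_data()]).
#' @param thresholds A [ned_thresholds()] object. Under
#'   `gap_rule = "indeterminate"`, indeterminate predictions count as
#'   incorrect.
#' @return List with `confusion` (observed x predicted table), `n_correct`,
#'   `n_total` and `accuracy`.
#' @export
evaluate_predictions <- function(records, thresholds = ned_thresholds()) {
  if (is.null(records) || nrow(records) == 0L) stop("no records to evaluate")
  pred <- classify_ned(records$ned, thresholds)
  correct <- pred == records$observed
  list(
    confusion = table(observed = records$observed, predicted = pred),
    n_correct = sum(correct),
    n_total = nrow(records),
    accuracy = mean(correct)
  )
}

#' Fraction of a morphology group beyond a NED cut-off
#'
#' For example: the fraction of network-forming RNAs with NED strictly above
#' 0.28, or of sphere-forming RNAs strictly below 0.265.
#'
#' @param records data.frame with `observed` and `ned` columns.
#' @param group `"sphere"` or `"network"`.
#' @param cut NED cut-off.
#' @param side `"above"` or `"below"` (strict inequality).
#' @return Fraction in `[0, 1]`.
#' @export
quartile_check <- function(records, group = c("network", "sphere"), cut,
                           side = c("above", "below")) {
  group <- match.arg(group)
  side <- match.arg(side)
  x <- records$ned[records$observed == group]
  if (length(x) == 0L) stop(sprintf("no records observed as '%s'", group))
  if (side == "above") mean(x > cut) else mean(x < cut)
}
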