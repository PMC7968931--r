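# Shared fixtures, built in code at test time.

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# RT at the default temperature, used in hand-computed Boltzmann expectations
RT_DEFAULT <- 0.0019872 * 310.15

# small GRanges builders for interval tests
gr <- function(chrom, start0, end0, strand = "*", name = NULL) {
  g <- GenomicRanges::GRanges(chrom,
                              IRanges::IRanges(start = start0 + 1L, end = end0),
                              strand = strand)
  if (!is.null(name)) S4Vectors::mcols(g)$name <- name
  g
}

# deterministic synthetic stand-in for a per-RNA source-data table; the
# expected statistics for it are recomputed independently inside the tests
synthetic_source_data <- function() {
  set.seed(4711)
  n_s <- 19L; n_n <- 28L
  df <- rbind(
    data.frame(gene = sprintf("S%02d", seq_len(n_s)), cohort = "initial",
               observed = "sphere",
               length_nt = round(exp(rnorm(n_s, log(1100), 0.4))),
               n_are = rpois(n_s, 5), gc_frac = round(runif(n_s, 0.3, 0.5), 3),
               ned = round(pmin(0.99, pmax(0, rnorm(n_s, 0.245, 0.025))), 4)),
    data.frame(gene = sprintf("N%02d", seq_len(n_n)), cohort = "initial",
               observed = "network",
               length_nt = round(exp(rnorm(n_n, log(1900), 0.4))),
               n_are = rpois(n_n, 7), gc_frac = round(runif(n_n, 0.25, 0.45), 3),
               ned = round(pmin(0.99, pmax(0, rnorm(n_n, 0.305, 0.025))), 4))
  )
  # a validation cohort drawn around the same group centres
  val <- rbind(
    data.frame(gene = sprintf("VS%02d", 1:10), cohort = "validation",
               observed = "sphere",
               length_nt = round(exp(rnorm(10, log(1200), 0.4))),
               n_are = rpois(10, 5), gc_frac = round(runif(10, 0.3, 0.5), 3),
               ned = round(pmin(0.99, pmax(0, rnorm(10, 0.25, 0.03))), 4)),
    data.frame(gene = sprintf("VN%02d", 1:14), cohort = "validation",
               observed = "network",
               length_nt = round(exp(rnorm(14, log(1700), 0.4))),
               n_are = rpois(14, 7), gc_frac = round(runif(14, 0.25, 0.45), 3),
               ned = round(pmin(0.99, pmax(0, rnorm(14, 0.31, 0.03))), 4))
  )
  rbind(df, val)
}
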