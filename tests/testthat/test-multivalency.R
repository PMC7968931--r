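test_that("element partnerships must be symmetric", {
  expect_s3_class(dimer_elements("D2", "D2"), "dimer_elements")
  expect_s3_class(dimer_elements(c("D1a", "D1b"), c("D1b", "D1a")), "dimer_elements")
  expect_error(dimer_elements(c("A", "B"), c("B", "C")), "symmetric")
  expect_error(dimer_elements("A", "B"), "symmetric")
})

test_that("single-site homotypic constructs can only dimerise", {
  el <- dimer_elements("D", "D")
  res <- match_sites(list(mono = "D"), c(mono = 10L), el, seed = 3)
  expect_equal(res$component_sizes, rep(2L, 5))
  expect_equal(res$largest, 2L)
  st <- component_stats(res)
  expect_equal(unname(st$histogram["2"]), 5L)
  expect_equal(st$n_molecules, 10L)
})

test_that("zero-site constructs stay singletons and undeclared elements fail", {
  el <- dimer_elements("D", "D")
  res <- match_sites(list(core = character(0)), c(core = 10L), el, seed = 1)
  expect_equal(res$component_sizes, rep(1L, 10))
  expect_equal(nrow(res$edges), 0L)
  expect_error(match_sites(list(x = "E"), c(x = 5L), el, seed = 1), "undeclared")
})

test_that("molecule count is conserved and valency-1 pools never exceed dimers", {
  el <- dimer_elements(c("D1a", "D1b", "D2"), c("D1b", "D1a", "D2"))
  set.seed(8)
  for (k in 1:5) {
    pools <- list(
      list(constructs = list(a = "D1a", b = "D1b", c = "D2", none = character(0)),
           copies = c(a = sample(5:30, 1), b = sample(5:30, 1),
                      c = sample(5:30, 1), none = sample(1:10, 1))),
      list(constructs = list(x = c("D1a", "D2"), y = c("D1b", "D2")),
           copies = c(x = sample(20:60, 1), y = sample(20:60, 1)))
    )
    for (p in seq_along(pools)) {
      res <- match_sites(pools[[p]]$constructs, pools[[p]]$copies, el, seed = k)
      expect_equal(sum(res$component_sizes), sum(pools[[p]]$copies))
      if (p == 1) expect_lte(res$largest, 2L)   # every construct has <= 1 site
    }
  }
})

test_that("two-site circuits percolate where one-site pools form only dimers", {
  el <- dimer_elements(c("D1a", "D1b", "D2"), c("D1b", "D1a", "D2"))
  frac <- vapply(1:20, function(s) {
    match_sites(list(A = c("D1a", "D2"), B = c("D1b", "D2")),
                c(A = 500L, B = 500L), el, seed = s)$fraction_in_largest
  }, numeric(1))
  expect_gt(median(frac), 0.5)
  largest1 <- vapply(1:20, function(s) {
    match_sites(list(A = "D1a", B = "D1b"), c(A = 500L, B = 500L),
                el, seed = s)$largest
  }, numeric(1))
  expect_true(all(largest1 <= 2))
  expect_gt(median(frac) * 1000, max(largest1) * 10)  # clear contrast
})

test_that("matching is deterministic given the seed", {
  el <- dimer_elements(c("D1a", "D1b", "D2"), c("D1b", "D1a", "D2"))
  pool <- list(A = c("D1a", "D2"), B = c("D1b", "D2"))
  cp <- c(A = 50L, B = 50L)
  r1 <- match_sites(pool, cp, el, seed = 42)
  r2 <- match_sites(pool, cp, el, seed = 42)
  expect_identical(r1$edges, r2$edges)
  expect_identical(r1$component_sizes, r2$component_sizes)
  r3 <- match_sites(pool, cp, el, seed = 43)
  expect_false(identical(r1$edges, r3$edges))
})

test_that("every site is matched at most once, to a compatible partner", {
  el <- dimer_elements(c("D1a", "D1b", "D2"), c("D1b", "D1a", "D2"))
  res <- match_sites(list(A = c("D1a", "D2"), B = c("D1b", "D2")),
                     c(A = 40L, B = 40L), el, seed = 9)
  expect_true(all(res$edges$mol_a != res$edges$mol_b))
  ok_pair <- function(a, b) {
    p <- el$partner[match(a, el$name)]
    p == b
  }
  expect_true(all(mapply(ok_pair, res$edges$element_a, res$edges$element_b)))
  # per element class, a molecule's single site of that class is used <= once
  for (elname in el$name) {
    use <- c(res$edges$mol_a[res$edges$element_a == elname],
             res$edges$mol_b[res$edges$element_b == elname])
    expect_false(anyDuplicated(use) > 0)
  }
})

test_that("duplex scan finds the minimum-energy antiparallel run", {
  m <- energy_model("pairsum")
  d <- duplex_scan("GGGG", "CCCC", m, min_len = 4)
  expect_equal(d$length, 4L)
  expect_equal(d$energy, -12)
  expect_equal(d$start_a, 0L)
  expect_equal(d$start_b, 0L)
  expect_null(duplex_scan("AAAA", "AAAA", m, min_len = 2))
  # a sequence against its reverse complement pairs full length
  set.seed(21)
  for (k in 1:5) {
    a <- random_rna(30)
    d <- duplex_scan(a, reverse_complement(a), m, min_len = 30)
    expect_equal(d$length, 30L)
    expect_equal(d$start_a, 0L)
    expect_equal(d$start_b, 0L)
  }
  # shorter runs are rejected by min_len
  expect_null(duplex_scan("GGAA", "AACC", m, min_len = 3))
})

test_that("pool and element TSV readers reconstruct the inputs", {
  ptsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("construct\tsites\tcopies", "A\tD1a,D2\t100", "core\t\t5"), ptsv)
  pool <- read_pool_tsv(ptsv)
  expect_equal(pool$constructs$A, c("D1a", "D2"))
  expect_equal(pool$constructs$core, character(0))
  expect_equal(unname(pool$copies["A"]), 100L)
  etsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tpartner", "D1a\tD1b", "D1b\tD1a", "D2\tD2"), etsv)
  el <- read_elements_tsv(etsv)
  expect_s3_class(el, "dimer_elements")
  expect_equal(nrow(el), 3L)
})
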