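test_that("hairpin generator builds stem-loop-antistem sequences deterministically", {
  h <- gen_hairpin(4, 3, gc_frac = 1, seed = 1)
  expect_equal(h$n, 11L)
  mf <- mfe_fold(h, energy_model("pairsum"))
  expect_equal(nrow(mf$structure$pairs), 4L)   # the full stem forms
  # stem 0: a pure loop with no pairs
  h0 <- gen_hairpin(0, 5, seed = 1)
  expect_equal(h0$residues, "AAAAA")
  # determinism
  expect_identical(gen_hairpin(10, 4, 0.8, seed = 7)$residues,
                   gen_hairpin(10, 4, 0.8, seed = 7)$residues)
  expect_false(identical(gen_hairpin(10, 4, 0.8, seed = 7)$residues,
                         gen_hairpin(10, 4, 0.8, seed = 8)$residues))
})

test_that("unstructured generator honours the AU fraction", {
  u <- gen_unstructured(300, au_frac = 1, seed = 2)
  expect_true(all(strsplit(u$residues, "")[[1]] %in% c("A", "U")))
  set.seed(0)
  for (au in c(0.5, 0.8)) {
    g <- gc_content(gen_unstructured(400, au, seed = sample.int(1e6, 1)))
    expect_lt(abs(g - (1 - au)), 0.1)
  }
  expect_identical(gen_unstructured(100, 0.8, seed = 3)$residues,
                   gen_unstructured(100, 0.8, seed = 3)$residues)
})

test_that("hairpins have lower NED than length-matched AU-rich sequences", {
  m <- energy_model("stacking")
  ned_hp <- vapply(1:20, function(s) ned(gen_hairpin(98, 4, 1, seed = s), m), numeric(1))
  ned_au <- vapply(1:20, function(s) ned(gen_unstructured(200, 0.8, seed = s), m), numeric(1))
  expect_lt(median(ned_hp), median(ned_au))
  expect_lt(median(ned_hp), 0.05)
  expect_gt(median(ned_au), 0.1)
})

test_that("antisense insertion preserves AREs and length bookkeeping", {
  u <- gen_unstructured(200, 0.7, seed = 11)
  plan <- plan_antisense_insertion(u, insert_len = 15, copies = 2)
  mut <- insert_antisense(u, plan$donor_start, plan$insert_pos, 15, 2)
  expect_equal(mut$n, u$n + 30L)
  expect_equal(count_ares(mut), count_ares(u))
  # insert_len 0 is the identity
  expect_identical(insert_antisense(u, 0, 50, insert_len = 0)$residues, u$residues)
  # out-of-bounds donors and upstream insertion points are rejected
  expect_error(insert_antisense(u, 190, 199, 15, 2), "out of bounds")
  expect_error(insert_antisense(u, 10, 5, 15, 1), "downstream")
})

test_that("splitting an ARE with an insertion raises a positional error", {
  s <- rna_sequence(paste0(strrep("C", 40), "AUUUA", strrep("C", 40)), "x")
  # inserting into the middle of the AUUUA (positions 40-44) must fail;
  # donor window chosen from the leading C-run so the insert is all G
  expect_error(insert_antisense(s, 0, 42, insert_len = 15, copies = 1), "split")
  # inserting right after it is fine
  mut <- insert_antisense(s, 0, 50, insert_len = 15, copies = 1)
  expect_equal(count_ares(mut), 1L)
})

test_that("antisense insertion lowers the NED of unstructured sequences", {
  m <- energy_model("stacking")
  deltas <- vapply(1:20, function(s) {
    u <- gen_unstructured(150, 0.7, seed = 100 + s)
    plan <- tryCatch(plan_antisense_insertion(u, 15, 2), error = function(e) NULL)
    if (is.null(plan)) return(NA_real_)
    mut <- insert_antisense(u, plan$donor_start, plan$insert_pos, 15, 2)
    ned(mut, m) - ned(u, m)
  }, numeric(1))
  deltas <- deltas[!is.na(deltas)]
  expect_gte(length(deltas), 15)
  expect_lt(median(deltas), 0)
})

test_that("synthetic cohorts have the requested shape and moments", {
  spec <- cohort_spec(seed = 5)
  tab <- gen_cohort(spec)
  expect_equal(nrow(tab), 47L)                    # 19 + 28
  expect_equal(sum(tab$observed == "sphere"), 19L)
  expect_equal(sum(tab$observed == "network"), 28L)
  expect_true(all(tab$ned >= 0 & tab$ned <= 1))
  expect_true(all(tab$n_are >= 0))
  expect_identical(gen_cohort(spec), gen_cohort(spec))
  # moments at large n match the requested parameters within a few SEs
  big <- cohort_spec(n_sphere = 1000L, n_network = 1000L, seed = 99L)
  bt <- gen_cohort(big)
  expect_equal(mean(bt$ned[bt$observed == "sphere"]), 0.24, tolerance = 0.01)
  expect_equal(mean(bt$ned[bt$observed == "network"]), 0.31, tolerance = 0.01)
  expect_equal(mean(log(bt$length_nt[bt$observed == "sphere"])), log(1200),
               tolerance = 0.05)
  are_rate <- sum(bt$n_are) / sum(bt$length_nt) * 1000
  expect_equal(are_rate, 5, tolerance = 0.25)
})

test_that("CLIP track generator is seed-deterministic down to the written bytes", {
  t1 <- gen_clip_tracks(n_utrs = 20, seed = 9)
  t2 <- gen_clip_tracks(n_utrs = 20, seed = 9)
  f1 <- withr::local_tempfile(fileext = ".bed")
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(t1$peaks[[1]], f1); write_bed(t2$peaks[[1]], f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(t1$truth, t2$truth)
})

test_that("enrichment is recovered in the top count bin, and absent under the null", {
  tr <- gen_clip_tracks(n_utrs = 120, enriched_fraction = 0.2,
                        enrichment_factor = 10, seed = 4)
  counts <- group_by_count(count_tags(tr$utrs, tr$peaks))
  top <- counts$bin == ">=5"
  precision <- mean(tr$truth[top])
  expect_gt(precision, 0.8)
  # null construction: no difference in mean union counts
  nul <- gen_clip_tracks(n_utrs = 200, background_rate = 2,
                         enriched_fraction = 0.5, enrichment_factor = 1, seed = 6)
  cts <- count_tags(nul$utrs, nul$peaks)
  a <- cts$union_count[nul$truth]; b <- cts$union_count[!nul$truth]
  pooled_se <- sqrt(var(a) / length(a) + var(b) / length(b))
  expect_lt(abs(mean(a) - mean(b)), 2 * pooled_se + 1e-9)
})
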