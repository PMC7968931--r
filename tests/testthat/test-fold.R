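test_that("partition sum matches hand-computed Boltzmann weights", {
  m <- energy_model("pairsum")
  expect_equal(partition_function("AAAAA", m)$Zq, 1.0, tolerance = 1e-12)
  # GAAAC: open chain + one GC pair at -3 kcal/mol
  z <- partition_function("GAAAC", m)$Zq
  expect_equal(z, 1 + exp(3 / RT_DEFAULT), tolerance = 1e-9)
  expect_gt(z, 1)   # open chain always contributes weight 1
})

test_that("pair probabilities reproduce the two-structure ensemble of GAAAC", {
  m <- energy_model("pairsum")
  p <- pair_probabilities("GAAAC", m)
  w <- exp(3 / RT_DEFAULT)
  expect_equal(p[1, 5], w / (1 + w), tolerance = 1e-9)
  expect_equal(p[1, 5], p[5, 1])
  expect_equal(sum(p) - 2 * p[1, 5], 0)
  # all-A sequence: nothing can pair
  expect_true(all(pair_probabilities("AAAAA", m) == 0))
})

test_that("engine agrees with exhaustive enumeration on random short sequences", {
  # the oracle-equivalence contract: Zq, every p_ij, MFE energy and ensemble
  # diversity to 1e-9 relative tolerance, under both energy models
  set.seed(20240601)
  for (k in 1:25) {
    n <- sample(5:18, 1)
    s <- rna_sequence(random_rna(n))
    for (kind in c("pairsum", "stacking")) {
      m <- energy_model(kind)
      or <- enumerate_ensemble(s, m)
      expect_equal(partition_function(s, m)$Zq, or$Zq, tolerance = 1e-9)
      bp <- pair_probabilities(s, m)
      expect_lt(max(abs(bp - or$bppm)), 1e-9)
      mf <- mfe_fold(s, m)
      expect_equal(mf$energy, or$mfe_energy, tolerance = 1e-9)
      expect_equal(ensemble_diversity(bp), or$diversity,
                   tolerance = 1e-9 + 1e-12 / max(or$diversity, 1e-12))
      # the traceback structure must achieve the reported MFE
      expect_equal(structure_energy(s, mf$structure, m), mf$energy, tolerance = 1e-9)
    }
  }
})

test_that("MFE fold finds the minimum and reports a deterministic structure", {
  m <- energy_model("pairsum")
  expect_equal(mfe_fold("AAAAA", m)$energy, 0)
  expect_equal(structure_to_dotbracket(mfe_fold("AAAAA", m)$structure), ".....")
  gaaac <- mfe_fold("GAAAC", m)
  expect_equal(gaaac$energy, -3.0)
  expect_equal(structure_to_dotbracket(gaaac$structure), "(...)")
  expect_equal(mfe_fold("GGGAAAACCC", m)$energy, 3 * (-3.0))
  # repeated calls give identical structures
  a <- mfe_fold("GGGAAAACCC", energy_model("stacking"))
  b <- mfe_fold("GGGAAAACCC", energy_model("stacking"))
  expect_identical(a$structure$pairs, b$structure$pairs)
})

test_that("bppm invariants hold on random sequences", {
  set.seed(99)
  for (kind in c("pairsum", "stacking")) {
    m <- energy_model(kind)
    for (k in 1:5) {
      s <- rna_sequence(random_rna(sample(20:60, 1)))
      p <- pair_probabilities(s, m)
      expect_true(all(p >= 0 & p <= 1))
      expect_equal(p, t(p))
      expect_true(all(rowSums(p) <= 1 + 1e-9))
      # near-diagonal band is structurally zero
      for (d in 0:m$min_hairpin) {
        expect_true(all(abs(p[col(p) - row(p) == d]) == 0))
      }
      q <- unpaired_profile(p)
      expect_true(all(q >= 0 & q <= 1))
      expect_equal(unname(q + rowSums(p)), rep(1, s$n), tolerance = 1e-12)
    }
  }
})

test_that("pairing probability decreases with temperature (Boltzmann behaviour)", {
  temps <- c(290, 310.15, 330, 360)
  p04 <- vapply(temps, function(Tk) {
    pair_probabilities("GAAAC", energy_model("pairsum", temperature = Tk))[1, 5]
  }, numeric(1))
  expect_true(all(diff(p04) < 0))
})

test_that("centroid keeps exactly the pairs above probability one half", {
  expect_equal(nrow(centroid_structure(matrix(0, 8, 8))$pairs), 0L)
  p <- matrix(0, 10, 10)
  p[1, 10] <- p[10, 1] <- 0.6
  p[2, 9] <- p[9, 2] <- 0.7
  p[3, 8] <- p[8, 3] <- 0.49
  ct <- centroid_structure(p)
  expect_equal(ct$pairs, matrix(c(0L, 1L, 9L, 8L), ncol = 2,
                                dimnames = list(NULL, c("i", "j"))))
  # GAAAC has its single pair at p ~ 0.992
  ct <- centroid_structure(pair_probabilities("GAAAC", energy_model("pairsum")))
  expect_equal(structure_to_dotbracket(ct), "(...)")
})

test_that("ensemble diversity follows the closed form and NED divides by length", {
  expect_equal(ensemble_diversity(matrix(0, 6, 6)), 0)
  p <- matrix(0, 8, 8); p[1, 8] <- p[8, 1] <- 0.5
  expect_equal(ensemble_diversity(p), 0.5)
  m <- energy_model("pairsum")
  w <- exp(3 / RT_DEFAULT)
  pr <- w / (1 + w)
  expect_equal(ned("GAAAC", m), 2 * pr * (1 - pr) / 5, tolerance = 1e-9)
  expect_equal(ned("AAAAA", m), 0)
})

test_that("NED stays in [0, 1] and long sequences are refused", {
  set.seed(3)
  for (k in 1:5) {
    x <- ned(random_rna(sample(10:80, 1)), energy_model("stacking"))
    expect_gte(x, 0); expect_lte(x, 1)
  }
  m <- energy_model("stacking", max_length = 100L)
  expect_error(ned(random_rna(101), m), "folding limit")
  expect_error(fold_ensemble(random_rna(101), m), "folding limit")
})

test_that("LDR calls are maximal runs above tau of sufficient length", {
  calls <- find_ldrs(c(rep(0.9, 40), rep(0.1, 10)), tau = 0.5, min_ldr_length = 30)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, 0L)
  expect_equal(calls$end, 40L)
  expect_equal(calls$mean_unpaired, 0.9)
  expect_equal(nrow(find_ldrs(rep(0.1, 100))), 0L)
  expect_equal(nrow(find_ldrs(rep(0.9, 10))), 0L)       # run too short
  # two separated runs, sorted and non-overlapping
  q <- c(rep(0.8, 35), rep(0.2, 5), rep(0.95, 31))
  calls <- find_ldrs(q)
  expect_equal(calls$start, c(0L, 40L))
  expect_equal(calls$end, c(35L, 71L))
  expect_true(all(calls$end[-nrow(calls)] <= calls$start[-1]))
})

test_that("fold_ensemble bundles consistent components", {
  fe <- fold_ensemble("GGGAAAACCC", energy_model("stacking"))
  expect_s3_class(fe, "rna_ensemble")
  expect_equal(fe$ned, fe$ensemble_diversity / fe$n)
  expect_equal(fe$Zq, exp(fe$log_Zq))
  expect_equal(fe$ensemble_free_energy, -fe$model$RT * fe$log_Zq)
  expect_lte(fe$mfe_energy, 0)
  sm <- summary(fe)
  expect_named(sm, c("id", "length", "mfe_kcal_mol", "ensemble_free_energy",
                     "ensemble_diversity", "ned", "n_ldrs"))
})
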