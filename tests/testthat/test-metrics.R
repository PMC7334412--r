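test_that("subset_frequency does the arithmetic and flags empty
          parents", {
  parent <- rep(c(TRUE, FALSE), c(12, 4))
  sub <- rep(c(TRUE, FALSE), c(3, 13))
  expect_equal(subset_frequency(sub, parent), 25)
  expect_equal(subset_frequency(parent, parent), 100)
  expect_true(is.na(subset_frequency(logical(16), logical(16))))
  expect_error(subset_frequency(c(TRUE, TRUE), c(TRUE, FALSE)),
               "subset")
})

test_that("pct_positive counts threshold crossings and honours Eomes
          truth labels", {
  truth <- data.frame(population = rep("NK_neg_CD16pos", 10),
                      eomes_truth = rep(c(1L, 0L), c(7, 3)))
  x <- make_table(list(
    `FSC-A` = rep(5e4, 10),
    CD16 = raw(c(rep(3, 8), rep(0, 2))),
    Eomes = raw(rep(c(3, 0), c(5, 5)))),
    panel = tiny_panel(c("FSC-A", "CD16", "Eomes")), truth = truth)
  th <- manual_thresholds(list(CD16 = 1.5, Eomes = 1.5))
  all10 <- rep(TRUE, 10)
  expect_equal(pct_positive(x, all10, "CD16", th), 80)
  expect_equal(pct_positive(x, all10, "Eomes", th), 70)  # truth-based
  expect_equal(pct_positive(x, all10, "Eomes", th,
                            eomes_from = "intensity"), 50)
  expect_true(is.na(pct_positive(x, rep(FALSE, 10), "CD16", th)))
})

test_that("mfi is the raw-scale median and flags empty subsets", {
  x <- make_table(list(`FSC-A` = rep(1, 3), CD16 = c(1, 2, 3)),
                  panel = tiny_panel(c("FSC-A", "CD16")))
  expect_equal(mfi(x, rep(TRUE, 3), "CD16"), 2)
  expect_true(is.na(mfi(x, rep(FALSE, 3), "CD16")))
})

test_that("donor tables have the documented schema, cardinality and
          byte-stable serialisation", {
  cohort <- build_cohort(cohort_config("HD", n_donors = 2,
                                       n_events = 5000, seed = 3))
  strategies <- list(cd16 = get_strategy("cd16"),
                     nkp80 = get_strategy("nkp80"))
  an <- analyze_cohort(cohort, strategies = strategies,
                       treatments = character(0))
  tab <- donor_table(an)
  # 2 donors x 2 strategies x 2 subsets each
  expect_identical(nrow(tab), 8L)
  expect_identical(
    names(tab),
    c("donor_id", "condition", "treatment", "strategy", "subset",
      "n_events", "freq_of_parent", "freq_of_nk", "pct_eomes_pos",
      "pct_cd123_pos", "mfi_CD16", "mfi_NKp80", "fsc_median",
      "pct_CD107a", "pct_IFNg", "pct_TNF"))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_donor_table(tab, f1)
  write_donor_table(tab, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("statistics are invariant under event-row permutation", {
  x <- sample_donor(donor_config("perm", n_events = 5000, seed = 9))
  th <- estimate_panel_thresholds(x)
  set.seed(1)
  xp <- subset_events(x, sample.int(n_events(x)))
  s1 <- subset_stats(x, th, list(nkp80 = get_strategy("nkp80")))
  s2 <- subset_stats(xp, th, list(nkp80 = get_strategy("nkp80")))
  num <- vapply(s1, is.numeric, TRUE)
  expect_equal(s1[, num], s2[, num], tolerance = 1e-12)
})

test_that("quadrant frequencies of the CD56neg parent sum to 100", {
  x <- sample_donor(donor_config("quad", n_events = 20000, seed = 13))
  th <- estimate_panel_thresholds(x)
  s <- subset_stats(x, th, list(quadrants = get_strategy("quadrants")))
  quads <- s$subset != "CD56neg"
  expect_equal(sum(s$freq_of_parent[quads]), 100, tolerance = 1e-9)
})

test_that("Eomes purity from truth labels agrees with the intensity
          cutoff within 3 points", {
  x <- sample_donor(donor_config("eo", n_events = 50000, seed = 19))
  th <- estimate_panel_thresholds(x)
  mem <- apply_strategy(x, get_strategy("nkp80"), th)$target
  a <- pct_positive(x, mem, "Eomes", th)
  b <- pct_positive(x, mem, "Eomes", th, eomes_from = "intensity")
  expect_lt(abs(a - b), 3)
})
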