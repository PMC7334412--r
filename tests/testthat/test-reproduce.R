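# Small studies keep these structural tests fast; the full-scale
# scientific assertions live in the acceptance suite.
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- run_study(seed = 11, n_donors = 4, n_events = 4000)
    }
    cache
  }
})

test_that("unknown figure ids and missing conditions are informative
          errors", {
  expect_error(reproduce("9Z", small_study()), "unknown figure id")
  hd_only <- run_study(seed = 5, n_donors = 3, n_events = 2000,
                       conditions = "HD", treatments = character(0))
  expect_error(reproduce("4A", hd_only), "missing required condition")
  expect_error(reproduce("5B", hd_only), "missing required perturbation")
})

test_that("figure output is deterministic given the study seed", {
  s1 <- run_study(seed = 19, n_donors = 3, n_events = 3000,
                  conditions = "HD", treatments = "stim_K562")
  s2 <- run_study(seed = 19, n_donors = 3, n_events = 3000,
                  conditions = "HD", treatments = "stim_K562")
  f1 <- reproduce("1A", s1)
  f2 <- reproduce("1A", s2)
  expect_identical(f1$per_donor, f2$per_donor)
  expect_identical(f1$summary, f2$summary)
})

test_that("every supported figure id renders a table, summary and
          plottable output", {
  study <- small_study()
  out <- withr::local_tempdir()
  for (id in c("1A", "1B", "1C", "1D", "2A", "2B", "2C", "3A", "3B",
               "3C", "3D", "4A", "4B", "4C", "5B", "6A", "6B",
               "S1-cryo", "S-dim-vs-neg")) {
    fig <- reproduce(id, study, out_dir = out)
    expect_s3_class(fig, "nk_figure")
    expect_gt(nrow(fig$per_donor), 0)
    expect_true(all(c("group", "n", "mean", "sem", "median")
                    %in% names(fig$summary)))
    base <- paste0("fig_", gsub("[^A-Za-z0-9]", "_", id))
    expect_true(file.exists(file.path(out, paste0(base,
                                                  "_per_donor.csv"))))
    expect_true(file.exists(file.path(out, paste0(base, ".png"))))
  }
  # comparisons always state the test used
  fig <- reproduce("1A", study)
  expect_true(all(vapply(fig$comparisons, `[[`, "", "test") %in%
                    c("wilcoxon_signed_rank", "mann_whitney_u")))
})

test_that("run_report writes an index of assertion outcomes", {
  out <- withr::local_tempdir()
  idx <- run_report(small_study(), figure_ids = c("1A", "2A"),
                    out_dir = out)
  expect_true(file.exists(file.path(out, "index.csv")))
  expect_setequal(unique(idx$figure_id), c("1A", "2A"))
  expect_true(is.logical(idx$pass))
})

test_that("summary legends are honoured: mean/SEM for purity panels,
          median for functional panels", {
  study <- small_study()
  expect_identical(reproduce("1A", study)$summary_stat, "mean_sem")
  expect_identical(reproduce("6B", study)$summary_stat, "median")
  expect_identical(reproduce("1B", study)$summary_stat, "median")
})
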