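hd_donor <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- sample_donor(donor_config("pert", n_events = 20000,
                                          seed = 31))
    }
    cache
  }
})

test_that("the identity perturbation returns the input unchanged", {
  x <- hd_donor()
  spec <- perturbation_spec("stim_K562", mfi_scale = c(CD16 = 1),
                            shed_fraction = 0,
                            response_induction = FALSE)
  y <- apply_perturbation(x, spec, preset_population_specs("HD"),
                          seed = 5)
  expect_identical(y$exprs, x$exprs)
  expect_identical(y$truth, x$truth)
})

test_that("mfi_scale rescales the raw-scale median exactly when nothing
          is shed", {
  x <- hd_donor()
  spec <- perturbation_spec("stim_K562", mfi_scale = c(CD16 = 0.5),
                            shed_fraction = 0,
                            response_induction = FALSE)
  y <- apply_perturbation(x, spec, preset_population_specs("HD"),
                          seed = 5)
  m <- rep(TRUE, n_events(x))
  expect_equal(mfi(y, m, "CD16") / mfi(x, m, "CD16"), 0.5,
               tolerance = 1e-12)
  expect_identical(marker_values(y, "NKp80"), marker_values(x, "NKp80"))
})

test_that("cryopreservation lowers CD16 but leaves NKp80 untouched", {
  x <- hd_donor()
  pops <- preset_population_specs("HD")
  y <- apply_perturbation(x, default_perturbation("cryopreservation"),
                          pops, seed = 8)
  m <- rep(TRUE, n_events(x))
  expect_identical(mfi(y, m, "NKp80"), mfi(x, m, "NKp80"))
  expect_lt(mfi(y, m, "CD16"), mfi(x, m, "CD16"))
  # conservation: event count and truth labels exact
  expect_identical(n_events(y), n_events(x))
  expect_identical(y$truth, x$truth)
})

test_that("perturbations are deterministic given a seed", {
  x <- hd_donor()
  pops <- preset_population_specs("HD")
  spec <- default_perturbation("stim_K562")
  y1 <- apply_perturbation(x, spec, pops, seed = 12)
  y2 <- apply_perturbation(x, spec, pops, seed = 12)
  y3 <- apply_perturbation(x, spec, pops, seed = 13)
  expect_identical(y1$exprs, y2$exprs)
  expect_false(identical(y1$exprs, y3$exprs))
})

test_that("stimulation induces responses and degranulating cells shed
          CD16 preferentially", {
  x <- hd_donor()
  pops <- preset_population_specs("HD")
  y <- apply_perturbation(x, default_perturbation("stim_K562"), pops,
                          seed = 21)
  dim_rows <- x$truth$population == "NK_dim_CD16pos"
  cutoff <- 1.5
  cd107 <- asinh_transform(marker_values(y, "CD107a")) > cutoff
  cd16_neg <- asinh_transform(marker_values(y, "CD16")) < cutoff
  # responders were induced at roughly the configured rate
  expect_gt(mean(cd107[dim_rows]), 0.3)
  expect_lt(mean(cd107[dim_rows]), 0.6)
  # CD107a+ events shed more often than CD107a- events
  shed_resp <- mean(cd16_neg[dim_rows & cd107])
  shed_nonresp <- mean(cd16_neg[dim_rows & !cd107])
  expect_gt(shed_resp, shed_nonresp + 0.2)
})

test_that("unknown mfi_scale markers and label-free tables are
          rejected", {
  x <- hd_donor()
  pops <- preset_population_specs("HD")
  bad <- perturbation_spec("stim_K562", mfi_scale = c(CD999 = 0.5))
  expect_error(apply_perturbation(x, bad, pops), "CD999")
  x$truth <- NULL
  expect_error(
    apply_perturbation(x, default_perturbation("stim_K562"), pops),
    "truth")
})
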