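test_that("a forced zero-event draw yields an empty table with metadata", {
  dc <- donor_config("d0", n_events = 1, seed = 1)
  dc$n_events <- 0L
  x <- sample_donor(dc)
  expect_s3_class(x, "event_table")
  expect_identical(n_events(x), 0L)
  expect_identical(x$panel, default_panel())
  expect_identical(nrow(x$truth), 0L)
})

test_that("single-population draws match direct sampling of the stated
          distributions", {
  pops <- hd_population_specs()
  solo <- pops["NK_dim_CD16pos"]
  solo[[1]]$abundance <- 1
  dc <- donor_config("solo", n_events = 1000, seed = 7,
                     abundance_jitter = Inf)
  x <- sample_donor(dc, solo)
  expect_true(all(x$truth$population == "NK_dim_CD16pos"))
  expect_identical(n_events(x), 1000L)

  # oracle: direct sampling from the declared state Gaussian
  sp <- default_state_params()
  set.seed(991)
  for (m in c("CD56", "CD16", "NKp80", "CD3")) {
    st <- marker_state(solo[[1]], m)
    i <- match(st, sp$state)
    oracle <- stats::rnorm(2e5, sp$location[i], sp$scale[i])
    med <- stats::median(marker_values(x, m, transformed = TRUE))
    # 3 x asymptotic SEM of a Gaussian median at n = 1000
    sem <- 1.2533 * sp$scale[i] / sqrt(1000)
    expect_lt(abs(med - stats::median(oracle)), 3 * sem)
  }
})

test_that("NK cells are 5-15% of viable lymphocytes in a default HD
          donor", {
  dc <- donor_config("hd", n_events = 50000, seed = 42)
  x <- sample_donor(dc)
  pops <- preset_population_specs("HD")
  lymph <- names(pops)[vapply(pops, function(p) p$lineage == "lymphoid",
                              TRUE)]
  nk <- names(pops)[vapply(pops, `[[`, TRUE, "is_nk")]
  frac <- sum(x$truth$population %in% nk) /
    sum(x$truth$population %in% lymph)
  expect_gte(frac, 0.05)
  expect_lte(frac, 0.15)
})

test_that("cohort generation is deterministic and validates input", {
  cfg <- cohort_config("HD", n_donors = 2, n_events = 2000, seed = 99)
  a <- build_cohort(cfg)
  b <- build_cohort(cfg)
  expect_identical(a$donors[[1]]$events$exprs, b$donors[[1]]$events$exprs)
  expect_identical(a$donors[[2]]$events$truth, b$donors[[2]]$events$truth)
  expect_identical(a$manifest, b$manifest)

  expect_error(cohort_config("HD", n_donors = 0), "n_donors")
  expect_error(cohort_config("NOPE"), "arg")
  expect_error(donor_config("d", n_events = 0), "n_events")
})

test_that("unknown markers in population specs are a panel-mismatch
          error", {
  pops <- hd_population_specs()
  pops$Tcell$positive <- c(pops$Tcell$positive, "CD999")
  expect_error(sample_donor(donor_config("d", n_events = 100), pops),
               "CD999")
})

test_that("CD56neg NK expansion: untreated HIV exceeds healthy donors", {
  hd <- build_cohort(cohort_config("HD", n_donors = 20, n_events = 5000,
                                   seed = 42))
  hiv <- build_cohort(cohort_config("HIV_untreated", n_donors = 20,
                                    n_events = 5000, seed = 42))
  frac_neg <- function(cohort) {
    vapply(cohort$donors, function(d) {
      tr <- d$events$truth$population
      nk_all <- grepl("^NK_", tr)
      mean(tr[nk_all] %in% c("NK_neg_CD16pos", "NK_neg_CD16neg"))
    }, 0)
  }
  expect_gt(mean(frac_neg(hiv)), mean(frac_neg(hd)))
})

test_that("truth-label fractions recover configured abundances within 3
          binomial SD (jitter disabled)", {
  cfg <- cohort_config("HD", n_donors = 20, n_events = 50000, seed = 7,
                       abundance_jitter = Inf)
  cohort <- build_cohort(cfg)
  pops <- preset_population_specs("HD")
  tr <- unlist(lapply(cohort$donors,
                      function(d) d$events$truth$population))
  n <- length(tr)
  for (nm in names(pops)) {
    p <- pops[[nm]]$abundance
    expect_lt(abs(mean(tr == nm) - p), 3 * sqrt(p * (1 - p) / n) + 1e-12)
  }
})

test_that("positive-state intensities clear the state midpoint with
          probability at least 0.95", {
  sp <- default_state_params()
  midpoint <- mean(sp$location[sp$state %in% c("neg", "pos")])
  set.seed(5)
  pos <- stats::rnorm(2e5, sp$location[sp$state == "pos"],
                      sp$scale[sp$state == "pos"])
  neg <- stats::rnorm(2e5, sp$location[sp$state == "neg"],
                      sp$scale[sp$state == "neg"])
  expect_gte(mean(pos > midpoint), 0.95)
  expect_gte(mean(neg <= midpoint), 0.95)
})
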