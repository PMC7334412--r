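# Small in-code fixtures shared across test files.

# Panel with a handful of markers for hand-built tables.
tiny_panel <- function(markers = c("FSC-A", "Viability", "CD3", "CD56",
                                   "CD16", "NKp80")) {
  role <- ifelse(markers == "FSC-A", "scatter", "fluorescence")
  nk_panel(sprintf("C%02d", seq_along(markers)), markers, role)
}

# Event table from a named list of raw-scale value vectors.
make_table <- function(values, panel = tiny_panel(names(values)),
                       truth = NULL) {
  ex <- do.call(cbind, values)
  colnames(ex) <- panel$marker
  event_table(ex, panel, truth = truth, donor_id = "fixture")
}

# Hand-built thresholds: named cutoffs on the transformed scale.
manual_thresholds <- function(cutoffs, high_cutoffs = c()) {
  out <- lapply(cutoffs, function(ct)
    structure(list(cutoff = ct, method = "manual",
                   means = c(NA, NA), sds = c(NA, NA),
                   weights = c(NA, NA), separation = NA),
              class = "nk_threshold"))
  structure(out, high_cutoffs = high_cutoffs, class = "nk_thresholds")
}

# Raw-scale value for a given transformed-scale value.
raw <- function(v, cofactor = 150) sinh(v) * cofactor

# A random event table (raw scale) over the default panel, for property
# tests; values span negative-to-bright transformed range.
random_table <- function(n, panel = default_panel()) {
  fl <- panel$marker
  ex <- matrix(raw(stats::runif(n * length(fl), -0.5, 6)),
               nrow = n, ncol = length(fl), dimnames = list(NULL, fl))
  if ("FSC-A" %in% fl) ex[, "FSC-A"] <- stats::runif(n, 3e4, 1e5)
  event_table(ex, panel, donor_id = "random")
}

# Thresholds for random_table tests: fixed cutoffs for all channels.
random_thresholds <- function(panel = default_panel(), cutoff = 1.5,
                              high = 4.5) {
  fl <- panel$marker[panel$role == "fluorescence"]
  manual_thresholds(stats::setNames(as.list(rep(cutoff, length(fl))), fl),
                    high_cutoffs = c(CD56 = high))
}

# Cached default-scale study for the acceptance suite: the healthy-donor
# cohort carries all perturbations; the disease cohorts are analysed
# unperturbed (their figures only use the untreated condition). Master
# seeds match run_study(seed = 42).
acceptance_study <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    conditions <- c("HD", "HIV_untreated", "HIV_cART", "MM")
    analyses <- list()
    for (i in seq_along(conditions)) {
      cs <- if (i == 1L) 42L else
        as.integer((42 + (i - 1) * 1000003) %% 2147483629)
      cohort <- build_cohort(cohort_config(condition = conditions[i],
                                           n_donors = 20,
                                           n_events = 50000, seed = cs))
      analyses[[conditions[i]]] <- analyze_cohort(
        cohort,
        treatments = if (i == 1L)
          c("cryopreservation", "stim_K562", "stim_IL12_IL18")
        else character(0))
    }
    cache <<- structure(list(analyses = analyses, seed = 42),
                        class = "nk_study")
    cache
  }
})
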