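#' Configuration for one simulated donor
#'
#' @param donor_id character label.
#' @param condition disease condition preset; see
#'   [preset_population_specs()].
#' @param n_events number of events to draw (>= 1).
#' @param abundance_jitter gamma concentration for donor-level resampling
#'   of population abundances: each jitter-group (biological compartment)
#'   abundance `a` is replaced by a draw from Gamma(shape = jitter * a),
#'   members of the group are scaled together, and everything is
#'   renormalised to sum to 1 (a Dirichlet over compartments). Smaller
#'   values give more donor-to-donor variability; `Inf` disables jitter.
#'   The default 2000 gives rare compartments (0.1-0.5%) a coefficient of
#'   variation of roughly 30-70%, matching the spread of donor dots in
#'   typical cytometry cohort figures, while within-compartment
#'   proportions stay fixed.
#' @param seed integer RNG seed for this donor.
#' @return object of class `donor_config`.
#' @export
donor_config <- function(donor_id, condition = "HD", n_events = 50000,
                         abundance_jitter = 2000, seed = 1L) {
  if (!is.numeric(n_events) || length(n_events) != 1L || n_events < 1) {
    stop("n_events must be a positive integer")
  }
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(abundance_jitter), abundance_jitter > 0)
  structure(list(donor_id = as.character(donor_id), condition = condition,
                 n_events = as.integer(n_events),
                 abundance_jitter = abundance_jitter,
                 seed = as.integer(seed)),
            class = "donor_config")
}

#' Draw one donor's synthetic event table
#'
#' Samples `n_events` events from the population mixture: population
#' identities are multinomial in the (optionally jittered) abundances;
#' each fluorescence marker is drawn from the population's expression-state
#' Gaussian on the arcsinh scale and mapped back to the raw scale;
#' forward scatter is Gaussian on the raw scale; the Eomes truth state is
#' Bernoulli in the population's `eomes_pos_prob` and drives the Eomes
#' channel intensity. Event order is shuffled. Fully deterministic given
#' the donor seed and configuration.
#'
#' @param config a [donor_config()]; `config$n_events` may be 0 to obtain
#'   an empty table with intact panel metadata.
#' @param population_specs named list of [population_spec()]; defaults to
#'   the `config$condition` preset.
#' @param panel an [nk_panel()].
#' @return an [event_table()] with truth labels.
#' @export
sample_donor <- function(config, population_specs = NULL,
                         panel = default_panel()) {
  stopifnot(inherits(config, "donor_config") ||
              (is.list(config) && !is.null(config$n_events)))
  if (is.null(population_specs)) {
    population_specs <- preset_population_specs(config$condition)
  }
  validate_population_specs(population_specs)
  check_population_markers(population_specs, panel)
  n <- as.integer(config$n_events)
  if (n < 0) stop("n_events must be non-negative")

  markers <- panel$marker
  if (n == 0L) {
    ex <- matrix(numeric(0), nrow = 0, ncol = length(markers),
                 dimnames = list(NULL, markers))
    truth <- data.frame(population = character(0),
                        eomes_truth = integer(0))
    return(event_table(ex, panel, truth = truth,
                       donor_id = config$donor_id,
                       condition = config$condition))
  }

  set.seed(config$seed)
  ab <- vapply(population_specs, `[[`, 0, "abundance")
  jit <- config$abundance_jitter
  if (is.null(jit)) jit <- Inf
  if (is.finite(jit)) {
    # donor variability acts on biological compartments (jitter groups):
    # populations in a group scale together, keeping within-compartment
    # proportions (e.g. the CD16+ fraction of pDCs) fixed
    grp <- vapply(population_specs, `[[`, "", "jitter_group")
    g_ab <- tapply(ab, grp, sum)
    g_draw <- stats::rgamma(length(g_ab), shape = jit * g_ab)
    # guard against all-zero draws for vanishingly rare compartments
    if (sum(g_draw) <= 0) g_draw <- g_ab
    factor_by_group <- ifelse(g_ab > 0, g_draw / g_ab, 0)
    ab <- ab * factor_by_group[grp]
    ab <- ab / sum(ab)
  }
  counts <- as.vector(stats::rmultinom(1, n, ab))
  names(counts) <- names(population_specs)

  fl <- panel$marker[panel$role == "fluorescence"]
  ex <- matrix(NA_real_, nrow = n, ncol = length(markers),
               dimnames = list(NULL, markers))
  population <- character(n)
  eomes_truth <- integer(n)
  cofactor <- 150
  row0 <- 0L
  for (nm in names(population_specs)) {
    k <- counts[[nm]]
    if (k == 0L) next
    pop <- population_specs[[nm]]
    rows <- row0 + seq_len(k)
    row0 <- row0 + k
    population[rows] <- nm
    et <- stats::rbinom(k, 1L, pop$eomes_pos_prob)
    eomes_truth[rows] <- et
    sp <- pop$state_params
    for (m in fl) {
      if (m == "Eomes") {
        st <- ifelse(et == 1L, "pos", "neg")
        loc <- sp$location[match(st, sp$state)]
        sc <- sp$scale[match(st, sp$state)]
        ex[rows, m] <- asinh_inverse(stats::rnorm(k, loc, sc), cofactor)
      } else {
        st <- marker_state(pop, m)
        i <- match(st, sp$state)
        ex[rows, m] <- asinh_inverse(
          stats::rnorm(k, sp$location[i], sp$scale[i]), cofactor)
      }
    }
    if ("FSC-A" %in% markers) {
      ex[rows, "FSC-A"] <- stats::rnorm(k, pop$fsc_location, pop$fsc_scale)
    }
  }
  ord <- sample.int(n)
  ex <- ex[ord, , drop = FALSE]
  truth <- data.frame(population = population[ord],
                      eomes_truth = eomes_truth[ord],
                      stringsAsFactors = FALSE)
  event_table(ex, panel, truth = truth, donor_id = config$donor_id,
              condition = config$condition, cofactor = cofactor)
}

check_population_markers <- function(population_specs, panel) {
  for (pop in population_specs) {
    unknown <- setdiff(c(pop$positive, pop$high), panel$marker)
    if (length(unknown)) {
      stop("population '", pop$name, "' references markers absent from ",
           "the panel: ", paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Configuration for a synthetic cohort
#'
#' @param condition condition preset name.
#' @param n_donors number of donors (>= 1).
#' @param n_events events per donor.
#' @param seed master seed; per-donor seeds are derived from it.
#' @param abundance_jitter see [donor_config()].
#' @param population_specs optional override of the condition preset.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(condition = "HD", n_donors = 20,
                          n_events = 50000, seed = 42,
                          abundance_jitter = 2000,
                          population_specs = NULL) {
  if (!is.numeric(n_donors) || length(n_donors) != 1L || n_donors < 1) {
    stop("n_donors must be a positive integer")
  }
  condition <- match.arg(condition,
                         c("HD", "HIV_untreated", "HIV_cART", "MM"))
  structure(list(condition = condition, n_donors = as.integer(n_donors),
                 n_events = as.integer(n_events), seed = as.integer(seed),
                 abundance_jitter = abundance_jitter,
                 population_specs = population_specs),
            class = "cohort_config")
}

#' Derive a stream of per-donor seeds from a master seed
#'
#' Deterministic affine derivation kept below 2^31 so the seeds remain
#' valid R integers.
#'
#' @param master_seed integer master seed.
#' @param n number of seeds.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(master_seed, n) {
  as.integer((as.numeric(master_seed) * 1009 + seq_len(n) * 9973) %%
               2147483629)
}

#' Generate a synthetic cohort
#'
#' @param config a [cohort_config()].
#' @param panel an [nk_panel()].
#' @return object of class `nk_cohort`: a list with elements `donors`
#'   (list of per-donor lists holding `config` and `events`) and
#'   `manifest` (resolved parameters, including per-donor seeds).
#' @export
build_cohort <- function(config, panel = default_panel()) {
  stopifnot(inherits(config, "cohort_config"))
  specs <- config$population_specs
  if (is.null(specs)) specs <- preset_population_specs(config$condition)
  seeds <- derive_seeds(config$seed, config$n_donors)
  donors <- vector("list", config$n_donors)
  for (i in seq_len(config$n_donors)) {
    dc <- donor_config(donor_id = sprintf("%s_donor%02d", config$condition, i),
                       condition = config$condition,
                       n_events = config$n_events,
                       abundance_jitter = config$abundance_jitter,
                       seed = seeds[i])
    donors[[i]] <- list(config = dc,
                        events = sample_donor(dc, specs, panel))
  }
  names(donors) <- vapply(donors, function(d) d$config$donor_id, "")
  manifest <- list(
    condition = config$condition,
    n_donors = config$n_donors,
    n_events = config$n_events,
    master_seed = config$seed,
    abundance_jitter = config$abundance_jitter,
    donor_seeds = as.list(stats::setNames(seeds, names(donors))),
    abundances = as.list(vapply(specs, `[[`, 0, "abundance"))
  )
  structure(list(donors = donors, manifest = manifest,
                 population_specs = specs, panel = panel),
            class = "nk_cohort")
}

#' @export
print.nk_cohort <- function(x, ...) {
  cat("<nk_cohort> ", length(x$donors), " donors, condition ",
      x$manifest$condition, ", ", x$manifest$n_events,
      " events/donor, master seed ", x$manifest$master_seed, "\n", sep = "")
  invisible(x)
}
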