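#' Subset frequency as a percentage of a parent gate
#'
#' @param membership logical vector of subset membership.
#' @param parent_membership logical vector of parent-gate membership;
#'   `membership` must be a subset of it.
#' @return `100 * |subset| / |parent|`, or `NA` when the parent is empty
#'   (undefined, never zero).
#' @export
subset_frequency <- function(membership, parent_membership) {
  stopifnot(length(membership) == length(parent_membership))
  if (any(membership & !parent_membership)) {
    stop("membership must be a subset of parent_membership")
  }
  np <- sum(parent_membership)
  if (np == 0L) return(NA_real_)
  100 * sum(membership) / np
}

#' Percentage of member events positive for a marker
#'
#' For the Eomes channel of a synthetic table the ground-truth label is
#' used when present (set `eomes_from = "intensity"` to force the fitted
#' cutoff); all other markers are compared against their threshold on the
#' transformed scale.
#'
#' @param x an [event_table()].
#' @param membership logical membership vector.
#' @param marker marker name.
#' @param thresholds an `nk_thresholds` object (or a single
#'   `nk_threshold` for `marker`).
#' @param eomes_from `"truth"` or `"intensity"`.
#' @return percentage in `[0, 100]`, or `NA` for an empty membership.
#' @export
pct_positive <- function(x, membership, marker, thresholds,
                         eomes_from = c("truth", "intensity")) {
  eomes_from <- match.arg(eomes_from)
  stopifnot(inherits(x, "event_table"),
            length(membership) == n_events(x))
  if (sum(membership) == 0L) return(NA_real_)
  if (marker == "Eomes" && eomes_from == "truth" && !is.null(x$truth)) {
    return(100 * mean(x$truth$eomes_truth[membership] == 1L))
  }
  th <- if (inherits(thresholds, "nk_threshold")) thresholds
        else thresholds[[marker]]
  if (is.null(th)) stop("no threshold for marker '", marker, "'")
  v <- marker_values(x, marker, transformed = TRUE)[membership]
  100 * mean(v > th$cutoff)
}

#' Median fluorescence intensity of a marker within a subset
#'
#' The MFI is the median of the raw-scale intensities of the member
#' events (not a geometric mean).
#'
#' @inheritParams pct_positive
#' @return median raw intensity, or `NA` for an empty membership.
#' @export
mfi <- function(x, membership, marker) {
  stopifnot(inherits(x, "event_table"),
            length(membership) == n_events(x))
  if (sum(membership) == 0L) return(NA_real_)
  stats::median(marker_values(x, marker)[membership])
}

#' Per-donor subset statistics for one event table
#'
#' Evaluates a set of strategies against frozen thresholds and computes,
#' per strategy subset: event count, frequency of the strategy's parent
#' gate, frequency of total NK cells (the NK-reference gate: NKp80+ or
#' CD56+ after standard exclusion), Eomes purity, CD123 contamination,
#' CD16/NKp80 MFI, FSC-A median, and functional positivity (CD107a,
#' IFNg, TNF).
#'
#' @param x an [event_table()].
#' @param thresholds `nk_thresholds` (estimated on the donor's fresh,
#'   unstimulated sample and frozen for perturbed conditions).
#' @param strategies named list of [gating_strategy()] objects.
#' @param treatment label recorded in the `treatment` column
#'   (`"none"`, `"cryopreservation"`, `"stim_K562"`, `"stim_IL12_IL18"`).
#' @return data.frame, one row per (strategy, subset); see
#'   [donor_table()] for the column schema.
#' @export
subset_stats <- function(x, thresholds, strategies = builtin_strategies(),
                         treatment = "none") {
  nk_mem <- apply_strategy(x, get_strategy("nk_ref"), thresholds)$NK
  rows <- list()
  for (snm in names(strategies)) {
    strat <- strategies[[snm]]
    mem <- apply_strategy(x, strat, thresholds)
    for (sub in names(strat$subsets)) {
      m <- mem[[sub]]
      parent <- if (strat$parent %in% names(mem) && sub != strat$parent)
        mem[[strat$parent]] else mem$viable
      freq_nk <- if (sum(nk_mem) == 0L) NA_real_ else
        100 * sum(m) / sum(nk_mem)
      rows[[length(rows) + 1L]] <- data.frame(
        donor_id = x$donor_id, condition = x$condition,
        treatment = treatment, strategy = snm, subset = sub,
        n_events = sum(m),
        freq_of_parent = subset_frequency(m & parent, parent),
        freq_of_nk = freq_nk,
        pct_eomes_pos = pct_positive(x, m, "Eomes", thresholds),
        pct_cd123_pos = pct_positive(x, m, "CD123", thresholds),
        mfi_CD16 = mfi(x, m, "CD16"),
        mfi_NKp80 = mfi(x, m, "NKp80"),
        fsc_median = mfi(x, m, "FSC-A"),
        pct_CD107a = pct_positive(x, m, "CD107a", thresholds),
        pct_IFNg = pct_positive(x, m, "IFNg", thresholds),
        pct_TNF = pct_positive(x, m, "TNF", thresholds),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Analyse a cohort: thresholds, gating and subset statistics
#'
#' Per donor: estimates per-channel thresholds on the fresh/unstimulated
#' sample, evaluates all strategies, then applies each requested
#' perturbation (with a seed derived from the donor seed) and re-evaluates
#' the same frozen gates on the perturbed sample — mirroring the practice
#' of comparing identical gates before and after stimulation, and
#' preventing CD16 shedding from silently moving the CD16 gate.
#'
#' @param cohort an `nk_cohort` from [build_cohort()].
#' @param strategies named list of strategies (default: full registry).
#' @param treatments character vector of perturbation kinds to add to the
#'   untreated condition; subset of
#'   `c("cryopreservation", "stim_K562", "stim_IL12_IL18")`.
#' @return object of class `nk_analysis`: list with `stats` (the pooled
#'   [subset_stats()] data.frame), `thresholds` (per donor), `cohort`.
#' @export
analyze_cohort <- function(cohort, strategies = builtin_strategies(),
                           treatments = c("cryopreservation", "stim_K562",
                                          "stim_IL12_IL18")) {
  stopifnot(inherits(cohort, "nk_cohort"))
  all_stats <- list()
  thresholds <- list()
  for (i in seq_along(cohort$donors)) {
    d <- cohort$donors[[i]]
    th <- estimate_panel_thresholds(d$events)
    thresholds[[d$config$donor_id]] <- th
    all_stats[[length(all_stats) + 1L]] <-
      subset_stats(d$events, th, strategies, treatment = "none")
    for (k in seq_along(treatments)) {
      kind <- treatments[k]
      pert <- apply_perturbation(
        d$events, default_perturbation(kind), cohort$population_specs,
        seed = perturbation_seed(d$config$seed, kind))
      all_stats[[length(all_stats) + 1L]] <-
        subset_stats(pert, th, strategies, treatment = kind)
    }
  }
  structure(list(stats = do.call(rbind, all_stats),
                 thresholds = thresholds, cohort = cohort,
                 treatments = treatments),
            class = "nk_analysis")
}

#' Deterministic seed for a donor's perturbed condition
#' @param donor_seed the donor's RNG seed.
#' @param kind perturbation kind.
#' @return integer seed below 2^31.
#' @export
perturbation_seed <- function(donor_seed, kind) {
  off <- match(kind, c("cryopreservation", "stim_K562", "stim_IL12_IL18"))
  as.integer((as.numeric(donor_seed) + off * 1299721) %% 2147483629)
}

#' @export
print.nk_analysis <- function(x, ...) {
  cat("<nk_analysis> ", length(x$thresholds), " donors, ",
      nrow(x$stats), " stat rows, treatments: none",
      if (length(x$treatments)) paste0(", ",
        paste(x$treatments, collapse = ", ")), "\n", sep = "")
  invisible(x)
}

#' Long-format per-donor statistics table
#'
#' One row per (donor, condition, treatment, strategy, subset). Columns:
#' `donor_id`, `condition`, `treatment`, `strategy`, `subset`,
#' `n_events`, `freq_of_parent`, `freq_of_nk`, `pct_eomes_pos`,
#' `pct_cd123_pos`, `mfi_CD16`, `mfi_NKp80`, `fsc_median`,
#' `pct_CD107a`, `pct_IFNg`, `pct_TNF`. Undefined statistics (empty
#' gates) are missing values, never zeros.
#'
#' @param analysis an `nk_analysis` (or a list of them, pooled).
#' @return data.frame in the documented schema.
#' @export
donor_table <- function(analysis) {
  if (inherits(analysis, "nk_analysis")) return(analysis$stats)
  do.call(rbind, lapply(analysis, donor_table))
}

#' Write a donor statistics table as CSV
#'
#' Percentages and MFIs are serialised with 4 decimal places for
#' byte-stable output; missing values are written as empty fields.
#'
#' @param stats data.frame from [donor_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_donor_table <- function(stats, path) {
  num <- vapply(stats, is.numeric, TRUE) & names(stats) != "n_events"
  out <- stats
  for (j in which(num)) {
    out[[j]] <- ifelse(is.na(stats[[j]]), "",
                       sprintf("%.4f", stats[[j]]))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
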