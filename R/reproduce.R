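#' Run the full synthetic study: cohorts, gating, statistics
#'
#' Builds one cohort per disease condition (each with its own master seed
#' derived from `seed`; the healthy-donor cohort uses `seed` itself, so it
#' coincides with the default cohort), analyses each with frozen per-donor
#' thresholds, and applies the requested perturbations.
#'
#' @param seed master seed.
#' @param n_donors donors per condition.
#' @param n_events events per donor.
#' @param conditions condition presets to simulate.
#' @param treatments perturbation kinds to apply (besides none).
#' @param strategies strategy registry to evaluate.
#' @return object of class `nk_study`: named list of `nk_analysis` in
#'   `$analyses`, plus `$seed`.
#' @export
run_study <- function(seed = 42, n_donors = 20, n_events = 50000,
                      conditions = c("HD", "HIV_untreated", "HIV_cART",
                                     "MM"),
                      treatments = c("cryopreservation", "stim_K562",
                                     "stim_IL12_IL18"),
                      strategies = builtin_strategies()) {
  analyses <- list()
  for (i in seq_along(conditions)) {
    cs <- if (i == 1L) as.integer(seed) else
      as.integer((as.numeric(seed) + (i - 1) * 1000003) %% 2147483629)
    cohort <- build_cohort(cohort_config(condition = conditions[i],
                                         n_donors = n_donors,
                                         n_events = n_events, seed = cs))
    analyses[[conditions[i]]] <-
      analyze_cohort(cohort, strategies = strategies,
                     treatments = treatments)
  }
  structure(list(analyses = analyses, seed = seed), class = "nk_study")
}

#' @export
print.nk_study <- function(x, ...) {
  cat("<nk_study> conditions:", paste(names(x$analyses), collapse = ", "),
      " seed:", x$seed, "\n")
  invisible(x)
}

as_study <- function(x) {
  if (inherits(x, "nk_study")) return(x)
  if (inherits(x, "nk_analysis")) {
    cond <- x$cohort$manifest$condition
    return(structure(list(analyses = stats::setNames(list(x), cond),
                          seed = x$cohort$manifest$master_seed),
                     class = "nk_study"))
  }
  stop("expected an nk_study or nk_analysis object")
}

study_analysis <- function(study, condition) {
  an <- study$analyses[[condition]]
  if (is.null(an)) {
    stop("missing required condition '", condition,
         "' in study (have: ", paste(names(study$analyses),
                                     collapse = ", "), ")", call. = FALSE)
  }
  an
}

need_treatment <- function(an, kind) {
  if (!kind %in% an$treatments) {
    stop("missing required perturbation '", kind, "' in analysis",
         call. = FALSE)
  }
}

# per-donor vector of one statistic, donor order preserved
stat_vec <- function(an, strategy, col, subset = "target",
                     treatment = "none") {
  s <- an$stats
  s[s$strategy == strategy & s$subset == subset &
      s$treatment == treatment, col]
}

donor_ids <- function(an) names(an$thresholds)

long_df <- function(donor_id, group, value) {
  data.frame(donor_id = donor_id, group = group, value = value,
             stringsAsFactors = FALSE)
}

summarize_groups <- function(per_donor, summary_stat) {
  sp <- split(per_donor$value, per_donor$group)
  sp <- sp[unique(per_donor$group)]
  data.frame(
    group = names(sp),
    n = vapply(sp, function(v) sum(is.finite(v)), 0L),
    mean = vapply(sp, function(v) mean(v, na.rm = TRUE), 0),
    sem = vapply(sp, function(v) {
      v <- v[is.finite(v)]
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
    }, 0),
    median = vapply(sp, function(v) stats::median(v, na.rm = TRUE), 0),
    row.names = NULL, stringsAsFactors = FALSE)
}

make_fig <- function(id, per_donor, comparisons = list(),
                     assertions = logical(), summary_stat = "mean_sem") {
  structure(list(id = id, per_donor = per_donor,
                 summary = summarize_groups(per_donor, summary_stat),
                 summary_stat = summary_stat,
                 comparisons = comparisons,
                 assertions = assertions),
            class = "nk_figure")
}

#' @export
print.nk_figure <- function(x, ...) {
  cat("<nk_figure> ", x$id, " (summary: ", x$summary_stat, ")\n",
      sep = "")
  print(x$summary, digits = 4)
  if (length(x$comparisons)) {
    cat("comparisons:\n")
    print(comparison_table(x$comparisons), digits = 4)
  }
  if (length(x$assertions)) {
    cat("assertions:\n")
    for (nm in names(x$assertions)) {
      cat("  [", if (isTRUE(x$assertions[[nm]])) "pass" else "FAIL",
          "] ", nm, "\n", sep = "")
    }
  }
  invisible(x)
}

sig <- function(cc, alpha = 0.05) is.finite(cc$p_value) &&
  cc$p_value < alpha

# Event-level per-donor statistic within a strategy target split by
# Eomes truth state: stat = "fsc" (FSC-A median) or "cd123" (% CD123+).
eomes_split_stat <- function(an, strategy, stat, thresholds_needed = TRUE) {
  strat <- get_strategy(strategy)
  out <- list()
  for (d in an$cohort$donors) {
    th <- an$thresholds[[d$config$donor_id]]
    mem <- apply_strategy(d$events, strat, th)$target
    epos <- d$events$truth$eomes_truth == 1L
    for (grp in c("Eomes_pos", "Eomes_neg")) {
      m <- if (grp == "Eomes_pos") mem & epos else mem & !epos
      val <- if (stat == "fsc") mfi(d$events, m, "FSC-A")
             else pct_positive(d$events, m, "CD123", th)
      out[[length(out) + 1L]] <-
        long_df(d$config$donor_id, paste0(strategy, ".", grp), val)
    }
  }
  do.call(rbind, out)
}

purity_fig <- function(an, strategies, comparisons_spec, id,
                       alpha = 0.05) {
  per <- do.call(rbind, lapply(strategies, function(s)
    long_df(donor_ids(an), s, stat_vec(an, s, "pct_eomes_pos"))))
  comps <- list()
  asserts <- logical()
  for (cs in comparisons_spec) {
    cc <- paired_compare(stat_vec(an, cs$a, "pct_eomes_pos"),
                         stat_vec(an, cs$b, "pct_eomes_pos"),
                         label = paste0(cs$a, " vs ", cs$b,
                                        " Eomes+ purity"),
                         labels = c(cs$a, cs$b))
    comps[[length(comps) + 1L]] <- cc
    if (!is.null(cs$assert)) {
      ok <- switch(cs$assert,
        b_higher_sig = sig(cc, alpha) && cc$direction == cs$b,
        a_higher_sig = sig(cc, alpha) && cc$direction == cs$a,
        ns = !sig(cc, alpha))
      asserts[[paste0(cs$a, " vs ", cs$b, ": ", cs$assert)]] <- ok
    }
  }
  make_fig(id, per, comps, asserts)
}

fig_1A <- function(study) {
  an <- study_analysis(study, "HD")
  purity_fig(an, c("cd16", "nkp80"),
             list(list(a = "cd16", b = "nkp80", assert = "b_higher_sig")),
             "1A")
}

fig_1B <- function(study) {
  an <- study_analysis(study, "HD")
  per <- eomes_split_stat(an, "cd16", "fsc")
  a <- per$value[per$group == "cd16.Eomes_pos"]
  b <- per$value[per$group == "cd16.Eomes_neg"]
  cc <- paired_compare(a, b, "FSC-A median: Eomes+ vs Eomes- (cd16 gate)",
                       labels = c("Eomes_pos", "Eomes_neg"))
  make_fig("1B", per, list(cc),
           c("Eomes- larger FSC, p<0.05" =
               sig(cc) && cc$direction == "Eomes_neg"),
           summary_stat = "median")
}

fig_1C <- function(study) {
  an <- study_analysis(study, "HD")
  per <- rbind(eomes_split_stat(an, "cd16", "cd123"),
               eomes_split_stat(an, "nkp80", "cd123"))
  a <- per$value[per$group == "nkp80.Eomes_neg"]
  b <- per$value[per$group == "cd16.Eomes_neg"]
  cc <- paired_compare(a, b,
                       "%CD123+ in Eomes- events: nkp80 vs cd16 gate",
                       labels = c("nkp80.Eomes_neg", "cd16.Eomes_neg"))
  make_fig("1C", per, list(cc),
           c("cd16 Eomes- events CD123-rich, p<0.05" =
               sig(cc) && cc$direction == "cd16.Eomes_neg"))
}

fig_1D <- function(study) {
  an <- study_analysis(study, "HD")
  purity_fig(an, c("cd16", "cd16_cd123excl", "nkp80", "nkp80_cd123excl"),
             list(list(a = "cd16", b = "cd16_cd123excl",
                       assert = "b_higher_sig"),
                  list(a = "cd16_cd123excl", b = "nkp80_cd123excl")),
             "1D")
}

quadrant_subsets <- c("CD16pos_NKp80neg", "CD16neg_NKp80pos",
                      "CD16pos_NKp80pos")

fig_2A <- function(study) {
  an <- study_analysis(study, "HD")
  per <- do.call(rbind, lapply(quadrant_subsets, function(q)
    long_df(donor_ids(an), q,
            stat_vec(an, "quadrants", "freq_of_parent", subset = q))))
  npp <- stat_vec(an, "quadrants", "n_events", subset = "CD16pos_NKp80pos")
  nnp <- stat_vec(an, "quadrants", "n_events", subset = "CD16neg_NKp80pos")
  coexpr <- ifelse(npp + nnp > 0, 100 * npp / (npp + nnp), NA_real_)
  per <- rbind(per, long_df(donor_ids(an), "pct_CD16pos_of_NKp80pos",
                            coexpr))
  mc <- mean(coexpr, na.rm = TRUE)
  make_fig("2A", per, list(),
           c("about half of CD56neg NKp80+ co-express CD16" =
               is.finite(mc) && mc >= 40 && mc <= 60))
}

quadrant_marker_fig <- function(an, col, id, low_label) {
  per <- do.call(rbind, lapply(quadrant_subsets, function(q)
    long_df(donor_ids(an), q, stat_vec(an, "quadrants", col, subset = q))))
  pn <- stat_vec(an, "quadrants", col, subset = "CD16pos_NKp80neg")
  np <- stat_vec(an, "quadrants", col, subset = "CD16neg_NKp80pos")
  pp <- stat_vec(an, "quadrants", col, subset = "CD16pos_NKp80pos")
  c1 <- paired_compare(pn, np, paste0(col, ": CD16+NKp80- vs CD16-NKp80+"),
                       labels = c("CD16pos_NKp80neg", "CD16neg_NKp80pos"))
  c2 <- paired_compare(pn, pp, paste0(col, ": CD16+NKp80- vs CD16+NKp80+"),
                       labels = c("CD16pos_NKp80neg", "CD16pos_NKp80pos"))
  list(per = per, comps = list(c1, c2), pn = pn, np = np, pp = pp)
}

fig_2B <- function(study) {
  an <- study_analysis(study, "HD")
  r <- quadrant_marker_fig(an, "pct_eomes_pos", "2B", "CD16pos_NKp80neg")
  ok <- sig(r$comps[[1]]) && r$comps[[1]]$direction == "CD16neg_NKp80pos" &&
    sig(r$comps[[2]]) && r$comps[[2]]$direction == "CD16pos_NKp80pos" &&
    mean(r$pn, na.rm = TRUE) < mean(r$np, na.rm = TRUE) &&
    mean(r$pn, na.rm = TRUE) < mean(r$pp, na.rm = TRUE)
  make_fig("2B", r$per, r$comps,
           c("Eomes+% lowest in CD16+NKp80- quadrant" = ok))
}

fig_2C <- function(study) {
  an <- study_analysis(study, "HD")
  r <- quadrant_marker_fig(an, "pct_cd123_pos", "2C", "CD16pos_NKp80neg")
  mpn <- mean(r$pn, na.rm = TRUE)
  ok <- mpn >= 40 && mpn <= 60 &&
    mean(r$np, na.rm = TRUE) < 10 && mean(r$pp, na.rm = TRUE) < 10
  make_fig("2C", r$per, r$comps,
           c("~50% CD123+ in CD16+NKp80-, negligible elsewhere" = ok))
}

fig_3A <- function(study) {
  an <- study_analysis(study, "HD")
  purity_fig(an, c("cd7_cd16", "cd7_only", "cd16", "nkp80"),
             list(list(a = "cd7_cd16", b = "nkp80", assert = "ns"),
                  list(a = "cd7_only", b = "nkp80",
                       assert = "b_higher_sig")),
             "3A")
}

fig_3B <- function(study) {
  an <- study_analysis(study, "HD")
  purity_fig(an, c("cd300a", "cd16", "nkp80"),
             list(list(a = "cd300a", b = "nkp80",
                       assert = "b_higher_sig")),
             "3B")
}

fig_3C <- function(study) {
  an <- study_analysis(study, "HD")
  purity_fig(an, c("tb4", "cd16", "nkp80"),
             list(list(a = "tb4", b = "nkp80", assert = "b_higher_sig")),
             "3C")
}

fig_3D <- function(study) {
  an <- study_analysis(study, "HD")
  strategies <- c("cd300a", "cd300a_cd123excl", "tb4", "tb4_cd123excl")
  per <- do.call(rbind, lapply(strategies, function(s)
    long_df(donor_ids(an), s, stat_vec(an, s, "pct_eomes_pos"))))
  ok1 <- mean(stat_vec(an, "cd300a_cd123excl", "pct_eomes_pos"),
              na.rm = TRUE) >=
    mean(stat_vec(an, "cd300a", "pct_eomes_pos"), na.rm = TRUE)
  ok2 <- mean(stat_vec(an, "tb4_cd123excl", "pct_eomes_pos"),
              na.rm = TRUE) >=
    mean(stat_vec(an, "tb4", "pct_eomes_pos"), na.rm = TRUE)
  make_fig("3D", per, list(),
           c("CD123 exclusion does not lower CD300a/2B4 purity" =
               ok1 && ok2))
}

fig_4A <- function(study) {
  conds <- c("HD", "HIV_untreated", "HIV_cART", "MM")
  vals <- lapply(conds, function(cn)
    stat_vec(study_analysis(study, cn), "nkp80", "freq_of_nk"))
  names(vals) <- conds
  per <- do.call(rbind, lapply(conds, function(cn)
    long_df(donor_ids(study_analysis(study, cn)), cn, vals[[cn]])))
  comp_specs <- list(c("HD", "HIV_untreated"), c("HIV_cART", "HIV_untreated"),
                     c("MM", "HIV_untreated"), c("HD", "HIV_cART"),
                     c("HD", "MM"))
  comps <- lapply(comp_specs, function(cs)
    group_compare(vals[[cs[1]]], vals[[cs[2]]],
                  paste0("CD56neg NKp80+ %NK: ", cs[1], " vs ", cs[2]),
                  labels = cs))
  asserts <- c(
    "HIV_untreated > HD" = sig(comps[[1]]) &&
      comps[[1]]$direction == "HIV_untreated",
    "HIV_untreated > HIV_cART" = sig(comps[[2]]) &&
      comps[[2]]$direction == "HIV_untreated",
    "HIV_untreated > MM" = sig(comps[[3]]) &&
      comps[[3]]$direction == "HIV_untreated",
    "HIV_cART > HD" = sig(comps[[4]]) &&
      comps[[4]]$direction == "HIV_cART",
    "MM > HD" = sig(comps[[5]]) && comps[[5]]$direction == "MM")
  make_fig("4A", per, comps, asserts)
}

fig_4B <- function(study) {
  per <- list(); comps <- list(); asserts <- logical()
  for (cn in c("HIV_untreated", "HIV_cART")) {
    an <- study_analysis(study, cn)
    for (s in c("cd16", "nkp80")) {
      per[[length(per) + 1L]] <-
        long_df(donor_ids(an), paste0(cn, ".", s),
                stat_vec(an, s, "pct_eomes_pos"))
    }
    cc <- paired_compare(stat_vec(an, "cd16", "pct_eomes_pos"),
                         stat_vec(an, "nkp80", "pct_eomes_pos"),
                         paste0(cn, ": cd16 vs nkp80 purity"),
                         labels = c("cd16", "nkp80"))
    comps[[length(comps) + 1L]] <- cc
    if (cn == "HIV_cART") {
      asserts["cART: nkp80 purity higher, p<0.05"] <-
        sig(cc) && cc$direction == "nkp80"
    }
  }
  make_fig("4B", do.call(rbind, per), comps, asserts)
}

fig_4C <- function(study) {
  an <- study_analysis(study, "MM")
  purity_fig(an, c("cd16", "nkp80"),
             list(list(a = "cd16", b = "nkp80", assert = "b_higher_sig")),
             "4C")
}

mfi_ratio_fig <- function(study, id, kinds) {
  an <- study_analysis(study, "HD")
  for (k in kinds) need_treatment(an, k)
  per <- list(); comps <- list(); asserts <- logical()
  for (m in c("CD16", "NKp80")) {
    col <- paste0("mfi_", m)
    base <- stat_vec(an, "nk_ref", col, subset = "NK")
    per[[length(per) + 1L]] <- long_df(donor_ids(an),
                                       paste0(m, ".none"), base)
    for (k in kinds) {
      v <- stat_vec(an, "nk_ref", col, subset = "NK", treatment = k)
      per[[length(per) + 1L]] <- long_df(donor_ids(an),
                                         paste0(m, ".", k), v)
      cc <- paired_compare(base, v, paste0(m, " MFI: none vs ", k),
                           labels = c("none", k))
      comps[[length(comps) + 1L]] <- cc
      ratio <- mean(v / base, na.rm = TRUE)
      if (m == "CD16") {
        asserts[paste0("CD16 MFI decreases under ", k)] <-
          sig(cc) && cc$direction == "none"
      } else {
        asserts[paste0("NKp80 MFI ratio in [0.9, 1.1] under ", k)] <-
          is.finite(ratio) && ratio >= 0.9 && ratio <= 1.1
      }
    }
  }
  make_fig(id, do.call(rbind, per), comps, asserts)
}

fig_5B <- function(study) {
  mfi_ratio_fig(study, "5B", c("stim_K562", "stim_IL12_IL18"))
}

fig_S1_cryo <- function(study) {
  mfi_ratio_fig(study, "S1-cryo", "cryopreservation")
}

functional_fig <- function(study, id, conditions, assert_conditions,
                           strategies = c("cd16", "nkp80")) {
  stims <- c("stim_K562", "stim_IL12_IL18")
  markers <- c("pct_CD107a", "pct_IFNg", "pct_TNF")
  per <- list(); comps <- list(); asserts <- logical()
  for (cn in conditions) {
    an <- study_analysis(study, cn)
    for (k in stims) need_treatment(an, k)
    for (k in stims) for (col in markers) for (s in strategies) {
      v <- stat_vec(an, s, col, treatment = k)
      v0 <- stat_vec(an, s, col, treatment = "none")
      grp <- paste(cn, k, col, s, sep = ".")
      per[[length(per) + 1L]] <- long_df(donor_ids(an), grp, v)
      per[[length(per) + 1L]] <-
        long_df(donor_ids(an), paste0(grp, ".ctrl_subtracted"), v - v0)
    }
    for (k in stims) for (col in c("pct_IFNg", "pct_TNF")) {
      a <- stat_vec(an, "cd16", col, treatment = k)
      b <- stat_vec(an, "nkp80", col, treatment = k)
      cc <- paired_compare(a, b,
                           paste0(cn, " ", k, " ", col,
                                  ": cd16 vs nkp80 gate"),
                           labels = c("cd16", "nkp80"))
      comps[[length(comps) + 1L]] <- cc
      if (cn %in% assert_conditions) {
        asserts[paste0(cn, " ", k, " ", col,
                       " higher in nkp80 gate, p<0.05")] <-
          sig(cc) && cc$direction == "nkp80"
      }
    }
  }
  make_fig(id, do.call(rbind, per), comps, asserts,
           summary_stat = "median")
}

fig_6A <- function(study) {
  functional_fig(study, "6A", c("HIV_untreated", "HIV_cART"),
                 assert_conditions = "HIV_cART")
}

fig_6B <- function(study) {
  functional_fig(study, "6B", "HD", assert_conditions = "HD")
}

fig_dim_vs_neg <- function(study) {
  an <- study_analysis(study, "HD")
  stims <- c("stim_K562", "stim_IL12_IL18")
  for (k in stims) need_treatment(an, k)
  markers <- c("pct_CD107a", "pct_IFNg", "pct_TNF")
  per <- list(); comps <- list(); asserts <- logical()
  for (k in stims) for (col in markers) {
    dim_v <- stat_vec(an, "cd56dim", col, treatment = k)
    neg_v <- stat_vec(an, "nkp80", col, treatment = k)
    per[[length(per) + 1L]] <-
      long_df(donor_ids(an), paste("CD56dim", k, col, sep = "."), dim_v)
    per[[length(per) + 1L]] <-
      long_df(donor_ids(an), paste("CD56neg", k, col, sep = "."), neg_v)
    cc <- paired_compare(neg_v, dim_v,
                         paste0(k, " ", col, ": CD56neg vs CD56dim"),
                         labels = c("CD56neg", "CD56dim"))
    comps[[length(comps) + 1L]] <- cc
    asserts[paste0(k, " ", col, ": CD56dim higher, p<0.05")] <-
      sig(cc) && cc$direction == "CD56dim"
  }
  make_fig("S-dim-vs-neg", do.call(rbind, per), comps, asserts,
           summary_stat = "median")
}

figure_registry <- function() {
  list("1A" = fig_1A, "1B" = fig_1B, "1C" = fig_1C, "1D" = fig_1D,
       "2A" = fig_2A, "2B" = fig_2B, "2C" = fig_2C,
       "3A" = fig_3A, "3B" = fig_3B, "3C" = fig_3C, "3D" = fig_3D,
       "4A" = fig_4A, "4B" = fig_4B, "4C" = fig_4C,
       "5B" = fig_5B, "6A" = fig_6A, "6B" = fig_6B,
       "S1-cryo" = fig_S1_cryo, "S-dim-vs-neg" = fig_dim_vs_neg)
}

#' Reproduce a figure-analog table from a synthetic study
#'
#' Computes the per-donor values, the summary the corresponding figure
#' legend uses (mean with SEM, or median), the nonparametric comparisons
#' the figure annotates, and a set of qualitative assertions mirroring
#' the figure's claims. The test used is stated for every comparison in
#' the output. Functional readouts are reported both raw and
#' unstimulated-control-subtracted (groups suffixed `.ctrl_subtracted`);
#' comparisons use the raw values.
#'
#' @param figure_id one of `"1A"`, `"1B"`, `"1C"`, `"1D"`, `"2A"`,
#'   `"2B"`, `"2C"`, `"3A"`, `"3B"`, `"3C"`, `"3D"`, `"4A"`, `"4B"`,
#'   `"4C"`, `"5B"`, `"6A"`, `"6B"`, `"S1-cryo"`, `"S-dim-vs-neg"`.
#' @param study an `nk_study` from [run_study()] (an `nk_analysis` is
#'   accepted for single-condition figures).
#' @param out_dir optional directory; when given, per-donor and summary
#'   CSV tables and a PNG plot are written under it.
#' @return object of class `nk_figure`.
#' @export
reproduce <- function(figure_id, study, out_dir = NULL) {
  reg <- figure_registry()
  if (!figure_id %in% names(reg)) {
    stop("unknown figure id '", figure_id, "'; supported: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  fig <- reg[[figure_id]](as_study(study))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    base <- file.path(out_dir, paste0("fig_", gsub("[^A-Za-z0-9]", "_",
                                                   figure_id)))
    utils::write.csv(fig$per_donor, paste0(base, "_per_donor.csv"),
                     row.names = FALSE)
    utils::write.csv(fig$summary, paste0(base, "_summary.csv"),
                     row.names = FALSE)
    if (length(fig$comparisons)) {
      utils::write.csv(comparison_table(fig$comparisons),
                       paste0(base, "_comparisons.csv"),
                       row.names = FALSE)
    }
    plot_figure(fig, paste0(base, ".png"))
  }
  fig
}

#' Plot a figure-analog as donor dots with summary bars
#'
#' @param fig an `nk_figure`.
#' @param file optional PNG path; when `NULL`, plots to the active
#'   device.
#' @return `fig`, invisibly.
#' @export
plot_figure <- function(fig, file = NULL) {
  per <- fig$per_donor[!grepl("ctrl_subtracted", fig$per_donor$group), ]
  groups <- unique(per$group)
  if (!is.null(file)) {
    grDevices::png(file, width = 220 + 90 * length(groups), height = 480,
                   res = 96)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mar = c(10, 4, 2, 1))
  # restore par before any dev.off() so no stray device is opened
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  vals <- split(per$value, factor(per$group, levels = groups))
  graphics::stripchart(vals, vertical = TRUE, method = "jitter",
                       jitter = 0.15, pch = 16,
                       col = grDevices::adjustcolor("steelblue", 0.7),
                       las = 2, main = paste("Figure analog", fig$id),
                       ylab = "value", cex.axis = 0.7)
  stat <- if (fig$summary_stat == "median") fig$summary$median
          else fig$summary$mean
  graphics::segments(seq_along(groups) - 0.3, stat,
                     seq_along(groups) + 0.3, stat, lwd = 2)
  invisible(fig)
}

#' Generate a full report directory for a set of figures
#'
#' Writes one CSV/PNG set per figure plus an `index.csv` listing every
#' figure id, each qualitative assertion and its pass/fail state.
#'
#' @param study an `nk_study`.
#' @param figure_ids figure ids to render; default all supported.
#' @param out_dir output directory (created if needed).
#' @return data.frame index, invisibly.
#' @export
run_report <- function(study, figure_ids = names(figure_registry()),
                       out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (id in figure_ids) {
    fig <- reproduce(id, study, out_dir = out_dir)
    if (length(fig$assertions)) {
      rows[[length(rows) + 1L]] <- data.frame(
        figure_id = id, assertion = names(fig$assertions),
        pass = unname(unlist(fig$assertions)), stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        figure_id = id, assertion = "(report only)", pass = NA,
        stringsAsFactors = FALSE)
    }
  }
  index <- do.call(rbind, rows)
  utils::write.csv(index, file.path(out_dir, "index.csv"),
                   row.names = FALSE)
  invisible(index)
}
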