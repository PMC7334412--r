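#' Paired nonparametric comparison (Wilcoxon signed-rank)
#'
#' Two-sided Wilcoxon signed-rank test on per-donor paired values. Pairs
#' with a missing value are dropped; zero differences are dropped before
#' the test (their count is reported). The exact null distribution is
#' used for up to 25 non-zero pairs (ties permitting), the normal
#' approximation with continuity correction otherwise.
#'
#' @param a,b numeric vectors of per-donor values, same length and order.
#' @param label comparison label carried into the result.
#' @param labels length-2 character: names for the two sides.
#' @return object of class `nk_comparison` with fields `label`,
#'   `n_pairs` (usable pairs), `n_zero` (zero differences dropped),
#'   `test`, `statistic`, `p_value` (`NA` when no non-zero pairs remain),
#'   `direction` (which side is larger; `"none"` for a zero effect) and
#'   `effect` (median of the usable paired differences, b - a).
#' @export
paired_compare <- function(a, b, label = "", labels = c("A", "B")) {
  stopifnot(length(a) == length(b))
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 3L) {
    stop("insufficient data: fewer than 3 usable pairs")
  }
  d <- b - a
  nz <- d != 0
  n_zero <- sum(!nz)
  effect <- stats::median(d)
  direction <- if (effect > 0) labels[2] else if (effect < 0) labels[1]
               else "none"
  if (!any(nz)) {
    return(structure(list(label = label, n_pairs = length(d),
                          n_zero = n_zero, test = "wilcoxon_signed_rank",
                          statistic = NA_real_, p_value = NA_real_,
                          direction = "none", effect = 0,
                          labels = labels),
                     class = "nk_comparison"))
  }
  ht <- suppressWarnings(stats::wilcox.test(
    b[nz], a[nz], paired = TRUE, alternative = "two.sided",
    exact = sum(nz) <= 25, correct = TRUE))
  structure(list(label = label, n_pairs = length(d), n_zero = n_zero,
                 test = "wilcoxon_signed_rank",
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value, direction = direction,
                 effect = effect, labels = labels),
            class = "nk_comparison")
}

#' Unpaired nonparametric comparison (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney U test between two groups of per-donor values
#' (e.g. across disease conditions). Exact for small samples without
#' ties, tie-corrected normal approximation otherwise.
#'
#' @param a,b numeric vectors (each >= 3 usable values).
#' @param label comparison label.
#' @param labels length-2 character: group names.
#' @return an `nk_comparison`; `effect` is the difference of group
#'   medians (b - a) and `statistic` the U statistic for group `b`.
#' @export
group_compare <- function(a, b, label = "", labels = c("A", "B")) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3L || length(b) < 3L) {
    stop("insufficient data: each group needs at least 3 usable values")
  }
  ht <- suppressWarnings(stats::wilcox.test(
    b, a, alternative = "two.sided",
    exact = (length(a) + length(b)) <= 50, correct = TRUE))
  effect <- stats::median(b) - stats::median(a)
  direction <- if (effect > 0) labels[2] else if (effect < 0) labels[1]
               else "none"
  structure(list(label = label, n_pairs = c(length(a), length(b)),
                 n_zero = 0L, test = "mann_whitney_u",
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value, direction = direction,
                 effect = effect, labels = labels),
            class = "nk_comparison")
}

#' @export
print.nk_comparison <- function(x, ...) {
  cat("<nk_comparison> ", x$label, "\n  ", x$test, ": statistic = ",
      format(x$statistic, digits = 4), ", p = ",
      format(x$p_value, digits = 4), "\n  direction: ", x$direction,
      " larger, effect = ", format(x$effect, digits = 4), sep = "")
  if (x$n_zero > 0) cat("  (", x$n_zero, " zero differences dropped)",
                        sep = "")
  cat("\n")
  invisible(x)
}

#' Flatten comparison results into a data.frame
#'
#' @param comparisons list of `nk_comparison` objects.
#' @return data.frame with one row per comparison.
#' @export
comparison_table <- function(comparisons) {
  do.call(rbind, lapply(comparisons, function(cc) data.frame(
    label = cc$label, test = cc$test,
    n = paste(cc$n_pairs, collapse = "+"),
    statistic = cc$statistic, p_value = cc$p_value,
    direction = cc$direction, effect = cc$effect,
    stringsAsFactors = FALSE)))
}
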