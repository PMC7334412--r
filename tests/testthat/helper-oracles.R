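# Independent oracles used to verify the package's implementations.
# These deliberately use brute force / enumeration, never the code paths
# they check.

# Exact two-sided Wilcoxon signed-rank p-value by enumerating all 2^n
# sign assignments (no ties or zeros expected in inputs).
enum_signed_rank_p <- function(a, b) {
  d <- b - a
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  ws <- vapply(seq_len(2^n) - 1L, function(mask) {
    signs <- bitwAnd(bitwShiftR(mask, seq_len(n) - 1L), 1L) == 1L
    sum(r[signs])
  }, 0)
  mean_w <- n * (n + 1) / 4
  p <- if (obs > mean_w) 2 * mean(ws >= obs) else 2 * mean(ws <= obs)
  min(1, p)
}

# Exact two-sided Mann-Whitney p-value by enumerating all choose(n1+n2,
# n1) group assignments of the pooled sample (U statistic for group b).
enum_mann_whitney_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a); n2 <- length(b)
  ustat <- function(idx_b) {
    bb <- pooled[idx_b]; aa <- pooled[-idx_b]
    sum(outer(bb, aa, ">")) + 0.5 * sum(outer(bb, aa, "=="))
  }
  obs <- ustat(seq.int(n1 + 1L, n1 + n2))
  all_u <- apply(utils::combn(n1 + n2, n2), 2, ustat)
  mean_u <- n1 * n2 / 2
  p <- if (obs > mean_u) 2 * mean(all_u >= obs) else 2 * mean(all_u <= obs)
  min(1, p)
}

# Per-event predicate interpreter: evaluates a strategy one event at a
# time with explicit recursion (independent of apply_strategy's
# vectorised evaluation).
interpret_node <- function(node, values, cutoffs, high_cutoffs) {
  if (node$type == "marker") {
    v <- values[[node$marker]]
    cut <- cutoffs[[node$marker]]
    return(switch(node$polarity,
                  positive = v > cut,
                  negative = v <= cut,
                  dim = v > cut && v <= high_cutoffs[[node$marker]],
                  bright = v > high_cutoffs[[node$marker]]))
  }
  kid <- function(k) interpret_node(k, values, cutoffs, high_cutoffs)
  if (node$type == "and") return(all(vapply(node$children, kid, TRUE)))
  if (node$type == "or") return(any(vapply(node$children, kid, TRUE)))
  !kid(node$children[[1]])
}

interpret_strategy <- function(x, strategy, thresholds) {
  cutoffs <- lapply(thresholds, `[[`, "cutoff")
  high_cutoffs <- as.list(attr(thresholds, "high_cutoffs"))
  n <- n_events(x)
  fl <- x$panel$marker[x$panel$role == "fluorescence"]
  out <- list(viable = logical(n))
  for (nm in names(strategy$subsets)) out[[nm]] <- logical(n)
  for (i in seq_len(n)) {
    values <- lapply(stats::setNames(fl, fl), function(m)
      asinh(x$exprs[i, m] / x$cofactor))
    ok <- TRUE
    for (m in strategy$exclusion) {
      if (values[[m]] > cutoffs[[m]]) ok <- FALSE
    }
    out$viable[i] <- ok
    for (nm in names(strategy$subsets)) {
      out[[nm]][i] <- ok && interpret_node(strategy$subsets[[nm]], values,
                                           cutoffs, high_cutoffs)
    }
  }
  out
}

# Density valley of a known two-component Gaussian mixture by grid
# search.
grid_valley <- function(w1, m1, s1, w2, m2, s2, lo = 0, hi = 3,
                        step = 0.001) {
  xs <- seq(lo, hi, by = step)
  dens <- w1 * stats::dnorm(xs, m1, s1) + w2 * stats::dnorm(xs, m2, s2)
  xs[which.min(dens)]
}
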