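#' Estimate a positive/negative cutoff for one channel
#'
#' Automates the manual gate placement of conventional cytometry analysis.
#' A two-component Gaussian mixture is fitted to the arcsinh-transformed
#' intensities (unequal variances); the cutoff is the equal-posterior
#' boundary between the two components. When the fit does not support a
#' bimodal reading — component separation `|mu2 - mu1| / pooled sd` below
#' `min_separation`, or a component weight below `min_weight`, or no
#' posterior crossing between the component means — the estimator falls
#' back to a quantile rule: the 99.5th percentile of declared
#' negative-control values when available, else the global 95th
#' percentile, and tags the result `quantile_fallback`.
#'
#' For speed and determinism the mixture is fitted to at most `max_fit_n`
#' evenly spaced order statistics of the input; the quantile fallback and
#' all diagnostics use the full vector.
#'
#' @param values numeric vector of transformed intensities (>= 20 values).
#' @param neg_control optional numeric vector of transformed intensities
#'   from negative-control events for the fallback rule.
#' @param min_separation minimum component separation to accept the
#'   mixture cutoff.
#' @param min_weight minimum mixing weight to accept the mixture cutoff.
#' @param neg_quantile,global_quantile fallback quantiles.
#' @param max_fit_n subsample cap for the mixture fit.
#' @return object of class `nk_threshold` with fields `cutoff`, `method`
#'   (`"mixture"` or `"quantile_fallback"`), component `means`, `sds`,
#'   `weights`, and `separation`.
#' @export
estimate_threshold <- function(values, neg_control = NULL,
                               min_separation = 2, min_weight = 0.02,
                               neg_quantile = 0.995,
                               global_quantile = 0.95,
                               max_fit_n = 8000) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("values must be finite")
  if (length(values) < 20L) {
    stop("insufficient data: need at least 20 values, got ",
         length(values))
  }
  if (diff(range(values)) == 0) {
    stop("degenerate input: all values identical")
  }

  fit_values <- sort(values)
  if (length(fit_values) > max_fit_n) {
    fit_values <- fit_values[unique(round(
      seq(1, length(fit_values), length.out = max_fit_n)))]
  }
  fit <- tryCatch(
    Mclust(fit_values, G = 2, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)

  mixture_ok <- FALSE
  means <- sds <- weights <- rep(NA_real_, 2)
  separation <- NA_real_
  cutoff <- NA_real_
  if (!is.null(fit)) {
    means <- as.numeric(fit$parameters$mean)
    sds <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
    if (length(sds) == 1L) sds <- rep(sds, 2)
    weights <- as.numeric(fit$parameters$pro)
    o <- order(means)
    means <- means[o]; sds <- sds[o]; weights <- weights[o]
    pooled <- sqrt(weights[1] * sds[1]^2 + weights[2] * sds[2]^2)
    separation <- abs(diff(means)) / pooled
    if (separation >= min_separation && min(weights) >= min_weight) {
      cutoff <- tryCatch(
        equal_posterior_boundary(means, sds, weights),
        error = function(e) NA_real_)
      mixture_ok <- is.finite(cutoff) && cutoff > means[1] &&
        cutoff < means[2]
    }
  }

  if (mixture_ok) {
    method <- "mixture"
  } else {
    method <- "quantile_fallback"
    cutoff <- if (!is.null(neg_control) && length(neg_control) >= 20L) {
      as.numeric(stats::quantile(neg_control, neg_quantile, names = FALSE))
    } else {
      as.numeric(stats::quantile(values, global_quantile, names = FALSE))
    }
  }
  structure(list(cutoff = cutoff, method = method, means = means,
                 sds = sds, weights = weights, separation = separation),
            class = "nk_threshold")
}

# Solve w1 N(x; m1, s1) = w2 N(x; m2, s2) for x between the means.
equal_posterior_boundary <- function(means, sds, weights) {
  f <- function(x) {
    log(weights[1]) + stats::dnorm(x, means[1], sds[1], log = TRUE) -
      log(weights[2]) - stats::dnorm(x, means[2], sds[2], log = TRUE)
  }
  stats::uniroot(f, lower = means[1], upper = means[2], tol = 1e-9)$root
}

#' @export
print.nk_threshold <- function(x, ...) {
  cat("<nk_threshold> cutoff = ", format(x$cutoff, digits = 4),
      " (", x$method, ")", sep = "")
  if (is.finite(x$separation)) {
    cat("  components ", format(x$means[1], digits = 3), "/",
        format(x$means[2], digits = 3), ", separation ",
        format(x$separation, digits = 3), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Estimate thresholds for every fluorescence channel of a table
#'
#' Fits [estimate_threshold()] per fluorescence marker on the transformed
#' intensities. For CD56 a second, upper cutoff separating CD56-dim from
#' CD56-bright is derived as the positive-component mean plus two positive
#' -component standard deviations (when the mixture was accepted; else the
#' mean plus two SD of the above-cutoff values).
#'
#' @param x an [event_table()].
#' @param markers markers to fit; defaults to all fluorescence channels.
#' @param ... passed to [estimate_threshold()].
#' @return object of class `nk_thresholds`: named list of `nk_threshold`,
#'   with a `high_cutoffs` attribute carrying the CD56 dim/bright boundary.
#' @export
estimate_panel_thresholds <- function(x, markers = NULL, ...) {
  stopifnot(inherits(x, "event_table"))
  if (is.null(markers)) {
    markers <- x$panel$marker[x$panel$role == "fluorescence"]
  }
  out <- list()
  high <- c()
  for (m in markers) {
    v <- marker_values(x, m, transformed = TRUE)
    th <- estimate_threshold(v, ...)
    out[[m]] <- th
    if (m == "CD56") {
      high[[m]] <- if (th$method == "mixture") {
        th$means[2] + 2 * th$sds[2]
      } else {
        up <- v[v > th$cutoff]
        if (length(up) >= 2L) mean(up) + 2 * stats::sd(up) else Inf
      }
    }
  }
  structure(out, high_cutoffs = high, class = "nk_thresholds")
}

#' @export
print.nk_thresholds <- function(x, ...) {
  for (m in names(x)) {
    cat(format(m, width = 10), format(x[[m]]$cutoff, digits = 4),
        " (", x[[m]]$method, ")\n", sep = "")
  }
  invisible(x)
}
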