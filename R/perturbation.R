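#' Specify a perturbation of a stained sample
#'
#' Perturbations model what happens to marker intensities between sample
#' preparation and acquisition: cryopreservation and stimulation both
#' reduce surface CD16 — partly as a graded MFI shift (multiplicative
#' `mfi_scale`) and partly as outright shedding, in which a fraction of
#' susceptible events has CD16 redrawn from the negative-state
#' distribution (metalloprotease-mediated loss of the receptor).
#' NKp80 is deliberately left at scale 1: its stability under freezing and
#' stimulation is the property that makes it the better gating marker.
#' Stimulation additionally induces functional-marker positivity
#' (CD107a, IFNg, TNF) per population response probabilities.
#'
#' @param kind `"cryopreservation"`, `"stim_K562"` or `"stim_IL12_IL18"`.
#' @param mfi_scale named numeric vector of multiplicative raw-scale
#'   intensity factors (> 0), e.g. `c(CD16 = 0.55)`.
#' @param shed_fraction fraction in `[0, 1]` of shed-susceptible events
#'   whose CD16 drops to the negative distribution.
#' @param response_induction logical; draw functional-marker responses?
#' @param responder_shed_multiplier shedding probability multiplier for
#'   events drawn CD107a-positive (degranulating cells shed CD16
#'   preferentially); capped at probability 1.
#' @return object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(kind = c("cryopreservation", "stim_K562",
                                       "stim_IL12_IL18"),
                              mfi_scale = numeric(),
                              shed_fraction = 0,
                              response_induction = FALSE,
                              responder_shed_multiplier = 2) {
  kind <- match.arg(kind)
  stopifnot(all(mfi_scale > 0), shed_fraction >= 0, shed_fraction <= 1,
            responder_shed_multiplier >= 0)
  structure(list(kind = kind, mfi_scale = mfi_scale,
                 shed_fraction = shed_fraction,
                 response_induction = response_induction,
                 responder_shed_multiplier = responder_shed_multiplier),
            class = "perturbation_spec")
}

#' Default perturbation presets
#'
#' Cryopreservation: CD16 MFI x0.55 plus 25% shedding, no functional
#' induction. Stimulation (K562 targets or IL-12+IL-18): CD16 MFI x0.4
#' plus 50% shedding with degranulating (CD107a+) cells shedding at twice
#' the base probability, and functional-marker induction enabled.
#'
#' @param kind perturbation kind.
#' @return a [perturbation_spec()].
#' @export
default_perturbation <- function(kind = c("cryopreservation", "stim_K562",
                                          "stim_IL12_IL18")) {
  kind <- match.arg(kind)
  if (kind == "cryopreservation") {
    perturbation_spec(kind, mfi_scale = c(CD16 = 0.55),
                      shed_fraction = 0.25, response_induction = FALSE)
  } else {
    perturbation_spec(kind, mfi_scale = c(CD16 = 0.4),
                      shed_fraction = 0.5, response_induction = TRUE)
  }
}

#' Apply a perturbation to an event table
#'
#' Returns a new table; the input is not modified. Event count and truth
#' labels are preserved exactly. Deterministic given `seed`.
#'
#' @param x an [event_table()] with truth labels.
#' @param spec a [perturbation_spec()].
#' @param population_specs the population specifications the table was
#'   generated from (source of shed susceptibility and response
#'   probabilities).
#' @param seed integer RNG seed for the stochastic parts (shedding,
#'   response draws).
#' @return a perturbed [event_table()].
#' @export
apply_perturbation <- function(x, spec, population_specs, seed = 1L) {
  stopifnot(inherits(x, "event_table"), inherits(spec, "perturbation_spec"))
  if (is.null(x$truth)) {
    stop("apply_perturbation requires an event table with truth labels")
  }
  unknown <- setdiff(names(spec$mfi_scale), x$panel$marker)
  if (length(unknown)) {
    stop("mfi_scale references markers absent from the panel: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ex <- x$exprs
  n <- nrow(ex)
  set.seed(as.integer(seed))

  pop <- x$truth$population
  sp0 <- default_state_params()
  state_row <- function(nm, st) {
    sp <- if (nm %in% names(population_specs))
      population_specs[[nm]]$state_params else sp0
    sp[sp$state == st, , drop = FALSE]
  }

  cd107_pos <- rep(FALSE, n)
  if (isTRUE(spec$response_induction) && n > 0L) {
    fl <- intersect(c("CD107a", "IFNg", "TNF"), x$panel$marker)
    for (nm in unique(pop)) {
      rows <- which(pop == nm)
      pspec <- population_specs[[nm]]
      probs <- if (!is.null(pspec)) pspec$response_probs[[spec$kind]] else NULL
      if (is.null(probs)) next
      for (m in fl) {
        p <- probs[[m]]
        if (is.null(p) || p <= 0) next
        hit <- rows[stats::rbinom(length(rows), 1L, p) == 1L]
        if (!length(hit)) next
        st <- state_row(nm, "pos")
        ex[hit, m] <- asinh_inverse(
          stats::rnorm(length(hit), st$location, st$scale), x$cofactor)
        if (m == "CD107a") cd107_pos[hit] <- TRUE
      }
    }
  }

  for (m in names(spec$mfi_scale)) {
    ex[, m] <- ex[, m] * spec$mfi_scale[[m]]
  }

  if (spec$shed_fraction > 0 && n > 0L && "CD16" %in% x$panel$marker) {
    susceptible <- vapply(population_specs, `[[`, TRUE,
                          "cd16_shed_susceptible")
    sus_rows <- which(pop %in% names(susceptible)[susceptible])
    if (length(sus_rows)) {
      p <- rep(spec$shed_fraction, length(sus_rows))
      p[cd107_pos[sus_rows]] <- pmin(
        1, p[cd107_pos[sus_rows]] * spec$responder_shed_multiplier)
      shed <- sus_rows[stats::rbinom(length(sus_rows), 1L, p) == 1L]
      if (length(shed)) {
        for (nm in unique(pop[shed])) {
          rows <- shed[pop[shed] == nm]
          st <- state_row(nm, "neg")
          ex[rows, "CD16"] <- asinh_inverse(
            stats::rnorm(length(rows), st$location, st$scale), x$cofactor)
        }
      }
    }
  }

  event_table(ex, x$panel, truth = x$truth, donor_id = x$donor_id,
              condition = x$condition, cofactor = x$cofactor)
}
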