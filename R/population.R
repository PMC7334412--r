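#' Expression-state parameters on the arcsinh scale
#'
#' Each marker in each population is in one of three expression states.
#' Intensities are Gaussian on the arcsinh-transformed scale and mapped to
#' the raw scale with `sinh(x) * cofactor`. Defaults: negative N(0, 0.25),
#' positive N(3.0, 0.4), high N(6.0, 0.4) — the high state is used for the
#' CD56-bright population, well over a decade above CD56-dim, so the
#' derived dim/bright boundary separates the two cleanly.
#'
#' @return data.frame with columns `state`, `location`, `scale`.
#' @export
default_state_params <- function() {
  data.frame(state = c("neg", "pos", "high"),
             location = c(0, 3.0, 6.0),
             scale = c(0.25, 0.4, 0.4),
             stringsAsFactors = FALSE)
}

#' Define one simulated cell population
#'
#' @param name population label.
#' @param abundance expected fraction of events in `[0, 1]`.
#' @param positive character vector of markers in the positive state.
#' @param high character vector of markers in the high state (e.g. CD56 on
#'   CD56-bright NK cells).
#' @param fsc_location,fsc_scale forward-scatter mean and SD (raw units).
#' @param eomes_pos_prob probability that an event of this population is
#'   truly Eomes-positive.
#' @param response_probs named list: stimulus name -> named numeric vector
#'   of per-marker response probabilities (CD107a, IFNg, TNF).
#' @param cd16_shed_susceptible can this population shed CD16 on
#'   perturbation?
#' @param lineage one of `"lymphoid"`, `"myeloid"`, `"dead"` — used only for
#'   truth-level summaries (e.g. NK fraction of viable lymphocytes).
#' @param is_nk is this a bona fide NK population (truth-level flag)?
#' @param jitter_group compartment label for donor-level abundance
#'   resampling: populations sharing a group jitter together, keeping
#'   their within-compartment proportions fixed (e.g. the CD16+ fraction
#'   of pDCs rides on the pDC compartment). Defaults to the population's
#'   own name.
#' @param state_params state location/scale table; see
#'   [default_state_params()].
#' @return object of class `population_spec`.
#' @export
population_spec <- function(name, abundance, positive = character(),
                            high = character(),
                            fsc_location = 50000, fsc_scale = 6000,
                            eomes_pos_prob = 0,
                            response_probs = list(),
                            cd16_shed_susceptible = FALSE,
                            lineage = c("lymphoid", "myeloid", "dead"),
                            is_nk = FALSE,
                            jitter_group = name,
                            state_params = default_state_params()) {
  lineage <- match.arg(lineage)
  stopifnot(is.numeric(abundance), abundance >= 0, abundance <= 1,
            eomes_pos_prob >= 0, eomes_pos_prob <= 1,
            fsc_scale > 0)
  for (st in response_probs) {
    stopifnot(all(st >= 0), all(st <= 1))
  }
  pos_loc <- state_params$location[state_params$state == "pos"]
  neg_loc <- state_params$location[state_params$state == "neg"]
  if (pos_loc <= neg_loc) {
    stop("positive-state location must exceed negative-state location")
  }
  structure(list(name = name, abundance = abundance,
                 positive = positive, high = high,
                 fsc_location = fsc_location, fsc_scale = fsc_scale,
                 eomes_pos_prob = eomes_pos_prob,
                 response_probs = response_probs,
                 cd16_shed_susceptible = cd16_shed_susceptible,
                 lineage = lineage, is_nk = is_nk,
                 jitter_group = jitter_group,
                 state_params = state_params),
            class = "population_spec")
}

#' Expression state of a marker in a population
#' @param pop a [population_spec()].
#' @param marker marker name.
#' @return `"neg"`, `"pos"` or `"high"`.
#' @export
marker_state <- function(pop, marker) {
  if (marker %in% pop$high) "high" else if (marker %in% pop$positive) "pos"
  else "neg"
}

# Functional response probability defaults. CD56-dim NK respond most
# strongly; CD56-neg NK respond, but less; the NKp80+Eomes- (ILC-like)
# population barely responds. K562 targets drive degranulation (CD107a),
# IL-12+IL-18 drives cytokines (IFNg, TNF).
.resp <- function(k562, il12) {
  list(stim_K562 = c(CD107a = k562[1], IFNg = k562[2], TNF = k562[3]),
       stim_IL12_IL18 = c(CD107a = il12[1], IFNg = il12[2], TNF = il12[3]))
}

#' Default healthy-donor PBMC population specifications
#'
#' Seventeen populations emulating a stained PBMC sample: the three
#' dumped lineages (T, B, monocytes), the CD123+ pDC and basophil
#' contaminants that plague CD16-based CD56-negative gates (each with a
#' minor CD16+ fraction, modelled as its own population because markers
#' are single-state), the NK compartment (CD56-bright, CD56-dim CD16+/-,
#' CD56-neg CD16+/-), a minor NKp80+Eomes- ILC-like population, a
#' CD16+CD123- monocyte-like contaminant that escapes the CD14 dump,
#' lineage-negative other lymphocytes, and dead cells. Abundances are
#' expected fractions of all acquired events and sum to 1.
#'
#' The composition is calibrated so that, after automated gating, the
#' CD56-neg NKp80+ gate contains about 20% Eomes-negative events, the
#' CD56-neg CD16+NKp80- quadrant contains about 50% CD123+ events and is
#' comparable in size to the other two quadrants, about half of CD56-neg
#' NKp80+ cells co-express CD16, and NK cells make up 5-15% of viable
#' lymphocytes. The NKp80+Eomes- population is split into CD16+ and
#' CD16- halves in the same ratio as the Eomes+ CD56-neg NK cells, so
#' that every gate drawn on the NKp80+/CD7+ lymphoid pool has the same
#' expected Eomes- fraction regardless of its CD16 requirement.
#'
#' @return named list of [population_spec()] objects.
#' @export
hd_population_specs <- function() {
  nk_markers <- c("NKp80", "CD7", "CD300a", "2B4")
  specs <- list(
    population_spec("Tcell", 0.45, positive = c("CD3", "CD7")),
    population_spec("Bcell", 0.08, positive = c("CD19", "CD300a")),
    population_spec("Monocyte", 0.12,
                    positive = c("CD14", "CD300a", "2B4"),
                    fsc_location = 90000, fsc_scale = 9000,
                    lineage = "myeloid"),
    population_spec("pDC", 0.00645, positive = c("CD123", "CD300a"),
                    fsc_location = 72000, fsc_scale = 8000,
                    lineage = "myeloid"),
    population_spec("pDC_CD16pos", 0.00055,
                    positive = c("CD123", "CD16", "CD300a"),
                    fsc_location = 72000, fsc_scale = 8000,
                    lineage = "myeloid", jitter_group = "pDC"),
    population_spec("Basophil", 0.00745,
                    positive = c("CD123", "CD300a", "2B4"),
                    fsc_location = 68000, fsc_scale = 8000,
                    lineage = "myeloid"),
    population_spec("Basophil_CD16pos", 0.00055,
                    positive = c("CD123", "CD16", "CD300a", "2B4"),
                    fsc_location = 68000, fsc_scale = 8000,
                    lineage = "myeloid", jitter_group = "Basophil"),
    population_spec("NK_bright", 0.008,
                    positive = nk_markers, high = "CD56",
                    eomes_pos_prob = 0.98, is_nk = TRUE,
                    cd16_shed_susceptible = TRUE,
                    response_probs = .resp(c(0.10, 0.08, 0.06),
                                           c(0.08, 0.70, 0.35))),
    population_spec("NK_dim_CD16pos", 0.072,
                    positive = c("CD56", "CD16", nk_markers),
                    jitter_group = "NK_dim",
                    eomes_pos_prob = 0.98, is_nk = TRUE,
                    cd16_shed_susceptible = TRUE,
                    response_probs = .resp(c(0.45, 0.20, 0.18),
                                           c(0.12, 0.55, 0.30))),
    population_spec("NK_dim_CD16neg", 0.006,
                    positive = c("CD56", nk_markers),
                    jitter_group = "NK_dim",
                    eomes_pos_prob = 0.98, is_nk = TRUE,
                    cd16_shed_susceptible = TRUE,
                    response_probs = .resp(c(0.45, 0.20, 0.18),
                                           c(0.12, 0.55, 0.30))),
    population_spec("NK_neg_CD16pos", 0.00175,
                    jitter_group = "CD56neg_NKp80pos",
                    positive = c("CD16", nk_markers),
                    eomes_pos_prob = 0.98, is_nk = TRUE,
                    cd16_shed_susceptible = TRUE,
                    response_probs = .resp(c(0.20, 0.10, 0.08),
                                           c(0.06, 0.28, 0.15))),
    population_spec("NK_neg_CD16neg", 0.00175,
                    jitter_group = "CD56neg_NKp80pos",
                    positive = nk_markers,
                    eomes_pos_prob = 0.98, is_nk = TRUE,
                    cd16_shed_susceptible = TRUE,
                    response_probs = .resp(c(0.20, 0.10, 0.08),
                                           c(0.06, 0.28, 0.15))),
    population_spec("NKp80pos_EomesNeg_CD16pos", 0.00045,
                    jitter_group = "CD56neg_NKp80pos",
                    positive = c("CD16", nk_markers),
                    eomes_pos_prob = 0,
                    cd16_shed_susceptible = TRUE,
                    response_probs = .resp(c(0.02, 0.02, 0.02),
                                           c(0.02, 0.02, 0.02))),
    population_spec("NKp80pos_EomesNeg_CD16neg", 0.00045,
                    jitter_group = "CD56neg_NKp80pos",
                    positive = nk_markers,
                    eomes_pos_prob = 0,
                    response_probs = .resp(c(0.02, 0.02, 0.02),
                                           c(0.02, 0.02, 0.02))),
    population_spec("Other_CD16pos", 0.0011,
                    positive = c("CD16", "CD300a", "2B4"),
                    fsc_location = 66000, fsc_scale = 8000,
                    lineage = "myeloid", jitter_group = "Monocyte"),
    population_spec("Other", 0.1935, positive = "CD7"),
    population_spec("Dead", 0.05, positive = "Viability",
                    fsc_location = 42000, fsc_scale = 7000,
                    lineage = "dead")
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  validate_population_specs(specs)
  specs
}

#' Validate a set of population specifications
#'
#' Checks that abundances sum to 1 within 1e-9 and that each spec is
#' internally consistent.
#'
#' @param specs named list of [population_spec()] objects.
#' @return `specs`, invisibly, or an error.
#' @export
validate_population_specs <- function(specs) {
  ab <- vapply(specs, `[[`, 0, "abundance")
  if (abs(sum(ab) - 1) > 1e-9) {
    stop("population abundances must sum to 1 (got ",
         format(sum(ab), digits = 12), ")")
  }
  invisible(specs)
}

#' Disease-condition presets for population composition
#'
#' Conditions rescale the abundance of the Eomes+ CD56-negative NK
#' populations relative to healthy donors (HD): untreated HIV x12,
#' HIV under cART x4, multiple myeloma x4 — the expansion is largest in
#' untreated HIV, with cART and myeloma intermediate. All abundances are
#' renormalised to sum to 1.
#'
#' @param condition one of `"HD"`, `"HIV_untreated"`, `"HIV_cART"`, `"MM"`.
#' @return named list of [population_spec()] objects.
#' @export
preset_population_specs <- function(condition = c("HD", "HIV_untreated",
                                                  "HIV_cART", "MM")) {
  condition <- match.arg(condition)
  specs <- hd_population_specs()
  mult <- switch(condition, HD = 1, HIV_untreated = 12, HIV_cART = 4,
                 MM = 4)
  if (mult != 1) {
    expand <- c("NK_neg_CD16pos", "NK_neg_CD16neg")
    for (nm in expand) specs[[nm]]$abundance <- specs[[nm]]$abundance * mult
    tot <- sum(vapply(specs, `[[`, 0, "abundance"))
    for (nm in names(specs)) specs[[nm]]$abundance <- specs[[nm]]$abundance / tot
  }
  validate_population_specs(specs)
  specs
}
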