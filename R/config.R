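#' Read a cohort configuration from a YAML file
#'
#' Recognised keys: `condition`, `n_donors`, `n_events`, `seed`,
#' `abundance_jitter`, and an optional `abundance_overrides` map of
#' population name to abundance (remaining abundances are rescaled so the
#' total stays 1).
#'
#' @param path path to the YAML file.
#' @return a [cohort_config()].
#' @export
read_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  specs <- NULL
  condition <- y$condition %||% "HD"
  if (!is.null(y$abundance_overrides)) {
    specs <- preset_population_specs(condition)
    ov <- y$abundance_overrides
    unknown <- setdiff(names(ov), names(specs))
    if (length(unknown)) {
      stop("abundance_overrides name unknown populations: ",
           paste(unknown, collapse = ", "))
    }
    fixed <- sum(unlist(ov))
    rest <- setdiff(names(specs), names(ov))
    rest_total <- sum(vapply(specs[rest], `[[`, 0, "abundance"))
    scale <- (1 - fixed) / rest_total
    for (nm in names(ov)) specs[[nm]]$abundance <- ov[[nm]]
    for (nm in rest) specs[[nm]]$abundance <- specs[[nm]]$abundance * scale
    validate_population_specs(specs)
  }
  cohort_config(condition = condition,
                n_donors = y$n_donors %||% 20,
                n_events = y$n_events %||% 50000,
                seed = y$seed %||% 42,
                abundance_jitter = y$abundance_jitter %||% 2000,
                population_specs = specs)
}

#' Write a cohort manifest as YAML
#'
#' Records every resolved generation parameter, including the per-donor
#' seeds, so a cohort can be regenerated exactly.
#'
#' @param cohort an `nk_cohort`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(cohort, path) {
  yaml::write_yaml(cohort$manifest, path)
  invisible(path)
}
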