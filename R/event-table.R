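#' Panel definition: channels, markers and roles
#'
#' A panel maps short channel identifiers to marker names and declares each
#' channel's role: `"scatter"` (kept on the raw scale, e.g. FSC-A),
#' `"fluorescence"` (arcsinh-transformed before thresholding) or `"truth"`
#' (simulation-only ground-truth channels that never enter gating).
#'
#' @param channel_id character vector of unique short channel names.
#' @param marker character vector of marker names (CD3, CD56, NKp80, ...).
#' @param role character vector, one of `"scatter"`, `"fluorescence"`,
#'   `"truth"`.
#' @return a `data.frame` of class `nk_panel`.
#' @export
nk_panel <- function(channel_id, marker, role) {
  stopifnot(length(channel_id) == length(marker),
            length(marker) == length(role))
  role <- match.arg(role, c("scatter", "fluorescence", "truth"),
                    several.ok = TRUE)
  if (anyDuplicated(channel_id)) {
    stop("channel_ids must be unique within a panel")
  }
  if (anyDuplicated(marker)) {
    stop("markers must be unique within a panel")
  }
  out <- data.frame(channel_id = as.character(channel_id),
                    marker = as.character(marker),
                    role = role,
                    stringsAsFactors = FALSE)
  class(out) <- c("nk_panel", "data.frame")
  out
}

#' Default 16-channel NK immunophenotyping panel
#'
#' Lineage/dump markers (Viability, CD3, CD14, CD19), the NK subsetting
#' markers (CD56, CD16, NKp80) and alternatives (CD7, CD300a, 2B4),
#' the contamination marker CD123, the intracellular NK identity marker
#' Eomes, functional readouts (CD107a, IFNg, TNF), and forward scatter.
#'
#' @return an [nk_panel()].
#' @export
default_panel <- function() {
  markers <- c("FSC-A", "Viability", "CD3", "CD14", "CD19", "CD56", "CD16",
               "NKp80", "CD7", "CD300a", "2B4", "CD123", "Eomes",
               "CD107a", "IFNg", "TNF")
  role <- c("scatter", rep("fluorescence", length(markers) - 1L))
  nk_panel(channel_id = sprintf("Ch%02d", seq_along(markers)),
           marker = markers, role = role)
}

#' Event table: the universal currency of the pipeline
#'
#' An `event_table` bundles an events-by-channels matrix of raw-scale
#' intensities with its panel metadata and, for synthetic data, per-event
#' ground-truth labels (sampled population and Eomes truth state).
#'
#' @param exprs numeric matrix, events in rows, one column per panel channel
#'   (raw scale). Column names must equal the panel's markers.
#' @param panel an [nk_panel()].
#' @param truth optional `data.frame` with columns `population` (character)
#'   and `eomes_truth` (0/1 integer), one row per event.
#' @param donor_id,condition optional character scalars recorded as metadata.
#' @param cofactor arcsinh cofactor used for this table's fluorescence
#'   channels.
#' @return object of class `event_table`.
#' @export
event_table <- function(exprs, panel, truth = NULL, donor_id = NA_character_,
                        condition = NA_character_, cofactor = 150) {
  stopifnot(is.matrix(exprs), is.numeric(exprs) || nrow(exprs) == 0L)
  if (!identical(colnames(exprs), panel$marker)) {
    stop("exprs columns must match panel markers in order")
  }
  if (!is.null(truth)) {
    stopifnot(is.data.frame(truth), nrow(truth) == nrow(exprs),
              all(c("population", "eomes_truth") %in% names(truth)))
  }
  structure(list(exprs = exprs, panel = panel, truth = truth,
                 donor_id = donor_id, condition = condition,
                 cofactor = cofactor),
            class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat("<event_table> ", nrow(x$exprs), " events x ", ncol(x$exprs),
      " channels", sep = "")
  if (!is.na(x$donor_id)) cat("  donor:", x$donor_id)
  if (!is.na(x$condition)) cat("  condition:", x$condition)
  cat("\n  markers:", paste(x$panel$marker, collapse = ", "), "\n")
  if (!is.null(x$truth)) {
    tab <- sort(table(x$truth$population), decreasing = TRUE)
    cat("  truth populations:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.event_table <- function(x) dim(x$exprs)

#' Number of events in an event table
#' @param x an `event_table`.
#' @return integer event count.
#' @export
n_events <- function(x) nrow(x$exprs)

#' Extract one marker's intensities
#'
#' @param x an `event_table`.
#' @param marker marker name present in the panel.
#' @param transformed if `TRUE`, fluorescence channels are returned on the
#'   arcsinh scale (scatter and truth channels are never transformed).
#' @return numeric vector, one value per event.
#' @export
marker_values <- function(x, marker, transformed = FALSE) {
  stopifnot(inherits(x, "event_table"))
  idx <- match(marker, x$panel$marker)
  if (is.na(idx)) {
    stop("marker '", marker, "' is not in the panel", call. = FALSE)
  }
  v <- unname(x$exprs[, idx])
  if (transformed && x$panel$role[idx] == "fluorescence") {
    v <- asinh_transform(v, x$cofactor)
  }
  v
}

#' Subset an event table by row
#'
#' @param x an `event_table`.
#' @param i logical or integer row index.
#' @return an `event_table` containing the selected events.
#' @export
subset_events <- function(x, i) {
  stopifnot(inherits(x, "event_table"))
  ex <- x$exprs[i, , drop = FALSE]
  tr <- if (is.null(x$truth)) NULL else x$truth[i, , drop = FALSE]
  event_table(ex, x$panel, truth = tr, donor_id = x$donor_id,
              condition = x$condition, cofactor = x$cofactor)
}
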