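#' Gate predicate nodes
#'
#' A gating strategy is a rooted tree of predicates over per-marker
#' cutoffs. Leaf nodes test one marker against its threshold; `gate_and`,
#' `gate_or` and `gate_not` combine child predicates. Events with a value
#' exactly at a cutoff classify as negative (deterministic, conservative).
#'
#' @param marker marker name.
#' @param polarity `"positive"` (above cutoff), `"negative"` (at or below
#'   cutoff), or — for markers carrying a second, upper cutoff such as
#'   CD56 — `"dim"` (between the cutoffs) or `"bright"` (above the upper
#'   cutoff).
#' @return a gate node (class `gate_node`).
#' @export
gate <- function(marker, polarity = c("positive", "negative", "dim",
                                      "bright")) {
  polarity <- match.arg(polarity)
  structure(list(type = "marker", marker = marker, polarity = polarity),
            class = "gate_node")
}

#' @rdname gate
#' @param ... child gate nodes.
#' @export
gate_and <- function(...) {
  structure(list(type = "and", children = list(...)), class = "gate_node")
}

#' @rdname gate
#' @export
gate_or <- function(...) {
  structure(list(type = "or", children = list(...)), class = "gate_node")
}

#' @rdname gate
#' @param node child gate node.
#' @export
gate_not <- function(node) {
  structure(list(type = "not", children = list(node)), class = "gate_node")
}

gate_markers <- function(node) {
  if (node$type == "marker") return(node$marker)
  unique(unlist(lapply(node$children, gate_markers)))
}

#' Define a gating strategy
#'
#' A strategy has an exclusion stage — events positive for any dump
#' marker (viability dye, CD3, CD14, CD19, optionally CD123) are removed —
#' followed by named subset predicates evaluated on the remaining events.
#' Subset predicates are written from the root, so a subset whose
#' predicate strengthens another subset's predicate is automatically
#' nested within it.
#'
#' @param name strategy name.
#' @param subsets named list of gate nodes.
#' @param exclusion character vector of dump markers.
#' @param target name of the strategy's subset of interest.
#' @param parent name of the subset serving as the frequency denominator
#'   for `target` (must be one of `names(subsets)` or `"viable"`).
#' @param scatter_range optional `c(min, max)` pre-gate on FSC-A (raw
#'   scale); `NULL` disables scatter pre-gating.
#' @return object of class `nk_strategy`.
#' @export
gating_strategy <- function(name, subsets,
                            exclusion = c("Viability", "CD3", "CD14",
                                          "CD19"),
                            target = names(subsets)[length(subsets)],
                            parent = "viable",
                            scatter_range = NULL) {
  stopifnot(is.list(subsets), length(names(subsets)) == length(subsets))
  structure(list(name = name, exclusion = exclusion, subsets = subsets,
                 target = target, parent = parent,
                 scatter_range = scatter_range),
            class = "nk_strategy")
}

#' @export
print.nk_strategy <- function(x, ...) {
  cat("<nk_strategy> ", x$name, "\n  exclusion: ",
      paste(x$exclusion, collapse = ", "), "\n  subsets: ",
      paste(names(x$subsets), collapse = ", "),
      "\n  target: ", x$target, " (parent: ", x$parent, ")\n", sep = "")
  invisible(x)
}

eval_gate_node <- function(node, tv, high_cutoffs, thresholds) {
  if (node$type == "marker") {
    v <- tv[[node$marker]]
    cut <- thresholds[[node$marker]]$cutoff
    return(switch(node$polarity,
      positive = v > cut,
      negative = v <= cut,
      dim = {
        hc <- high_cutoffs[[node$marker]]
        if (is.null(hc)) stop("marker '", node$marker,
                              "' has no upper cutoff for 'dim'")
        v > cut & v <= hc
      },
      bright = {
        hc <- high_cutoffs[[node$marker]]
        if (is.null(hc)) stop("marker '", node$marker,
                              "' has no upper cutoff for 'bright'")
        v > hc
      }))
  }
  kids <- lapply(node$children, eval_gate_node, tv = tv,
                 high_cutoffs = high_cutoffs, thresholds = thresholds)
  switch(node$type,
         and = Reduce(`&`, kids),
         or = Reduce(`|`, kids),
         not = !kids[[1]])
}

#' Evaluate a gating strategy on an event table
#'
#' @param x an [event_table()].
#' @param strategy an [nk_strategy()].
#' @param thresholds an `nk_thresholds` object from
#'   [estimate_panel_thresholds()] covering every marker the strategy
#'   references.
#' @return named list of per-event logical membership vectors: `"viable"`
#'   (events surviving the exclusion stage and any scatter pre-gate) plus
#'   one entry per strategy subset.
#' @export
apply_strategy <- function(x, strategy, thresholds) {
  stopifnot(inherits(x, "event_table"), inherits(strategy, "nk_strategy"))
  needed <- unique(c(strategy$exclusion,
                     unlist(lapply(strategy$subsets, gate_markers))))
  missing <- setdiff(needed, names(thresholds))
  if (length(missing)) {
    stop("missing thresholds for markers: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(needed, x$panel$marker)
  if (length(absent)) {
    stop("strategy references markers absent from the panel: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  n <- n_events(x)
  tv <- stats::setNames(
    lapply(needed, function(m) marker_values(x, m, transformed = TRUE)),
    needed)
  high_cutoffs <- attr(thresholds, "high_cutoffs")

  included <- rep(TRUE, n)
  for (m in strategy$exclusion) {
    included <- included & (tv[[m]] <= thresholds[[m]]$cutoff)
  }
  if (!is.null(strategy$scatter_range) && "FSC-A" %in% x$panel$marker) {
    fsc <- marker_values(x, "FSC-A")
    included <- included & fsc >= strategy$scatter_range[1] &
      fsc <= strategy$scatter_range[2]
  }
  out <- list(viable = included)
  for (nm in names(strategy$subsets)) {
    out[[nm]] <- included &
      eval_gate_node(strategy$subsets[[nm]], tv, high_cutoffs, thresholds)
  }
  out
}

#' Built-in gating strategies
#'
#' The registry holds the NKp80-based strategy, the classical CD16-based
#' strategy, the alternative-marker strategies (CD7+CD16, CD7 only,
#' CD300a, 2B4), the CD16 x NKp80 quadrant decomposition of CD56-negative
#' events, the CD56-dim reference subset, and an NK-reference gate
#' (NKp80-positive or CD56-positive after exclusion) used as the
#' "total NK" denominator. Every strategy exists in two variants:
#' standard exclusion (Viability/CD3/CD14/CD19) and, under the key suffix
#' `"_cd123excl"`, exclusion extended with CD123 (removing pDC- and
#' basophil-like events before subsetting).
#'
#' @return named list of [gating_strategy()] objects.
#' @export
builtin_strategies <- function() {
  cd56neg <- gate("CD56", "negative")
  base <- list(
    cd16 = gating_strategy("cd16", list(
      CD56neg = cd56neg,
      target = gate_and(cd56neg, gate("CD16", "positive"))),
      target = "target", parent = "CD56neg"),
    nkp80 = gating_strategy("nkp80", list(
      CD56neg = cd56neg,
      target = gate_and(cd56neg, gate("NKp80", "positive"))),
      target = "target", parent = "CD56neg"),
    cd7_cd16 = gating_strategy("cd7_cd16", list(
      CD56neg = cd56neg,
      target = gate_and(cd56neg, gate("CD7", "positive"),
                        gate("CD16", "positive"))),
      target = "target", parent = "CD56neg"),
    cd7_only = gating_strategy("cd7_only", list(
      CD56neg = cd56neg,
      target = gate_and(cd56neg, gate("CD7", "positive"))),
      target = "target", parent = "CD56neg"),
    cd300a = gating_strategy("cd300a", list(
      CD56neg = cd56neg,
      target = gate_and(cd56neg, gate("CD300a", "positive"))),
      target = "target", parent = "CD56neg"),
    tb4 = gating_strategy("tb4", list(
      CD56neg = cd56neg,
      target = gate_and(cd56neg, gate("2B4", "positive"))),
      target = "target", parent = "CD56neg"),
    quadrants = gating_strategy("quadrants", list(
      CD56neg = cd56neg,
      CD16pos_NKp80neg = gate_and(cd56neg, gate("CD16", "positive"),
                                  gate("NKp80", "negative")),
      CD16neg_NKp80pos = gate_and(cd56neg, gate("CD16", "negative"),
                                  gate("NKp80", "positive")),
      CD16pos_NKp80pos = gate_and(cd56neg, gate("CD16", "positive"),
                                  gate("NKp80", "positive")),
      CD16neg_NKp80neg = gate_and(cd56neg, gate("CD16", "negative"),
                                  gate("NKp80", "negative"))),
      target = "CD16pos_NKp80neg", parent = "CD56neg"),
    cd56dim = gating_strategy("cd56dim", list(
      target = gate("CD56", "dim")),
      target = "target", parent = "viable"),
    nk_ref = gating_strategy("nk_ref", list(
      NK = gate_or(gate("NKp80", "positive"), gate("CD56", "dim"),
                   gate("CD56", "bright"))),
      target = "NK", parent = "viable")
  )
  out <- base
  for (nm in names(base)) {
    s <- base[[nm]]
    s$name <- paste0(s$name, "_cd123excl")
    s$exclusion <- c(s$exclusion, "CD123")
    out[[paste0(nm, "_cd123excl")]] <- s
  }
  out
}

#' Look up a built-in strategy by name
#'
#' @param name registry key, e.g. `"nkp80"` or `"cd16_cd123excl"`.
#' @return an [gating_strategy()] object.
#' @export
get_strategy <- function(name) {
  reg <- builtin_strategies()
  if (!name %in% names(reg)) {
    stop("unknown strategy '", name, "'; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  reg[[name]]
}

# ---- structured-text strategy definitions (YAML) ----

parse_gate_node <- function(node) {
  if (!is.null(node$marker)) {
    return(gate(node$marker, node$polarity))
  }
  combiner <- intersect(names(node), c("and", "or", "not"))
  if (length(combiner) != 1L) {
    stop("gate node must have 'marker' or exactly one of and/or/not")
  }
  kids <- lapply(node[[combiner]], parse_gate_node)
  switch(combiner,
         and = do.call(gate_and, kids),
         or = do.call(gate_or, kids),
         not = gate_not(kids[[1]]))
}

#' Read a gating strategy from a YAML file
#'
#' The file carries `name`, `exclusion` (list of markers), `subsets`
#' (map of subset name to a predicate tree of `marker`/`polarity` leaves
#' and `and`/`or`/`not` combiners), and optional `target`/`parent`,
#' so strategies can be added without code changes.
#'
#' @param path path to a YAML strategy definition.
#' @return an [gating_strategy()] object.
#' @export
read_strategy <- function(path) {
  y <- yaml::read_yaml(path)
  subsets <- lapply(y$subsets, parse_gate_node)
  gating_strategy(
    name = y$name, subsets = subsets,
    exclusion = if (is.null(y$exclusion))
      c("Viability", "CD3", "CD14", "CD19") else unlist(y$exclusion),
    target = if (is.null(y$target)) names(subsets)[length(subsets)]
             else y$target,
    parent = if (is.null(y$parent)) "viable" else y$parent)
}
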