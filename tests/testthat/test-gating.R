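# transformed-scale layout of the six hand events:
#   e1 viable CD56- CD16+  NKp80-   e4 dead (viability+)
#   e2 viable CD56- CD16@cutoff (tie -> negative) NKp80+
#   e3 viable CD56dim CD16+ NKp80+  e5 CD3+ (excluded)
#   e6 viable CD56bright NKp80+
hand_table <- function() {
  make_table(list(
    `FSC-A` = rep(5e4, 6),
    Viability = raw(c(0, 0, 0, 3, 0, 0)),
    CD3 = raw(c(0, 0, 0, 0, 3, 0)),
    CD56 = raw(c(0, 0, 3, 0, 0, 5)),
    CD16 = raw(c(3, 1.5, 3, 3, 3, 0)),
    NKp80 = raw(c(0, 3, 3, 0, 0, 3))))
}

hand_thresholds <- function() {
  manual_thresholds(list(Viability = 1.5, CD3 = 1.5, CD56 = 1.5,
                         CD16 = 1.5, NKp80 = 1.5),
                    high_cutoffs = c(CD56 = 4.5))
}

test_that("hand-evaluated memberships match apply_strategy, with ties
          classifying negative", {
  x <- hand_table()
  th <- hand_thresholds()
  strat <- gating_strategy("nkp80", list(
    CD56neg = gate("CD56", "negative"),
    target = gate_and(gate("CD56", "negative"),
                      gate("NKp80", "positive"))),
    exclusion = c("Viability", "CD3"))
  mem <- apply_strategy(x, strat, th)
  expect_identical(mem$viable, c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_identical(mem$CD56neg, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_identical(mem$target, c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))

  cd16 <- gating_strategy("cd16", list(
    target = gate_and(gate("CD56", "negative"),
                      gate("CD16", "positive"))),
    exclusion = c("Viability", "CD3"))
  m2 <- apply_strategy(x, cd16, th)
  # e2's CD16 sits exactly at the cutoff: a tie is negative
  expect_identical(m2$target, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))

  dimb <- gating_strategy("dim", list(
    dim = gate("CD56", "dim"), bright = gate("CD56", "bright")),
    exclusion = c("Viability", "CD3"))
  m3 <- apply_strategy(x, dimb, th)
  expect_identical(which(m3$dim), 3L)
  expect_identical(which(m3$bright), 6L)
})

test_that("empty tables gate without error and dump-positive events are
          in no subset", {
  x0 <- subset_events(hand_table(), integer(0))
  strat0 <- gating_strategy("s0", list(
    CD56neg = gate("CD56", "negative"),
    target = gate_and(gate("CD56", "negative"),
                      gate("NKp80", "positive"))),
    exclusion = c("Viability", "CD3"))
  mem <- apply_strategy(x0, strat0, hand_thresholds())
  expect_identical(lengths(mem), c(viable = 0L, CD56neg = 0L,
                                   target = 0L))

  x <- hand_table()
  th <- hand_thresholds()
  strat <- gating_strategy("s", list(
    a = gate("CD56", "negative"), b = gate("NKp80", "positive")),
    exclusion = c("Viability", "CD3"))
  mem <- apply_strategy(x, strat, th)
  for (nm in names(mem)) expect_false(mem[[nm]][4])
})

test_that("missing thresholds and unknown panel markers are errors", {
  x <- hand_table()
  strat <- gating_strategy("s", list(t = gate("CD56", "negative")),
                           exclusion = c("Viability", "CD3"))
  expect_error(apply_strategy(x, strat,
                              manual_thresholds(list(CD56 = 1.5))),
               "missing thresholds.*Viability")
  strat2 <- gating_strategy("s2", list(t = gate("CD99", "positive")),
                            exclusion = "Viability")
  expect_error(
    apply_strategy(x, strat2,
                   manual_thresholds(list(Viability = 1.5, CD99 = 1))),
    "absent from the panel")
})

test_that("vectorised gating matches the per-event interpreter on random
          tables", {
  reg <- builtin_strategies()
  th <- random_thresholds()
  set.seed(101)
  for (trial in 1:200) {
    x <- random_table(sample(0:50, 1))
    strat <- reg[[sample(names(reg), 1)]]
    got <- apply_strategy(x, strat, th)
    want <- interpret_strategy(x, strat, th)
    expect_identical(got, want)
  }
})

test_that("gate nesting: every subset is contained in the viable gate
          and conjunctions nest", {
  th <- random_thresholds()
  set.seed(55)
  for (trial in 1:20) {
    x <- random_table(200)
    for (strat in builtin_strategies()) {
      mem <- apply_strategy(x, strat, th)
      for (nm in names(strat$subsets)) {
        expect_true(all(!mem[[nm]] | mem$viable))
      }
      if ("CD56neg" %in% names(mem)) {
        others <- setdiff(names(strat$subsets), "CD56neg")
        for (nm in others) {
          expect_true(all(!mem[[nm]] | mem$CD56neg))
        }
      }
    }
  }
})

test_that("the CD16xNKp80 quadrants partition the CD56neg gate", {
  th <- random_thresholds()
  set.seed(77)
  x <- random_table(500)
  mem <- apply_strategy(x, get_strategy("quadrants"), th)
  quads <- c("CD16pos_NKp80neg", "CD16neg_NKp80pos", "CD16pos_NKp80pos",
             "CD16neg_NKp80neg")
  counts <- Reduce(`+`, lapply(quads, function(q) as.integer(mem[[q]])))
  expect_identical(counts, as.integer(mem$CD56neg))
})

test_that("the strategy registry contains the documented gates in both
          exclusion variants", {
  reg <- builtin_strategies()
  base <- c("cd16", "nkp80", "cd7_cd16", "cd7_only", "cd300a", "tb4",
            "quadrants", "cd56dim")
  expect_true(all(base %in% names(reg)))
  expect_true(all(paste0(base, "_cd123excl") %in% names(reg)))
  expect_true("CD123" %in% reg$nkp80_cd123excl$exclusion)
  expect_false("CD123" %in% reg$nkp80$exclusion)
  expect_error(get_strategy("does_not_exist"), "unknown strategy")

  # nkp80 semantics: CD56-negative AND NKp80-positive after exclusion
  x <- make_table(list(
    `FSC-A` = rep(5e4, 3), Viability = raw(c(0, 0, 3)),
    CD3 = raw(c(0, 0, 0)), CD14 = raw(c(0, 0, 0)),
    CD19 = raw(c(0, 0, 0)), CD56 = raw(c(0, 3, 0)),
    CD16 = raw(c(0, 0, 0)), NKp80 = raw(c(3, 3, 3))),
    panel = tiny_panel(c("FSC-A", "Viability", "CD3", "CD14", "CD19",
                         "CD56", "CD16", "NKp80")))
  th <- manual_thresholds(list(Viability = 1.5, CD3 = 1.5, CD14 = 1.5,
                               CD19 = 1.5, CD56 = 1.5, CD16 = 1.5,
                               NKp80 = 1.5))
  mem <- apply_strategy(x, get_strategy("nkp80"), th)
  expect_identical(mem$target, c(TRUE, FALSE, FALSE))
})

test_that("strategies round-trip through the YAML text format", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "name: custom_nkp80",
    "exclusion: [Viability, CD3]",
    "target: hit",
    "parent: neg",
    "subsets:",
    "  neg:",
    "    marker: CD56",
    "    polarity: negative",
    "  hit:",
    "    and:",
    "      - {marker: CD56, polarity: negative}",
    "      - {marker: NKp80, polarity: positive}"), path)
  strat <- read_strategy(path)
  expect_identical(strat$name, "custom_nkp80")
  expect_identical(strat$target, "hit")
  x <- hand_table()
  mem <- apply_strategy(x, strat, hand_thresholds())
  expect_identical(mem$hit, c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
})
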