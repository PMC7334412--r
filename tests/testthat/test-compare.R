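test_that("identical paired vectors yield an undefined p with all zeros
          dropped", {
  cc <- paired_compare(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_true(is.na(cc$p_value))
  expect_identical(cc$n_zero, 4L)
  expect_identical(cc$direction, "none")
  expect_identical(cc$effect, 0)
})

test_that("five concordant pairs give the exact two-sided p of 2/32", {
  a <- c(1, 2, 3, 4, 5)
  b <- a + c(0.5, 1.1, 0.7, 2.2, 0.9)
  cc <- paired_compare(a, b, labels = c("A", "B"))
  expect_equal(cc$p_value, 2 / 32)
  expect_equal(cc$p_value, enum_signed_rank_p(a, b))
  expect_identical(cc$direction, "B")
})

test_that("signed-rank p-values equal sign-assignment enumeration for
          n <= 8", {
  set.seed(61)
  for (n in 3:8) {
    for (rep in 1:5) {
      a <- stats::rnorm(n)
      b <- a + stats::rnorm(n, 0.3)
      cc <- paired_compare(a, b)
      expect_equal(cc$p_value, enum_signed_rank_p(a, b),
                   tolerance = 1e-12)
    }
  }
})

test_that("Mann-Whitney matches arrangement enumeration, including the
          separated-groups case", {
  cc <- group_compare(c(1, 2, 3), c(10, 11, 12), labels = c("lo", "hi"))
  expect_equal(cc$p_value, 0.1)
  expect_equal(cc$p_value, enum_mann_whitney_p(c(1, 2, 3),
                                               c(10, 11, 12)))
  expect_identical(cc$direction, "hi")

  set.seed(71)
  for (n1 in 3:6) {
    a <- stats::rnorm(n1)
    b <- stats::rnorm(n1 + 1, 0.5)
    cc <- group_compare(a, b)
    expect_equal(cc$p_value, enum_mann_whitney_p(a, b),
                 tolerance = 1e-12)
  }
})

test_that("identical groups are not distinguishable", {
  cc <- group_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(cc$p_value, 1)
  expect_identical(cc$direction, "none")
})

test_that("p-values are symmetric in the order of the two sides", {
  set.seed(81)
  a <- stats::rnorm(10)
  b <- stats::rnorm(10, 0.5)
  expect_equal(paired_compare(a, b)$p_value,
               paired_compare(b, a)$p_value)
  expect_equal(group_compare(a, b)$p_value,
               group_compare(b, a)$p_value)
})

test_that("too few usable pairs or group members is an error", {
  expect_error(paired_compare(c(1, 2), c(2, 3)), "insufficient")
  expect_error(paired_compare(c(1, 2, NA), c(2, 3, 4)), "insufficient")
  expect_error(group_compare(c(1, 2), c(1, 2, 3)), "insufficient")
})

test_that("direction is consistent with the sign of the effect size", {
  set.seed(91)
  for (rep in 1:20) {
    a <- stats::rnorm(8)
    b <- stats::rnorm(8, sample(c(-1, 1), 1))
    cc <- paired_compare(a, b, labels = c("A", "B"))
    if (cc$effect > 0) expect_identical(cc$direction, "B")
    if (cc$effect < 0) expect_identical(cc$direction, "A")
    expect_gte(cc$p_value, 0)
    expect_lte(cc$p_value, 1)
  }
})
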