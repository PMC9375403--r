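test_that("archetype banks place item locations on the documented grids", {
  # archetype 2: locations regularly spaced between -1 and 1
  b2 <- make_archetype_bank(4, 3, archetype = 2)
  expect_equal(unname(b2$locations), c(-1, -1/3, 1/3, 1), tolerance = 1e-12)
  # archetype 1: regularly spaced between -0.25 and 0.25
  b1 <- make_archetype_bank(4, 3, archetype = 1)
  expect_equal(unname(b1$locations), c(-0.25, -0.25 + 0.5 / 3,
                                       -0.25 + 1 / 3, 0.25),
               tolerance = 1e-12)
  b10 <- make_archetype_bank(10, 5, archetype = 2)
  expect_equal(unname(b10$locations), seq(-1, 1, length.out = 10),
               tolerance = 1e-12)
})

test_that("archetype thresholds are normal-percentile offsets around the location", {
  # 5 categories, archetype 2: offsets 1.5 * qnorm(0.2, 0.4, 0.6, 0.8)
  b <- make_archetype_bank(7, 5, archetype = 2)
  off <- sweep(b$thresholds, 1, b$locations)
  for (j in 1:7)
    expect_equal(unname(off[j, ]),
                 c(-1.2624319, -0.3800207, 0.3800207, 1.2624319),
                 tolerance = 1e-6)
  # 3 categories, archetype 1: offsets 2.5 * qnorm(1/3, 2/3)
  b3 <- make_archetype_bank(4, 3, archetype = 1)
  off3 <- sweep(b3$thresholds, 1, b3$locations)
  expect_equal(unname(off3[2, ]), 2.5 * qnorm(c(1, 2) / 3), tolerance = 1e-12)
})

test_that("archetype banks satisfy their structural invariants", {
  for (J in c(4, 7, 10)) for (M in c(3, 5)) for (a in 1:2) {
    b <- make_archetype_bank(J, M, a)
    expect_equal(mean(b$thresholds), 0, tolerance = 1e-12)
    expect_equal(unname(b$locations), unname(rowMeans(b$thresholds)),
                 tolerance = 1e-12)
    expect_true(all(apply(b$thresholds, 1, function(r) all(diff(r) > 0))))
    # pure function of (J, M, archetype)
    expect_identical(b$thresholds, make_archetype_bank(J, M, a)$thresholds)
  }
})

test_that("the literal 0.33/0.66 percentile switch gives an asymmetric variant", {
  exact <- make_archetype_bank(4, 3, 2)
  lit <- make_archetype_bank(4, 3, 2, percentiles = "literal")
  expect_equal(mean(lit$thresholds), 0, tolerance = 1e-12)  # still centered
  expect_gt(max(abs(lit$thresholds - exact$thresholds)), 1e-3)
  # with two thresholds the centered offsets stay symmetric; the literal
  # percentiles narrow the within-item spread instead
  spread <- function(b) b$thresholds[1, 2] - b$thresholds[1, 1]
  expect_lt(spread(lit), spread(exact))
})

test_that("unsupported design parameters are rejected", {
  expect_error(make_archetype_bank(5, 3, 2), "'J'")
  expect_error(make_archetype_bank(4, 4, 2), "'M'")
  expect_error(make_archetype_bank(4, 3, 3), "archetype")
  expect_error(item_bank(matrix(c(1, Inf), 1)), "finite")
})

test_that("category probabilities follow the partial credit form", {
  expect_equal(category_probabilities(0, c(0, 0)), rep(1 / 3, 3),
               tolerance = 1e-12)
  expect_equal(category_probabilities(0, 0), c(0.5, 0.5), tolerance = 1e-12)
  # frozen direct evaluation: numerators (1, e^1.5, e^2)
  expect_equal(category_probabilities(1, c(-0.5, 0.5)),
               c(0.07769558, 0.34820743, 0.57409699), tolerance = 1e-7)
  expect_error(category_probabilities(NA, c(0, 0)), "finite")
  expect_error(category_probabilities(0, c(0, NaN)), "finite")
})

test_that("probabilities stay normalized and symmetric at extreme latent values", {
  thr <- c(-1.2, -0.1, 0.4, 1.3)
  for (theta in seq(-50, 50, by = 5)) {
    p <- category_probabilities(theta, thr)
    expect_true(all(is.finite(p)))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    # reflection: negate theta and reverse-negate thresholds
    expect_equal(rev(p), category_probabilities(-theta, rev(-thr)),
                 tolerance = 1e-12)
  }
})

test_that("expected score is monotone with the documented range and values", {
  grid <- seq(-6, 6, by = 0.25)
  for (J in c(4, 10)) for (M in c(3, 5)) for (a in 1:2) {
    b <- make_archetype_bank(J, M, a)
    es <- expected_score(grid, b)
    expect_true(all(diff(es) > 0))
    expect_true(all(es > 0 & es < J * (M - 1)))
  }
  one <- item_bank(matrix(c(-0.5, 0.5), 1))
  expect_equal(expected_score(1, one), 1.4964014, tolerance = 1e-6)
  expect_equal(expected_score(0, item_bank(matrix(c(-0.7, 0.7), 1))), 1,
               tolerance = 1e-12)
  # degenerate category limits
  b <- make_archetype_bank(4, 3, 2)
  expect_lt(expected_score(-40, b), 1e-8)
  expect_gt(expected_score(40, b), 4 * 2 - 1e-8)
})

test_that("item banks round-trip through the tabular text format", {
  b <- make_archetype_bank(7, 5, 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_item_bank(b, f)
  b2 <- read_item_bank(f)
  expect_equal(b2$thresholds, b$thresholds, tolerance = 1e-10)
  expect_equal(b2$M, b$M)
  expect_error(read_item_bank(withr::local_tempfile(lines = "a\tb\n1\t2")),
               "delta")
})
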