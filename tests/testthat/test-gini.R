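test_that("weighted Gini closed forms hold", {
  expect_equal(weighted_gini(c(3, 3, 3, 3), c(1, 5, 2, 9)), 0)
  # two-point (0, x) with equal weights: exactly 0.5 for any x > 0
  for (x in c(0.01, 1, 7, 1000)) {
    expect_equal(weighted_gini(c(0, x), c(1, 1)), 0.5)
  }
  expect_true(is.na(weighted_gini(c(0, 0), c(1, 2))))  # mean zero: undefined
  expect_error(weighted_gini(c(1, 2), c(1, -1)), class = "bp_validation_error")
  expect_error(weighted_gini(5, 1), class = "bp_validation_error")
})

test_that("weighted Gini equals the unweighted Gini on the weight-expanded vector", {
  unweighted_gini <- function(v) {
    n <- length(v)
    sum(abs(outer(v, v, "-"))) / (2 * n^2 * mean(v))
  }
  set.seed(81)
  for (i in 1:30) {
    n <- sample(3:10, 1)
    v <- runif(n, 0, 3)
    w <- sample(1:6, n, replace = TRUE)
    expect_equal(weighted_gini(v, w), unweighted_gini(rep(v, times = w)),
                 tolerance = 1e-12)
  }
})

test_that("Gini is scale invariant and increases under concentration", {
  set.seed(82)
  v <- runif(6); w <- runif(6, 0.5, 4)
  g <- weighted_gini(v, w)
  expect_equal(weighted_gini(10 * v, w), g, tolerance = 1e-12)
  expect_equal(weighted_gini(v, 3 * w), g, tolerance = 1e-12)
  # majorization probe: moving success from a poorer to a richer patch
  # (equal weights) increases dispersion
  v3 <- c(2, 3, 4)
  for (d in c(0.5, 1, 1.5)) {
    expect_gt(weighted_gini(c(2 - d / 2, 3 - d / 2, 4 + d), rep(1, 3)),
              weighted_gini(v3, rep(1, 3)))
  }
})

test_that("the prerequisite check reproduces its inputs' structure", {
  # zero-nest patches are excluded and do not affect the year's Gini
  tab <- data.frame(year = rep(1:4, each = 3),
                    patch = rep(1:3, 4),
                    n_nests = c(10, 20, 0, 10, 20, 5, 8, 16, 4, 12, 6, 3),
                    n_fledglings = c(5, 2, 0, 9, 4, 1, 3, 8, 1, 6, 2, 2))
  chk <- prerequisite_check(tab)
  expect_identical(chk$per_year$n_patches[1], 2L)
  g1 <- weighted_gini(c(5 / 10, 2 / 20), c(10, 20))
  expect_equal(chk$per_year$gini[1], g1)
  # correlation equals the textbook product-moment value
  expect_equal(chk$correlation,
               cor(chk$per_year$mean_success, chk$per_year$gini),
               tolerance = 1e-12)

  # identical patches everywhere: Gini 0, correlation undefined with warning
  flat <- data.frame(year = rep(1:3, each = 2), patch = rep(1:2, 3),
                     n_nests = 10, n_fledglings = 5)
  expect_warning(chk0 <- prerequisite_check(flat), "undefined")
  expect_true(is.na(chk0$correlation))

  expect_error(prerequisite_check(tab[tab$year == 1, ]),
               class = "bp_validation_error")
})

test_that("strongly linked patch failure produces the negative mean-Gini association", {
  set.seed(83)
  quality <- runif(28, 0.1, 1.1)
  tab <- generate_patch_table(28, 30, quality, failure_link = 0.9)
  chk <- prerequisite_check(tab)
  expect_lt(chk$correlation, -0.5)
})
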