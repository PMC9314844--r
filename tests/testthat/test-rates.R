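test_that("rate containers recycle scalars and enforce ranges", {
  r <- study_rates(28)
  expect_length(r$phi2, 27L)
  expect_length(r$pi_e, 28L)
  expect_error(demographic_rates(1.2, 0.8, 0.1, 0.4, 0.5, 0.6, 0.9, 0.7,
                                 0.2, 0.3, n_years = 5),
               class = "bp_validation_error")
  expect_error(demographic_rates(0.5, 0.8, 0.1, 0.4, 0.5, 0.6, 0.9, 0.7,
                                 -0.1, 0.3, n_years = 5),
               class = "bp_validation_error")
  expect_error(demographic_rates(c(0.5, 0.6), 0.8, 0.1, 0.4, 0.5, 0.6,
                                 0.9, 0.7, 0.2, 0.3, n_years = 5),
               class = "bp_validation_error")

  o <- observation_model(0.05, 0.81, 0.998, 0.05, 28)
  expect_length(o$p_y, 27L)
  expect_error(observation_model(0.5, 0.5, 1.5, 0.1, 10),
               class = "bp_validation_error")
})

test_that("population states are non-negative integer matrices with B = F + E", {
  st <- population_state(stationary_state())
  expect_identical(breeders(st), 366L + 1371L)
  m <- cbind(stationary_state(), stationary_state() * 2)
  expect_equal(breeders(population_state(m)), c(1737L, 3474L))
  expect_error(population_state(c(-1, rep(1, 8))), class = "bp_validation_error")
  expect_error(population_state(c(1.5, rep(1, 8))), class = "bp_validation_error")
})
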