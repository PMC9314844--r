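test_that("expected projection encodes the life cycle", {
  # forced recruitment: survivors of the oldest pre-breeder class all recruit
  r <- demographic_rates(0.5, 1, 0, 0, 0, 0, 0.5, 0.5, 0, 0, n_years = 2)
  st <- c(0, 0, 0, 0, 0, 50, 0, 0, 0)
  e <- project_expectation(r, st, I_next = 0)
  expect_equal(unname(e["F"]), 50)

  # annihilation: all rates zero gives an all-zero expectation
  r0 <- demographic_rates(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, n_years = 2)
  expect_equal(unname(project_expectation(r0, stationary_state(), 0)),
               rep(0, 9))

  # negative immigrant values are clamped in the projection
  e2 <- project_expectation(study_rates(2), stationary_state(), I_next = -3)
  e3 <- project_expectation(study_rates(2), stationary_state(), I_next = 0)
  expect_equal(e2, e3)

  expect_error(project_expectation(study_rates(2), c(-1, rep(10, 8)), 0),
               class = "bp_validation_error")
})

test_that("stochastic transitions stay within their source classes", {
  r <- study_rates(2)
  set.seed(31)
  sims <- simulate_transition(r, stationary_state(), I_next = 230, nsim = 10000)
  expect_true(all(sims >= 0))
  # recruits + aged pre-breeders cannot exceed the source pre-breeders:
  # P4' <= P3, and next-year experienced breeders <= F + E + S
  expect_true(all(sims["P4", ] <= 164))
  expect_true(all(sims["P2", ] <= 359))
  expect_true(all(sims["E", ] <= 366 + 1371 + 188))

  # all-zero survival kills the population except the immigrant pulse
  r0 <- demographic_rates(0, 0, 0.1, 0.4, 0.5, 0.6, 0.9, 0.7, 0.2, 0.3,
                          n_years = 2)
  z <- simulate_transition(r0, stationary_state(), I_next = 0, nsim = 50)
  expect_true(all(z == 0))
})

test_that("a single experienced-breeder class transitions as the exact binomial", {
  # E' | E = 200 only from surviving breeders that breed: Binomial(200, 0.72)
  r <- demographic_rates(0.5, 0.8, 0, 0, 0, 0, 0.9, 0.5, 0, 0, n_years = 2)
  st <- c(0, 0, 0, 0, 0, 0, 0, 200, 0)
  set.seed(7)
  sims <- simulate_transition(r, st, 0, nsim = 50000)
  x <- sims["E", ]
  p <- 0.8 * 0.9
  breaks <- qbinom(seq(0, 1, by = 0.1), 200, p)
  breaks[1] <- -1; breaks <- unique(breaks)
  obs <- table(cut(x, breaks))
  expp <- diff(pbinom(breaks, 200, p)) * length(x)
  chi2 <- sum((as.numeric(obs) - expp)^2 / expp)
  expect_lt(chi2, qchisq(0.99, df = length(expp) - 1))
})

test_that("expectation matches Monte-Carlo transition means (spot check)", {
  set.seed(91)
  r <- random_rates(2)
  st <- rpois(9, 300)
  I <- 40
  e <- project_expectation(r, st, I, t = 1)
  sims <- simulate_transition(r, st, I, nsim = 20000)
  mc <- rowMeans(sims)
  se <- apply(sims, 1, sd) / sqrt(ncol(sims))
  expect_true(all(abs(mc - e) <= 4 * pmax(se, 1e-9) + 1e-9))
})

test_that("individual trajectories aggregate exactly and are reproducible", {
  r <- study_rates(12)
  traj <- simulate_trajectory(r, rep(80, 11), round(stationary_state() / 3),
                              seed = 5)
  agg <- vapply(1:12, function(t) tabulate(traj$class_mat[, t], 9L), integer(9))
  expect_equal(unname(unclass(traj$states)), unname(agg), ignore_attr = TRUE)
  # branch bookkeeping reproduces next-year classes
  for (t in 1:11) {
    b <- traj$branches[[t]]
    expect_identical(unname(traj$states[2L, t + 1L]), as.integer(b[["sy"]]))
    expect_identical(unname(traj$states[7L, t + 1L]),
                     as.integer(b[["rec2"]] + b[["rec3"]] + b[["rec4"]] +
                                b[["rec5"]] + b[["sp6"]] + traj$I_pulse[t]))
  }
  traj2 <- simulate_trajectory(r, rep(80, 11), round(stationary_state() / 3),
                               seed = 5)
  expect_identical(traj$class_mat, traj2$class_mat)
  expect_error(simulate_trajectory(r, rep(80, 11), rep(-1, 9)),
               class = "bp_validation_error")
})

test_that("realized growth matches the dominant eigenvalue of the expectation matrix", {
  r <- study_rates(16)
  lam <- Re(eigen(expectation_matrix(r, 1))$values[1])
  # large population, no immigration: demographic noise shrinks relative
  # to the deterministic decay
  set.seed(12)
  st <- as.integer(stationary_state() * 40)
  growth <- replicate(30, {
    s <- st
    for (t in 1:15) s <- simulate_transition(r, s, 0, t = 1)
    (sum(s) / sum(st))^(1 / 15)
  })
  expect_lt(abs(mean(growth) - lam), 0.004)

  # with the balancing immigrant pulse the study population is stationary
  set.seed(13)
  lam_imm <- replicate(100, {
    s <- stationary_state()
    for (t in 1:27) s <- simulate_transition(study_rates(2), s, 230, t = 1)
    (breeders(s) / 1737)^(1 / 27)
  })
  expect_lt(abs(mean(lam_imm) - 1), 0.01)
})
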