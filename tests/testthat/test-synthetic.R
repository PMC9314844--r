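test_that("the generator is bit-identical under a fixed seed", {
  s1 <- generate_study(tiny_config(seed = 3))
  s2 <- generate_study(tiny_config(seed = 3))
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$histories$obs, s2$histories$obs)
  expect_identical(s1$reproduction, s2$reproduction)
  expect_identical(s1$patches, s2$patches)
  s3 <- generate_study(tiny_config(seed = 4))
  expect_false(identical(s1$counts, s3$counts))
})

test_that("zero marking intensity yields an empty history set, other streams intact", {
  s <- generate_study(tiny_config(seed = 3, n_marked = 0L))
  expect_identical(nrow(s$histories$obs), 0L)
  expect_gt(nrow(s$counts), 0L)
  expect_gt(sum(s$reproduction$n_nests), 0L)
})

test_that("degenerate observation reproduces the latent truth", {
  s <- generate_study(tiny_config(seed = 5, sigma_obs = 0, p_y = 1, p_p = 1,
                                  p_r = 1))
  expect_equal(s$counts$count, breeders(s$truth$trajectory$states))
  # every alive ringed individual is seen, in its true class
  traj <- s$truth$trajectory
  code_of <- c(1L, 1L, 1L, 1L, 1L, 1L, 2L, 2L, 3L)
  for (k in seq_along(s$histories$id)) {
    i <- s$histories$id[k]
    r <- s$histories$ring_year[k]
    for (y in (r + 1):10) {
      cl <- traj$class_mat[i, y]
      expect_identical(s$histories$obs[k, y],
                       if (cl == 0L) 0L else code_of[cl])
    }
  }
})

test_that("count observation error is log-normal with the configured SD", {
  B <- rep(1500, 10000)
  set.seed(8)
  cts <- observe_counts(B, sigma_obs = 0.08)$count
  lr <- log(cts / B)
  expect_lt(abs(mean(lr)), 0.003)            # E[log C] = log B
  expect_lt(abs(sd(lr) - 0.08) / 0.08, 0.05) # SD within 5%
  expect_equal(observe_counts(B[1:3], 0)$count, B[1:3])
  expect_error(observe_counts(c(10, 0), 0.1), class = "bp_validation_error")
})

test_that("detection of recruited birds happens at rate p_r", {
  s <- generate_study(synthetic_config(seed = 9, n_years = 14, n_marked = 120,
                                       p_r = 0.8))
  traj <- s$truth$trajectory
  obs <- s$histories$obs
  alive_rec <- seen <- 0
  for (k in seq_along(s$histories$id)) {
    cl <- traj$class_mat[s$histories$id[k], ]
    for (y in (s$histories$ring_year[k] + 1):14) {
      if (cl[y] >= 7L) {
        alive_rec <- alive_rec + 1
        seen <- seen + (obs[k, y] > 0L)
      }
    }
  }
  expect_gt(alive_rec, 300)
  expect_lt(abs(seen / alive_rec - 0.8), 3 * sqrt(0.8 * 0.2 / alive_rec))
})

test_that("reproduction categories follow the configured pairing model", {
  # fully ringed, fully assortative pairing: no mixed/unknown nests
  st <- population_state(stationary_state())
  set.seed(11)
  tab <- observe_reproduction(st, study_rates(2), ringed_fraction = 1,
                              assortment = 1)
  expect_identical(tab$n_nests[tab$category == "MIX"], 0L)

  # zero productivity: no fledglings anywhere
  r0 <- demographic_rates(0.65, 0.81, 0.13, 0.41, 0.53, 0.67, 0.90, 0.69,
                          0, 0, n_years = 2)
  tab0 <- observe_reproduction(st, r0, ringed_fraction = 0.3)
  expect_true(all(tab0$n_fledglings == 0L))

  # experienced-pair nests fledge 2*pi_e young on average
  set.seed(12)
  tot_f <- tot_n <- 0
  for (i in 1:300) {
    tab <- observe_reproduction(st, study_rates(2), ringed_fraction = 0.5)
    ee <- tab[tab$category == "EE", ]
    tot_f <- tot_f + sum(ee$n_fledglings); tot_n <- tot_n + sum(ee$n_nests)
  }
  rate <- tot_f / tot_n
  expect_lt(abs(rate - 2 * 0.36), 4 * sqrt(2 * 0.36 / tot_n))
})

test_that("patch tables couple spatial dispersion to year quality", {
  set.seed(13)
  # no failure linkage: homogeneous patches, Gini near zero
  t0 <- generate_patch_table(10, 25, quality = 0.8, failure_link = 0,
                             mean_nests = 200)
  chk0 <- prerequisite_check(t0)
  expect_true(all(chk0$per_year$gini < 0.1))

  # quality at its maximum: no failed patches regardless of linkage
  set.seed(14)
  t1 <- generate_patch_table(1, 400, quality = 0.8, failure_link = 1,
                             mean_nests = 200)
  pm <- t1$n_fledglings / t1$n_nests
  expect_gt(min(pm), 0.5)  # no near-total failures

  expect_error(generate_patch_table(5, 1, 0.5, 0.5), class = "bp_validation_error")
})
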