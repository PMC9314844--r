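test_that("count likelihood matches the log-normal density", {
  # at the mode, a single year contributes -log(sigma * C * sqrt(2 pi))
  expect_equal(loglik_counts(1000, 1000, 0.05),
               -log(0.05 * 1000 * sqrt(2 * pi)))

  # shrinking sigma with C != B drives the likelihood to -Inf monotonely
  # (sigma already below |log C/B|, so every step moves down the tail)
  lls <- vapply(c(0.2, 0.1, 0.05, 0.01), function(s) {
    loglik_counts(1500, 1000, s)
  }, 0)
  expect_true(all(diff(lls) < 0))
  expect_lt(loglik_counts(1500, 1000, 1e-4), -1e6)

  # textbook log-normal density oracle
  set.seed(21)
  C <- exp(rnorm(30, log(1500), 0.2))
  B <- round(runif(30, 1200, 1900))
  s <- 0.13
  expect_equal(loglik_counts(C, B, s),
               sum(stats::dlnorm(C, log(B), s, log = TRUE)),
               tolerance = 1e-12)
  expect_error(loglik_counts(c(1, -2), c(1, 1), 0.1),
               class = "bp_validation_error")
})

test_that("forward likelihood has the closed form for a never-seen chick", {
  # one interval: chick dies, or survives undetected
  T <- 2
  rates <- demographic_rates(0.6, 0.8, 0.1, 0.4, 0.5, 0.6, 0.9, 0.7,
                             0.2, 0.3, n_years = T)
  obs <- observation_model(p_y = 0.07, p_p = 0.5, p_r = 0.99, 0.1, T)
  h <- one_history(0L, ring = 1, n_years = T)
  expect_equal(forward_loglik(h, rates, obs),
               log((1 - 0.6) + 0.6 * (1 - 0.07)))
})

test_that("impossible histories give -Inf, not an error", {
  T <- 8
  rates <- study_rates(T)
  obs <- observation_model(0.05, 0.81, p_r = 1, 0.05, T)
  # recruited birds are always seen when p_r = 1: a gap is impossible
  h <- one_history(c(0, 0, 2, 0, 2), ring = 3, n_years = T)
  expect_identical(forward_loglik(h, rates, obs), -Inf)
  # breeder at age 2 is outside the life cycle
  h2 <- one_history(c(2, 0, 0, 0, 0, 0, 0), ring = 1, n_years = T,
                    validate = FALSE)
  expect_identical(forward_loglik(h2, rates, obs), -Inf)
})

test_that("forward equals exhaustive path enumeration on short histories", {
  set.seed(33)
  T <- 5
  rates <- random_rates(T)
  obs <- random_obs(T)
  for (ring in 1:3) {
    seqs <- all_code_seqs(T - ring)
    for (i in seq_len(nrow(seqs))) {
      h <- one_history(seqs[i, ], ring, T, validate = FALSE)
      f <- forward_loglik(h, rates, obs)
      e <- enum_forward_ll(seqs[i, ], ring, rates, obs)
      if (is.infinite(e)) expect_identical(f, -Inf) else
        expect_equal(f, e, tolerance = 1e-10)
    }
  }
})

test_that("observation-sequence probabilities sum to one", {
  set.seed(34)
  T <- 4
  rates <- random_rates(T)
  obs <- random_obs(T)
  for (ring in 1:2) {
    seqs <- all_code_seqs(T - ring)
    tot <- sum(vapply(seq_len(nrow(seqs)), function(i) {
      exp(forward_loglik(one_history(seqs[i, ], ring, T, validate = FALSE),
                         rates, obs))
    }, 0))
    expect_equal(tot, 1, tolerance = 1e-10)
  }
})

test_that("pre-window birds are conditioned on first in-window resighting", {
  T <- 5
  set.seed(36)
  rates <- random_rates(T)
  obs <- random_obs(T)
  # adult bird ringed well before the window, first seen as breeder at year 2:
  # likelihood = P(obs[3..T] | recruited and alive at year 2), enumerated over
  # paths through {E, S, dead}
  codes <- c(0L, 2L, 0L, 3L, 2L)
  h <- capture_histories(matrix(codes, 1, T), ring_year = -6L)
  f <- forward_loglik(h, rates, obs)
  paths <- as.matrix(expand.grid(rep(list(c(3, 4, 5)), T - 2)))  # E,S,dead
  tot <- 0
  for (p in seq_len(nrow(paths))) {
    st <- c(3, paths[p, ])  # conditioned state at year 2: recruited (E)
    pr <- 1
    for (k in 2:length(st)) {
      y <- k + 1  # calendar year
      j <- y - 1
      f2 <- rates$phi2[j]; pb <- rates$psi_b[j]; ps <- rates$psi_s[j]
      prev <- st[k - 1]; cur <- st[k]
      tp <- if (prev == 3) c(f2 * pb, f2 * (1 - pb), 1 - f2) else
        if (prev == 4) c(f2 * ps, f2 * (1 - ps), 1 - f2) else c(0, 0, 1)
      pr <- pr * tp[cur - 2]
      o <- codes[y]
      em <- if (cur == 5) (if (o == 0) 1 else 0) else
        if (o == 0) 1 - obs$p_r else
          if (o == 2 && cur == 3) obs$p_r else
            if (o == 3 && cur == 4) obs$p_r else 0
      pr <- pr * em
      if (pr == 0) break
    }
    tot <- tot + pr
  }
  expect_equal(f, log(tot), tolerance = 1e-10)
  # a bird never seen in the window contributes nothing
  h0 <- capture_histories(matrix(0L, 1, T), ring_year = -6L)
  expect_identical(forward_loglik(h0, rates, obs), 0)
})

test_that("reproduction likelihood uses the experience-weighted population rate", {
  tab <- data.frame(year = 1, category = "MIX", n_nests = 100,
                    n_fledglings = 64)
  # per-nest rate 2*(20*0.16 + 80*0.36)/100 = 0.64
  expect_equal(loglik_reproduction(tab, 0.16, 0.36, N_F = 20, N_E = 80),
               dpois(64, 100 * 0.64, log = TRUE))

  expect_identical(loglik_reproduction(tab[0, ], 0.16, 0.36, 20, 80), 0)

  # zero rate with positive fledglings is impossible
  tab0 <- data.frame(year = 1, category = "FF", n_nests = 10, n_fledglings = 3)
  expect_identical(loglik_reproduction(tab0, 0, 0.36, 20, 80), -Inf)

  # independent Poisson pmf oracle across random cells
  set.seed(35)
  for (i in 1:25) {
    n <- sample(1:200, 1); f <- rpois(1, n * 0.6)
    cat_i <- sample(c("FF", "EE", "MIX"), 1)
    pf <- runif(1, 0.05, 0.5); pe <- runif(1, 0.05, 0.5)
    NF <- sample(10:100, 1); NE <- sample(10:100, 1)
    rate <- switch(cat_i, FF = 2 * pf, EE = 2 * pe,
                   MIX = 2 * (NF * pf + NE * pe) / (NF + NE))
    tab_i <- data.frame(year = 1, category = cat_i, n_nests = n,
                        n_fledglings = f)
    expect_equal(loglik_reproduction(tab_i, pf, pe, NF, NE),
                 dpois(f, n * rate, log = TRUE), tolerance = 1e-12)
  }
})

test_that("the joint likelihood is the sum of its stream components", {
  study <- generate_study(tiny_config(seed = 17))
  tr <- study$truth$trajectory
  rates <- study$truth$rates
  obs <- study$truth$observation
  ll <- joint_loglik(study, rates, obs, tr)
  comp <- attr(ll, "components")
  expect_true(is.finite(ll))
  expect_equal(as.numeric(ll), sum(comp), tolerance = 1e-12)
  expect_equal(unname(comp["counts"]),
               loglik_counts(study$counts, breeders(tr$states), obs$sigma_obs))
  expect_equal(unname(comp["capture"]), forward_loglik(study$histories, rates, obs))

  # removing one stream changes only its term
  no_counts <- study; no_counts$counts <- NULL
  comp2 <- attr(joint_loglik(no_counts, rates, obs, tr), "components")
  expect_identical(unname(comp2["counts"]), 0)
  expect_equal(comp2[c("capture", "reproduction", "state")],
               comp[c("capture", "reproduction", "state")])
})

test_that("the sampler kernel evaluates the same joint likelihood as the R code", {
  study <- generate_study(tiny_config(seed = 19, rate_sd = 0.2, imm_log_sd = 0.3))
  tr <- study$truth$trajectory
  rates <- study$truth$rates
  obs <- study$truth$observation
  prep <- breedprop:::prepare_data(study)
  vals <- list(phi0 = rates$phi0, phi2 = rates$phi2, rho3 = rates$rho3,
               rho4 = rates$rho4, rho5 = rates$rho5, rho6 = rates$rho6,
               psi_b = rates$psi_b, psi_s = rates$psi_s,
               pi_f = rates$pi_f, pi_e = rates$pi_e,
               p_y = obs$p_y, p_p = obs$p_p, p_r = obs$p_r,
               sigma_obs = obs$sigma_obs, I = tr$I_series,
               N1 = as.integer(tr$states[, 1]),
               branches = sapply(tr$branches, identity))
  cpp <- breedprop:::bp_joint_loglik_cpp(prep$T, prep$counts, prep$repro_n,
                                         prep$repro_f, prep$hobs, prep$hring,
                                         prep$hweight, TRUE, vals)
  rll <- joint_loglik(study, rates, obs, tr)
  expect_equal(cpp$joint, as.numeric(rll), tolerance = 1e-9)
  expect_equal(cpp$cr, unname(attr(rll, "components")["capture"]),
               tolerance = 1e-9)
  expect_equal(cpp$state, unname(attr(rll, "components")["state"]),
               tolerance = 1e-9)
})

test_that("pooled histories leave the capture likelihood unchanged", {
  study <- generate_study(tiny_config(seed = 23))
  h <- study$histories
  rates <- study$truth$rates
  obs <- study$truth$observation
  pooled <- breedprop:::pool_histories(h)
  ll_pooled <- sum(pooled$weight * breedprop:::bp_forward(
    pooled$obs, pooled$ring_year, rates$phi0, rates$phi2, rates$rho3,
    rates$rho4, rates$rho5, rates$rho6, rates$psi_b, rates$psi_s,
    obs$p_y, obs$p_p, obs$p_r, TRUE))
  expect_equal(ll_pooled, forward_loglik(h, rates, obs), tolerance = 1e-9)
  expect_identical(sum(pooled$weight), as.numeric(nrow(h$obs)))
})
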