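test_that("growth rate is the ratio of successive breeder totals", {
  expect_equal(growth_rate(c(100, 110)), 1.1)
  expect_equal(growth_rate(rep(480, 6)), rep(1, 5))
  set.seed(71)
  B <- round(runif(15, 800, 2500))
  lam <- growth_rate(B)
  expect_equal(prod(lam), B[15] / B[1], tolerance = 1e-12)  # telescoping
  expect_error(growth_rate(c(10, 0, 5)), class = "bp_validation_error")
})

test_that("scalar derived quantities match their definitions", {
  expect_equal(integrative_recruitment(30, 70), 0.3)
  expect_true(is.na(integrative_recruitment(0, 0)))
  expect_equal(immigration_rate(-2, 1000), -0.002)  # negative is meaningful
  expect_equal(immigration_rate(0, 750), 0)
  expect_equal(present_nonbreeders(120, 40, p_p = 1, p_r = 1), 160)
  expect_equal(present_nonbreeders(120, 40, p_p = 0, p_r = 0.9), 36)
  comp <- breeder_composition(700, 70, 80, 150)
  expect_equal(sum(comp), 1)
  solo <- breeder_composition(500, 0, 0, 0)
  expect_equal(unname(solo[1, "former_breeder"]), 1)
})

test_that("derived series agree with the synthetic truth record", {
  study <- generate_study(tiny_config(seed = 73))
  tr <- study$truth$trajectory
  cm <- tr$class_mat
  T <- ncol(tr$states)
  for (t in 2:T) {
    # origins of current breeders counted directly from individual paths
    prev <- cm[, t - 1L]; cur <- cm[, t]
    n_fb <- sum(prev %in% c(7L, 8L) & cur == 8L)
    n_fs <- sum(prev == 9L & cur == 8L)
    is_new <- tr$entry_year == t
    n_imm <- sum(is_new & tr$origin == "immigrant")
    n_loc <- sum(cur == 7L) - n_imm
    b <- tr$branches[[t - 1L]]
    expect_identical(n_fb, as.integer(b[["fb"]] + b[["eb"]]))
    expect_identical(n_fs, as.integer(b[["sb"]]))
    expect_identical(n_loc, as.integer(b[["rec2"]] + b[["rec3"]] +
                                       b[["rec4"]] + b[["rec5"]] + b[["sp6"]]))
    comp <- breeder_composition(n_fb, n_fs, n_loc, n_imm)
    expect_equal(sum(comp), 1)
    # integrative recruitment equals the individual-level count
    avail <- sum(cur %in% 3:6)
    expect_equal(integrative_recruitment(n_loc, avail), n_loc / (n_loc + avail))
  }
})

test_that("partial correlation agrees with the precision-matrix formula", {
  set.seed(74)
  # no controls: plain product-moment correlation
  y <- rnorm(30); x <- 0.4 * y + rnorm(30)
  expect_equal(partial_correlation(y, x), cor(y, x), tolerance = 1e-12)

  for (i in 1:20) {
    n <- 40
    Z <- matrix(rnorm(n * 2), n, 2)
    y <- rnorm(n) + Z %*% c(1, -0.5)
    x <- rnorm(n) + Z %*% c(-0.3, 0.8) + 0.2 * y
    r1 <- partial_correlation(y, x, Z)
    Rm <- cor(cbind(y, x, Z))
    P <- solve(Rm)
    r2 <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
    expect_equal(r1, r2, tolerance = 1e-10)
    # symmetry and affine invariance
    expect_equal(partial_correlation(x, y, Z), r1, tolerance = 1e-10)
    expect_equal(partial_correlation(3 * y + 7, x, Z %*% diag(c(2, -1))),
                 r1, tolerance = 1e-10)
  }

  # response identical to a control: residual variance zero, undefined
  z <- rnorm(20)
  expect_true(is.na(partial_correlation(z, rnorm(20), z)))
  # collinear controls are refused
  expect_error(partial_correlation(rnorm(20), rnorm(20), cbind(z, 2 * z)),
               class = "bp_validation_error")
})

test_that("sign support counts posterior mass on the side of the mean", {
  expect_equal(sign_support(c(0.2, 0.1, 0.3)), 1)
  expect_equal(sign_support(c(2, -1, 1)), 2 / 3)
  expect_equal(sign_support(c(-1, 1)), 0.5)  # mean exactly zero
  expect_equal(sign_support(c(0, 1, 1)), 2 / 3)  # zeros match neither sign
  expect_error(sign_support(numeric(0)), class = "bp_validation_error")
  set.seed(75)
  x <- rnorm(1000, 0.3)
  s <- sign(mean(x))
  expect_equal(sign_support(x), sum(sign(x) == s) / 1000)
})

test_that("posterior partial correlations detect and calibrate dependence", {
  set.seed(76)
  nd <- 150; ny <- 20
  yrs <- 1:ny
  ctrl <- matrix(rnorm(nd * ny), nd, ny, dimnames = list(NULL, yrs))
  pred <- matrix(rnorm(nd * ny), nd, ny, dimnames = list(NULL, yrs))
  resp <- 2 * pred + 0.000 * ctrl
  colnames(resp) <- yrs
  # exact positive linear dependence with independent controls
  r <- posterior_partial_correlation(resp, pred, list(ctrl), yrs, yrs)
  expect_gt(r$mean, 0.99)
  expect_equal(r$P, 1)

  # predictor permuted independently per draw: no dependence, P near 0.5
  Ps <- replicate(40, {
    perm <- t(apply(pred, 1, sample))
    colnames(perm) <- yrs
    posterior_partial_correlation(resp - 2 * pred + ctrl, perm, list(),
                                  yrs, yrs)$P
  })
  expect_lt(mean(Ps), 0.8)
  expect_lt(mean(Ps > 0.95), 0.2)
})

test_that("built-in density dependence of breeding propensity is recovered", {
  study <- generate_study(synthetic_config(seed = 77, rate_sd = 0.1,
                                           imm_log_sd = 0.5, dd_psi_b = -1.5,
                                           n_marked = 120))
  fit <- run_mcmc(study, config = mcmc_config(n_chains = 1, n_iter = 3000,
                                              n_burnin = 1200, thin = 3,
                                              seed = 8, time_varying = TRUE))
  tabs <- analysis_tables(fit)
  cell <- tabs$propensity[tabs$propensity$propensity == "former_breeder" &
                          tabs$propensity$feature == "n_breeders", ]
  expect_lt(cell$mean, 0)
  expect_gt(cell$P, 0.95)
  expect_identical(nrow(tabs$propensity), 12L)  # 4 statuses x 3 features
  expect_identical(nrow(tabs$growth), 5L)
  expect_true(all(tabs$propensity$mean >= tabs$propensity$lo &
                  tabs$propensity$mean <= tabs$propensity$hi))
})
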