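test_that("parameter counts match the model hierarchy", {
  expect_equal(count_parameters("main_effect"), 14)
  expect_equal(count_parameters("full"), 18)
  expect_equal(count_parameters("esii_full"), 18)
  expect_equal(count_parameters("pta_only"), 13)
  expect_equal(count_parameters("age_only"), 13)
  expect_equal(count_parameters(psych_model_spec("main_effect"), n_sites = 3),
               10)
})

# deterministic mock: pta_only spec, single site, chosen so the linear
# predictor reproduces any vector we like
mock_from_eta <- function(y, n, cond, eta, pmiss = 0) {
  X <- cbind(pta = eta, cond = cond, gender = 0)
  mock_fit(y, n, cond, X, beta = c(pta = 1, cond = 0, gender = 0),
           pmiss = pmiss)
}

test_that("variance explained is 100% for perfect predictions, 0% when flat", {
  set.seed(4)
  y <- c(20, 28, 35, 40, 44, 15, 25, 33)
  n <- rep(48L, 8)
  cond <- rep(c(0, 1), each = 4)
  obs <- presbyfit:::observed_logodds(y, n, cond, 0)
  perfect <- mock_from_eta(y, n, cond, obs)
  expect_equal(rho_squared(perfect, 0), 100)
  expect_equal(rho_squared(perfect, 1), 100)
  flat <- mock_from_eta(y, n, cond, rep(0.4, 8))
  expect_equal(rho_squared(flat, 0), 0)
  expect_error(rho_squared(mock_from_eta(y[1:4], n[1:4], c(0, 0, 1, 1),
                                         obs[1:4]), 2), "observations")
})

test_that("training deviance behaves like a binomial deviance", {
  y <- c(10, 24, 40, 46)
  n <- rep(48L, 4)
  cond <- rep(0, 4)
  eta <- stats::qlogis(presbyfit:::inverse_link((y + 0.5) / (n + 1), 0))
  close_fit <- mock_from_eta(y, n, cond, eta)
  far_fit <- mock_from_eta(y, n, cond, eta + 1.5)
  expect_lt(training_deviance(close_fit), training_deviance(far_fit))
  # saturated bound: probabilities exactly at the observed proportions
  p_sat <- y / n
  sat <- -2 * sum(stats::dbinom(y, n, p_sat, log = TRUE))
  expect_gt(training_deviance(close_fit), sat)
  # duplicating every observation doubles the deviance
  dbl <- mock_from_eta(rep(y, 2), rep(n, 2), rep(cond, 2), rep(eta, 2))
  expect_equal(training_deviance(dbl), 2 * training_deviance(close_fit),
               tolerance = 1e-9)
  # the posterior-average alternative matches at degenerate draws
  expect_equal(training_deviance(close_fit, average = TRUE),
               training_deviance(close_fit), tolerance = 1e-9)
})

test_that("counterfactual curve is flat when the PTA weight is zero", {
  y <- rep(24L, 6); n <- rep(48L, 6); cond <- rep(c(0, 1), 3)
  X <- cbind(pta = stats::rnorm(6), cond = cond, gender = 0)
  f0 <- mock_fit(y, n, cond, X, beta = c(pta = 0, cond = -1, gender = 0),
                 beta0 = 0.5)
  cc <- counterfactual_curve(f0, 0, pta_grid = seq(10, 70, 10))
  expect_true(all(abs(diff(cc$mean)) < 1e-12))
  expect_equal(unname(cc$max_abs_slope["mean"]), 0)
})

test_that("analytic counterfactual slope equals central finite differences", {
  y <- rep(24L, 6); n <- rep(48L, 6); cond <- rep(c(0, 1), 3)
  X <- cbind(pta = stats::rnorm(6), cond = cond, gender = 0)
  fit <- mock_fit(y, n, cond, X,
                  beta = c(pta = -1.3, cond = -2, gender = 0),
                  beta0 = 1.8, pmiss = 0.17,
                  standardization = list(age = c(mean = 69, sd = 10),
                                         pta = c(mean = 39, sd = 11)))
  grid <- seq(15, 70, 5)
  h <- 0.005
  for (cnd in 0:1) {
    cc <- counterfactual_curve(fit, cnd, pta_grid = grid)
    up <- counterfactual_curve(fit, cnd, pta_grid = grid + h)
    dn <- counterfactual_curve(fit, cnd, pta_grid = grid - h)
    num <- (up$mean - dn$mean) / (2 * h)
    # hand-derived analytic slope on the same grid
    eta <- 1.8 - 2 * cnd - 1.3 * (grid - 39) / 11
    sfac <- 1 - 0.17 * cnd - 1 / 16
    analytic <- 100 * sfac * stats::plogis(eta) * (1 - stats::plogis(eta)) *
      (-1.3 / 11)
    expect_equal(num, analytic, tolerance = 1e-6)
    expect_equal(cc$max_abs_slope[["mean"]], max(abs(analytic)),
                 tolerance = 1e-9)
    # slope sign follows the PTA weight's sign
    expect_lt(cc$slope[1], 0)
  }
  # quiet slopes are steeper than noise slopes (lapse compresses the range)
  ccq <- counterfactual_curve(fit, 0, pta_grid = grid)
  expect_true(all(ccq$slope_diff < 0))
})

test_that("effect ratios are recomputable from the raw draws", {
  y <- rep(24L, 4); n <- rep(48L, 4); cond <- rep(0, 4)
  X <- cbind(pta = stats::rnorm(4), cond = 0, gender = 0)
  same <- mock_fit(y, n, cond, X, beta = c(pta = -1, cond = 0, gender = 0))
  same$draws[, "cond"] <- same$draws[, "pta"]
  r1 <- effect_ratio(same, "pta", "cond")
  expect_equal(r1$mean, 1)
  expect_equal(r1$upper - r1$lower, 0)
  # mock posterior draws: brute-force summary must match exactly
  fit <- mock_fit(y, n, cond, X, beta = c(pta = -1, cond = 0, gender = 0),
                  n_draws = 500)
  set.seed(8)
  fit$draws[, "pta"] <- stats::rnorm(500, -1.36, 0.03)
  fit$draws[, "gender"] <- stats::rnorm(500, -0.27, 0.02)
  r <- effect_ratio(fit, "pta", "gender")
  ref <- abs(fit$draws[, "pta"]) / abs(fit$draws[, "gender"])
  expect_equal(r$mean, mean(ref))
  expect_equal(r$lower, unname(stats::quantile(ref, 0.025)))
  expect_false(r$unstable)
  # unstable denominator triggers the warning path
  fit$draws[, "gender"] <- stats::rnorm(500, 0, 0.05)
  expect_warning(effect_ratio(fit, "pta", "gender"), "unstable")
})

test_that("residual dispersion vanishes for perfect fits and matches a
           Monte-Carlo binomial oracle", {
  y <- c(20, 30, 40); n <- rep(48L, 3); cond <- rep(0, 3)
  obs <- presbyfit:::observed_logodds(y, n, cond, 0)
  perfect <- mock_from_eta(y, n, cond, obs)
  rd <- residual_dispersion(perfect, "HI")
  expect_equal(rd$mean, 0, tolerance = 1e-12)
  # binomial sampling noise on the log-odds scale, fixed p
  set.seed(31)
  p <- 0.6
  ysim <- stats::rbinom(400, 48, p)
  eta_true <- stats::qlogis(presbyfit:::inverse_link(p, 0))
  fitsim <- mock_from_eta(ysim, rep(48L, 400), rep(0, 400),
                          rep(eta_true, 400))
  rd2 <- residual_dispersion(fitsim, "HI")
  mc <- stats::sd(presbyfit:::observed_logodds(
    stats::rbinom(20000, 48, p), 48, 0, 0))
  expect_lt(abs(rd2$mean - mc), 0.05)
  expect_error(residual_dispersion(perfect, "NH"), "absent")
})

test_that("score-level log-odds SD has a two-point closed form", {
  sc <- data.frame(participant_id = c("a", "b"), condition = 1,
                   n_trials = 48, n_correct = c(24, 36), censored = FALSE)
  lo <- function(k) {
    p <- (k + 0.5) / 49
    stats::qlogis((p - 1 / 16) / (1 - 1 / 16))
  }
  expect_equal(score_sd_logodds(sc), stats::sd(c(lo(24), lo(36))))
  same <- sc; same$n_correct <- c(30, 30)
  expect_equal(score_sd_logodds(same), 0)
  expect_error(score_sd_logodds(sc, subset = FALSE), "empty")
})
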