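test_that("pre-selection HI marginals match the configured age model", {
  cfg <- cohort_config(n_hi = 10000, n_nh = 0)
  pop <- simulate_population(cfg, seed = 3)
  expect_equal(mean(pop$age), 69, tolerance = 0.5 / 69)
  expect_true(abs(stats::sd(pop$age) - 10) < 1)
  expect_true(all(pop$age >= 42 & pop$age <= 92))
  # recorded PTA is the mean of the four tabulated thresholds
  thr <- as.matrix(pop[, paste0("thr_", c(0.5, 1, 2, 4))])
  expect_equal(pop$pta, rowMeans(thr), tolerance = 1e-12)
})

test_that("degenerate noise collapses the PTA model", {
  cfg <- cohort_config(
    n_hi = 50, n_nh = 0,
    pta_hi = list(intercept = 30, slope_female = 0, slope_male = 0,
                  male_offset = 0, sd = 0),
    tilt = list(hi = c(mean = 3, age_slope = 0, sd = 0),
                nh = c(mean = 0, age_slope = 0, sd = 0)),
    thr_noise_sd = 0)
  pop <- simulate_population(cfg, seed = 1)
  expect_equal(length(unique(round(pop$pta, 9))), 1)
  expect_equal(unique(round(pop$pta, 6)), 30)
})

test_that("simulated age-PTA dependence recovers the configured slope", {
  cfg <- cohort_config(n_hi = 5000, n_nh = 0)
  pop <- simulate_population(cfg, seed = 9)
  expect_gt(stats::cor(pop$age, pop$pta), 0)
  f <- pop[pop$gender == 0, ]
  slope_hat <- stats::coef(stats::lm(pta ~ age, data = f))[["age"]]
  se <- summary(stats::lm(pta ~ age, data = f))$coefficients["age", 2]
  expect_lt(abs(slope_hat - cfg$pta_hi$slope_female), 4 * se)
})

test_that("inclusion criteria are enforced rowwise", {
  pop <- simulate_population(cohort_config(n_hi = 200, n_nh = 50), seed = 2)
  inc <- apply_inclusion(pop)
  hi <- inc[inc$group == "HI", ]
  expect_true(all(hi$pta <= 70))
  expect_true(all(hi$age > 40))
  expect_true(all(as.matrix(hi[, grep("^thr_", names(hi))]) <= 85))
  nh <- inc[inc$group == "NH", ]
  expect_true(all(nh$age > 55))
  expect_true(all(nh$pta <= 25))
  # explicit boundary cases
  one <- pop[pop$group == "HI", ][1:2, ]
  one$pta <- c(80, 80)
  expect_equal(nrow(apply_inclusion(one)), 0)
  two <- pop[pop$group == "NH", ][1:2, ]
  two$age <- c(50, 50)
  expect_equal(nrow(apply_inclusion(two)), 0)
})

test_that("score simulation follows the guess/lapse binomial model", {
  ch <- tiny_cohort(n_hi = 30, seed = 5)
  # ceiling: enormous intercept drives p' to 1; no lapses
  up <- simulate_scores(ch$participants,
                        generative_params(beta0 = 50, p_miss = 0), seed = 1)
  expect_true(all(up$n_correct == 48))
  # floor: p' to 0 leaves chance performance, mean 3 of 48
  lo <- do.call(rbind, lapply(1:40, function(s)
    simulate_scores(ch$participants,
                    generative_params(beta0 = -50, p_miss = 0), seed = s)))
  expect_equal(mean(lo$n_correct), 3, tolerance = 0.05)
  # Monte-Carlo mean against the closed-form probability for one covariate
  # vector: reference participant at the sample mean, quiet
  pars <- generative_params(sigma0 = 0)   # all site intercepts at beta0
  p1 <- ch$participants[1, ]
  p1$pta <- ch$standardization$pta[["mean"]]
  p1$age <- ch$standardization$age[["mean"]]
  p1$gender <- 0
  draws <- vapply(1:400, function(s)
    simulate_scores(p1, pars, seed = s,
                    standardize = ch$standardization)$n_correct[1], 0)
  p_true <- psychometric_link(presbyfit:::inv_logit(pars$beta0), 0)
  se <- sqrt(p_true * (1 - p_true) / (48 * 400))
  expect_lt(abs(mean(draws) / 48 - p_true), 3 * se)
})

test_that("floor censoring replaces sub-chance scores and is idempotent", {
  sc <- data.frame(participant_id = c("a", "b", "c"), condition = 1,
                   n_trials = 48, n_correct = c(5, 1, 0), censored = FALSE)
  out <- apply_floor_censoring(sc)
  expect_equal(out$n_correct, c(5, 3, 3))
  expect_equal(out$censored, c(FALSE, TRUE, TRUE))
  expect_identical(apply_floor_censoring(out), out)
})

test_that("included cohorts track the study's marginals and censoring rate", {
  ch <- simulate_cohort(cohort_config(n_hi = 2000, n_nh = 200), seed = 21)
  hi <- ch$participants[ch$participants$group == "HI", ]
  expect_lt(abs(mean(hi$age) - 69), 1)
  expect_lt(abs(stats::sd(hi$age) - 10), 1.2)
  expect_lt(abs(mean(hi$pta) - 39), 2)
  expect_lt(abs(stats::sd(hi$pta) - 11), 1.5)
  nh <- ch$participants[ch$participants$group == "NH", ]
  expect_lt(abs(mean(nh$pta) - 10), 1.5)
  # floor-censored fraction stays in the single digits (3.7% in the study)
  cen <- mean(ch$scores$censored)
  expect_gt(cen, 0)
  expect_lt(cen, 0.1)
  expect_true(all(ch$scores$n_correct[ch$scores$censored] == 3))
})

test_that("generation is reproducible from the seed", {
  a <- simulate_cohort(cohort_config(n_hi = 80, n_nh = 10), seed = 33)
  b <- simulate_cohort(cohort_config(n_hi = 80, n_nh = 10), seed = 33)
  expect_identical(a$participants, b$participants)
  expect_identical(a$scores, b$scores)
  c <- simulate_cohort(cohort_config(n_hi = 80, n_nh = 10), seed = 34)
  expect_false(identical(a$scores, c$scores))
})
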