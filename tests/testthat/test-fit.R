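# Reduced-scale MCMC tests: small cohorts, short chains, fixed seeds.

fit_small <- function(ch, variant = "main_effect", iter = 800, warmup = 600,
                      seed = 2, ...) {
  # short chains: the convergence gate is relaxed because these tests
  # exercise structure and coverage, not mixing
  fit_psychometric(ch$participants, ch$scores, variant = variant,
                   chains = 2, iter = iter, warmup = warmup, adapt = 400,
                   seed = seed, rhat_tol = 1.1, ...)
}

test_that("fit object is complete and internally consistent", {
  ch <- tiny_cohort(n_hi = 50, seed = 7)
  fit <- fit_small(ch)
  n_draws <- fit$settings$chains * fit$settings$iter
  expect_equal(dim(fit$loglik), c(n_draws, nrow(ch$scores)))
  expect_true(all(c("beta0", "sigma0", "pta", "age", "cond", "gender",
                    "pmiss") %in% colnames(fit$draws)))
  expect_equal(nrow(fit$diagnostics), ncol(fit$draws))
  expect_true(all(is.finite(fit$diagnostics$rhat)))
  expect_true(all(fit$diagnostics$ess > 0, na.rm = TRUE))
  # lapse probability respects the slope-positivity bound
  expect_true(all(fit$draws[, "pmiss"] >= 0 &
                  fit$draws[, "pmiss"] <= 1 - 1 / 16))
  # response probabilities live in [1/16, 1]; exactly (1/16, 1] in quiet
  P <- presbyfit:::prob_draws(fit)
  expect_true(all(P >= 1 / 16 - 1e-12 & P <= 1 + 1e-12))
  q <- fit$data$cond == 0
  expect_true(max(P[, q]) > 1 - 0.05)    # quiet upper asymptote is 1
  s <- summary(fit)
  expect_true(all(s$lower <= s$mean & s$mean <= s$upper))
  expect_output(print(fit), "guess/lapse")
})

test_that("a null age effect is recovered as a CI covering zero", {
  cfg <- cohort_config(n_hi = 80, n_nh = 0,
                       params = generative_params(beta = c(
                         pta = -1.3, age = 0, cond = -2, gender = 0)))
  ch <- simulate_cohort(cfg, seed = 19)
  fit <- fit_small(ch)
  ci <- stats::quantile(fit$draws[, "age"], c(0.025, 0.975))
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("centered and non-centered parameterizations agree", {
  ch <- tiny_cohort(n_hi = 40, seed = 3)
  f_c <- fit_small(ch, iter = 1200, warmup = 800, check = FALSE)
  f_n <- fit_psychometric(ch$participants, ch$scores, chains = 2,
                          iter = 1200, warmup = 800, adapt = 400, seed = 2,
                          parameterization = "noncentered", check = FALSE)
  pars <- c("pta", "age", "cond", "gender", "pmiss", "beta0")
  for (p in pars) {
    m1 <- mean(f_c$draws[, p]); m2 <- mean(f_n$draws[, p])
    ess <- function(f) max(f$diagnostics$ess[f$diagnostics$parameter == p], 50)
    mcse <- sqrt(stats::var(f_c$draws[, p]) / ess(f_c) +
                 stats::var(f_n$draws[, p]) / ess(f_n))
    expect_lt(abs(m1 - m2), 4 * mcse + 0.02)
  }
})

test_that("prediction and simulation methods are coherent", {
  ch <- tiny_cohort(n_hi = 50, seed = 7)
  fit <- fit_small(ch)
  nd <- data.frame(pta = c(20, 40, 60), age = 69, cond = 1, gender = 0)
  p <- predict(fit, nd)
  expect_true(all(diff(p) < 0))           # deeper loss, lower scores
  eta <- predict(fit, nd, type = "link")
  expect_equal(dim(eta), NULL)            # posterior means by default
  pd <- predict(fit, nd, draws = TRUE)
  expect_equal(ncol(pd), 3)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(nrow(ch$scores), 3))
  expect_true(all(sims >= 0 & sims <= 48))
  r <- residuals(fit)
  expect_length(r, nrow(ch$scores))
  expect_true(all(is.finite(r)))
  expect_lt(abs(mean(r)), 0.5)
  ll <- logLik(fit)
  expect_equal(attr(ll, "df"), 14)
  expect_lt(as.numeric(ll), 0)
})

test_that("the likelihood peaks at the generative truth for large samples", {
  # no MCMC needed: compare the binomial log-likelihood of the simulated
  # data under the truth and under single-weight perturbations
  cfg <- cohort_config(n_hi = 1500, n_nh = 0)
  ch <- simulate_cohort(cfg, seed = 8)
  pars <- cfg$params
  spec <- psych_model_spec("main_effect")
  site_idx <- match(ch$participants$site, sort(unique(ch$participants$site)))
  ll_at <- function(p) {
    idx <- match(ch$scores$participant_id, ch$participants$id)
    cov <- list(
      pta = (ch$participants$pta[idx] - ch$standardization$pta[["mean"]]) /
        ch$standardization$pta[["sd"]],
      age = (ch$participants$age[idx] - ch$standardization$age[["mean"]]) /
        ch$standardization$age[["sd"]],
      cond = ch$scores$condition, gender = ch$participants$gender[idx],
      site = site_idx[idx])
    eta <- linear_predictor(cov, p, spec)
    pr <- psychometric_link(presbyfit:::inv_logit(eta),
                            p$p_miss * ch$scores$condition)
    sum(stats::dbinom(ch$scores$n_correct, ch$scores$n_trials, pr, log = TRUE))
  }
  base <- ll_at(pars)
  for (w in c("pta", "age", "cond")) {
    for (d in c(-0.5, 0.5)) {
      pp <- pars
      pp$beta[w] <- pp$beta[w] + d
      expect_lt(ll_at(pp), base)
    }
  }
})

test_that("data assembly rejects malformed inputs", {
  ch <- tiny_cohort(n_hi = 20, seed = 1)
  bad <- ch$scores
  bad$participant_id[1] <- "nope"
  expect_error(fit_psychometric(ch$participants, bad), "unknown participant")
  bad2 <- ch$scores
  bad2$n_correct[1] <- 50
  expect_error(fit_psychometric(ch$participants, bad2), "n_correct")
  expect_error(fit_psychometric(ch$participants, ch$scores,
                                variant = "esii_full"),
               "requires an 'esii' column")
})

test_that("ESII-based variants fit with a per-record audibility predictor", {
  ch <- tiny_cohort(n_hi = 30, n_nh = 10, seed = 15)
  sc <- ch$scores
  idx <- match(sc$participant_id, ch$participants$id)
  # audibility proxy varying over listeners and conditions
  sc$esii <- plogis(1 - 0.03 * ch$participants$pta[idx] - 0.6 * sc$condition)
  hi <- ch$participants$group == "HI"
  f1 <- fit_psychometric(ch$participants[hi, ],
                         sc[sc$participant_id %in% ch$participants$id[hi], ],
                         variant = "esii_full", chains = 2, iter = 500,
                         warmup = 400, adapt = 300, seed = 6, check = FALSE)
  expect_true(all(c("esii", "esii:cond", "esii:age:cond") %in%
                  colnames(f1$draws)))
  expect_false(is.null(f1$standardization$esii))
  # group model on the joint NH/HI sample uses combined standardization
  f2 <- fit_psychometric(ch$participants, sc, variant = "esii_group",
                         chains = 2, iter = 500, warmup = 400, adapt = 300,
                         seed = 6, check = FALSE,
                         standardize = standardization_constants(
                           ch$participants, "all"))
  expect_true(all(c("group", "group:age", "group:cond") %in%
                  colnames(f2$draws)))
  expect_false(any(grepl("^esii:group|^group:esii",
                         colnames(f2$draws))))
  rd_nh <- residual_dispersion(f2, "NH", condition = 1)
  rd_hi <- residual_dispersion(f2, "HI", condition = 1)
  expect_true(rd_nh$mean > 0 && rd_hi$mean > 0)
})

test_that("posterior ranks of the truth are uniform at reduced scale", {
  # simulation-based calibration, heavily reduced: draw the PTA weight
  # from its prior, simulate a small cohort, refit, record the rank of
  # the truth among thinned posterior draws
  base <- cohort_config(n_hi = 24, n_nh = 0)
  set.seed(99)
  n_sbc <- 24
  bins <- 8
  ranks <- vapply(seq_len(n_sbc), function(r) {
    truth <- stats::rnorm(1)
    cfg <- base
    cfg$params <- generative_params(beta = c(pta = truth, age = -0.27,
                                             cond = -2.07, gender = -0.03))
    ch <- simulate_cohort(cfg, seed = 1000 + r)
    fit <- fit_psychometric(ch$participants, ch$scores, chains = 1,
                            iter = 420, warmup = 300, adapt = 300,
                            seed = r, check = FALSE)
    thin <- fit$draws[seq(1, 420, by = 60), "pta"]   # 7 draws
    sum(thin < truth)
  }, 0)
  counts <- tabulate(ranks + 1, nbins = bins)
  pval <- suppressWarnings(
    stats::chisq.test(counts, p = rep(1 / bins, bins))$p.value)
  expect_gt(pval, 0.01)
})
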