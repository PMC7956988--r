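#' Fit a hierarchical Bayesian guess/lapse psychometric model
#'
#' Fits, by MCMC, a binomial model of consonant-identification counts
#' (`n_correct` out of `n_trials`) in which the probability of a correct
#' response is `1/16 + (1 - p_miss * cond - 1/16) * p_prime`, the lapse
#' probability `p_miss` is free in noise and structurally 0 in quiet, and
#' `logit(p_prime)` is a logistic regression with varying site intercepts:
#' `gamma_0[site] = beta0 + sigma0 * z[site]` (non-centered
#' parameterization, `z ~ N(0, 1)`). Priors: `N(0, 1)` on the weights and
#' `beta0`, half-normal(0, 0.05) on the between-site SD `sigma0`, and a
#' flat Beta on `p_miss / (1 - 1/16)` (so the link slope stays
#' nonnegative). PTA, age (and ESII when used) are standardized with the
#' mean/SD of the fit sample, which is stored in the fit for
#' counterfactual back-transformation.
#'
#' Sampling uses JAGS via \pkg{rjags}. Convergence is monitored with
#' split-R-hat and effective sample size for every parameter; the fit
#' fails with an informative error when any split-R-hat exceeds
#' `rhat_tol` (set `check = FALSE` to keep a non-converged fit for
#' inspection).
#'
#' @param participants participant data frame (`id`, `group`, `gender`,
#'   `age`, `site`, `pta`).
#' @param scores score data frame (`participant_id`, `condition`,
#'   `n_trials`, `n_correct`); ESII-based variants additionally require an
#'   `esii` column (per participant and condition).
#' @param variant model variant name, or pass `spec` directly.
#' @param spec a [psych_model_spec()].
#' @param chains number of independent chains.
#' @param iter post-warmup iterations per chain.
#' @param warmup burn-in iterations discarded after adaptation.
#' @param adapt JAGS adaptation iterations.
#' @param seed integer seed; chain RNGs are derived from it.
#' @param parameterization site-intercept parameterization: `"centered"`
#'   (`gamma_0[site] ~ N(beta0, sigma0)`; mixes better under Gibbs
#'   sampling when every site is data-rich, the default) or
#'   `"noncentered"` (`gamma_0[site] = beta0 + sigma0 z[site]`,
#'   `z ~ N(0,1)`). Both target the identical posterior; draws are always
#'   stored in the non-centered layout (`z` columns).
#' @param rhat_tol split-R-hat threshold for the convergence check.
#' @param check error on non-convergence (default) or keep the fit.
#' @param standardize optional [standardization_constants()] to reuse
#'   (default: computed from `participants`).
#' @return an object of class `psychfit`; see [summary.psychfit()],
#'   [coef.psychfit()], [predict.psychfit()], [psis_loo()].
#' @examples
#' \dontrun{
#' ch <- simulate_cohort(cohort_config(n_hi = 60, n_nh = 0), seed = 1)
#' fit <- fit_psychometric(ch$participants, ch$scores, chains = 2,
#'                         iter = 500, warmup = 300, seed = 1)
#' summary(fit)
#' }
#' @export
fit_psychometric <- function(participants, scores, variant = "main_effect",
                             spec = psych_model_spec(variant),
                             chains = 2, iter = 1500, warmup = 1000,
                             adapt = 500, seed = 1,
                             parameterization = c("centered", "noncentered"),
                             rhat_tol = 1.01,
                             check = TRUE, standardize = NULL) {
  parameterization <- match.arg(parameterization)
  dat <- assemble_model_data(participants, scores, spec, standardize)
  K <- ncol(dat$X)
  model_str <- jags_model_string(spec, parameterization)
  inits <- lapply(seq_len(chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed + 97L * ch))
  })
  jm <- rjags::jags.model(
    textConnection(model_str),
    data = list(y = dat$y, ntr = dat$n_trials, X = dat$X, N = length(dat$y),
                S = dat$n_sites, K = K, site = dat$site_idx, cond = dat$cond,
                beta_prec = 1 / spec$beta_sd^2,
                sigma0_prec = 1 / spec$sigma0_sd^2,
                pm_a = spec$pmiss_shape[1], pm_b = spec$pmiss_shape[2],
                pm_up = spec$pmiss_upper),
    inits = inits, n.chains = chains, n.adapt = adapt, quiet = TRUE)
  stats::update(jm, warmup, progress.bar = "none")
  monitor_site <- if (parameterization == "centered") "gamma" else "z"
  sm <- rjags::coda.samples(jm, c("beta0", "sigma0", "beta", "pmiss",
                                  monitor_site),
                            n.iter = iter, progress.bar = "none")
  # rename beta[k] columns; convert centered gamma draws to the z layout
  rename <- function(m) {
    cn <- colnames(m)
    cn[match(paste0("beta[", seq_len(K), "]"), cn)] <- colnames(dat$X)
    colnames(m) <- cn
    if (parameterization == "centered") {
      gcols <- paste0("gamma[", seq_len(dat$n_sites), "]")
      z <- (m[, gcols, drop = FALSE] - m[, "beta0"]) /
        pmax(m[, "sigma0"], 1e-12)
      colnames(z) <- paste0("z[", seq_len(dat$n_sites), "]")
      m <- cbind(m[, setdiff(cn, gcols), drop = FALSE], z)
    }
    m
  }
  sm <- coda::as.mcmc.list(lapply(sm, function(ch) coda::mcmc(rename(as.matrix(ch)))))
  draws <- do.call(rbind, lapply(sm, as.matrix))
  diag <- diagnostics_table(sm)
  fit <- structure(list(
    draws = draws, spec = spec, diagnostics = diag, divergences = 0L,
    standardization = dat$standardize, data = dat,
    settings = list(chains = chains, iter = iter, warmup = warmup,
                    adapt = adapt, seed = seed,
                    parameterization = parameterization),
    loglik = NULL), class = "psychfit")
  fit$loglik <- pointwise_loglik(fit)
  if (check) {
    core <- diag[!grepl("^z\\[", diag$parameter), ]
    bad <- core[core$rhat > rhat_tol, ]
    if (nrow(bad)) {
      stop("MCMC did not converge (split-R-hat > ", rhat_tol, "): ",
           paste(sprintf("%s=%.3f", bad$parameter, bad$rhat), collapse = ", "),
           call. = FALSE)
    }
  }
  fit
}

jags_model_string <- function(spec, parameterization = "centered") {
  site_block <- if (parameterization == "centered")
    "for (s in 1:S) { gamma[s] ~ dnorm(beta0, tau0) }
    tau0 <- pow(sigma0, -2)" else
    "for (s in 1:S) { z[s] ~ dnorm(0, 1); gamma[s] <- beta0 + sigma0 * z[s] }"
  paste0("model {
    for (i in 1:N) {
      logit(pprime[i]) <- gamma[site[i]] + inprod(X[i,], beta)
      p[i] <- 1/16 + (1 - pmiss * cond[i] - 1/16) * pprime[i]
      y[i] ~ dbin(p[i], ntr[i])
    }
    ", site_block, "
    beta0 ~ dnorm(0, beta_prec)
    sigma0 ~ dnorm(0, sigma0_prec) T(0,)
    for (k in 1:K) { beta[k] ~ dnorm(0, beta_prec) }
    u ~ dbeta(pm_a, pm_b)
    pmiss <- pm_up * u
  }")
}

assemble_model_data <- function(participants, scores, spec, standardize = NULL) {
  idx <- match(scores$participant_id, participants$id)
  if (anyNA(idx))
    stop("score rows with unknown participant_id: ",
         paste(utils::head(which(is.na(idx))), collapse = ", "))
  if (is.null(standardize)) standardize <- standardization_constants(
    participants, if (any(participants$group == "HI")) "HI" else "all")
  site_levels <- sort(unique(participants$site))
  covars <- list(
    pta = (participants$pta[idx] - standardize$pta[["mean"]]) / standardize$pta[["sd"]],
    age = (participants$age[idx] - standardize$age[["mean"]]) / standardize$age[["sd"]],
    cond = as.numeric(scores$condition),
    gender = as.numeric(participants$gender[idx]),
    group = as.numeric(participants$group[idx] == "HI"))
  needs_esii <- any(grepl("esii", spec$terms))
  if (needs_esii) {
    if (is.null(scores$esii))
      stop("variant '", spec$variant, "' requires an 'esii' column in scores")
    standardize$esii <- c(mean = mean(scores$esii), sd = stats::sd(scores$esii))
    covars$esii <- (scores$esii - standardize$esii[["mean"]]) /
      standardize$esii[["sd"]]
  }
  X <- design_matrix(covars, spec$terms)
  if (any(scores$n_correct < 0 | scores$n_correct > scores$n_trials))
    stop("n_correct outside [0, n_trials]")
  list(y = as.integer(scores$n_correct),
       n_trials = as.integer(scores$n_trials),
       cond = as.numeric(scores$condition), X = X,
       site_idx = match(participants$site[idx], site_levels),
       site_levels = site_levels, n_sites = length(site_levels),
       group = participants$group[idx],
       participant_id = scores$participant_id,
       censored = scores$censored %||% rep(FALSE, nrow(scores)),
       standardize = standardize)
}

diagnostics_table <- function(mcmc_list) {
  mats <- lapply(mcmc_list, as.matrix)
  pars <- colnames(mats[[1]])
  rhat <- vapply(pars, function(p) {
    split_rhat(sapply(mats, function(m) m[, p]))
  }, 0)
  ess_mat <- sapply(mcmc_list, function(ch) coda::effectiveSize(ch)[pars])
  ess <- tryCatch(rowSums(matrix(ess_mat, nrow = length(pars)))[seq_along(pars)],
                  error = function(e) rep(NA_real_, length(pars)))
  data.frame(parameter = pars, rhat = as.numeric(rhat),
             ess = as.numeric(ess), row.names = NULL)
}

# per-draw linear predictor matrix (draws x observations)
eta_draws <- function(fit, X = fit$data$X, site_idx = fit$data$site_idx) {
  d <- fit$draws
  gamma <- d[, "beta0"] + d[, "sigma0"] * d[, paste0("z[", site_idx, "]"),
                                            drop = FALSE]
  gamma + d[, colnames(X), drop = FALSE] %*% t(X)
}

# per-draw response probability matrix (draws x observations)
prob_draws <- function(fit, X = fit$data$X, site_idx = fit$data$site_idx,
                       cond = fit$data$cond) {
  eta <- eta_draws(fit, X, site_idx)
  pp <- 1 / (1 + exp(-eta))
  slope <- 1 - outer(fit$draws[, "pmiss"], cond) - 1 / 16
  1 / 16 + slope * pp
}

pointwise_loglik <- function(fit) {
  P <- prob_draws(fit)
  y <- fit$data$y
  n <- fit$data$n_trials
  ll <- t(stats::dbinom(y, n, t(P), log = TRUE))  # draws x obs
  colnames(ll) <- NULL
  ll
}

#' Per-site intercepts of a fit
#' @param fit a `psychfit`.
#' @return matrix of posterior draws of `gamma_0[site]`, one column per
#'   site (labelled).
#' @export
site_intercepts <- function(fit) {
  S <- fit$data$n_sites
  g <- fit$draws[, "beta0"] + fit$draws[, "sigma0"] *
    fit$draws[, paste0("z[", seq_len(S), "]"), drop = FALSE]
  colnames(g) <- fit$data$site_levels
  g
}

#' @export
print.psychfit <- function(x, ...) {
  cat("Hierarchical guess/lapse psychometric model ('",
      x$spec$variant, "' variant)\n", sep = "")
  cat(sprintf("  %d observations, %d sites; %d chains x %d draws\n",
              length(x$data$y), x$data$n_sites,
              x$settings$chains, x$settings$iter))
  est <- coef(x)
  cat("  posterior means:\n")
  print(round(est, 3))
  invisible(x)
}

#' @export
coef.psychfit <- function(object, ...) {
  pars <- c("beta0", object$spec$terms, "sigma0", "pmiss")
  colMeans(object$draws[, pars, drop = FALSE])
}

#' Posterior summary of a psychometric-model fit
#'
#' @param object a `psychfit`.
#' @param prob central credible-interval mass.
#' @param ... unused.
#' @return data frame with posterior mean, SD, credible bounds, split-R-hat
#'   and effective sample size for each parameter.
#' @export
summary.psychfit <- function(object, prob = 0.95, ...) {
  a <- (1 - prob) / 2
  d <- object$draws
  out <- data.frame(
    parameter = colnames(d),
    mean = colMeans(d),
    sd = apply(d, 2, stats::sd),
    lower = apply(d, 2, stats::quantile, a),
    upper = apply(d, 2, stats::quantile, 1 - a),
    row.names = NULL)
  merge(out, object$diagnostics, by = "parameter", sort = FALSE)
}

standardize_newdata <- function(fit, newdata) {
  st <- fit$standardization
  cov <- list(
    cond = as.numeric(newdata$cond %||% newdata$condition),
    gender = as.numeric(newdata$gender %||% 0))
  if (!is.null(newdata$pta))
    cov$pta <- (newdata$pta - st$pta[["mean"]]) / st$pta[["sd"]]
  if (!is.null(newdata$age))
    cov$age <- (newdata$age - st$age[["mean"]]) / st$age[["sd"]]
  if (!is.null(newdata$esii) && !is.null(st$esii))
    cov$esii <- (newdata$esii - st$esii[["mean"]]) / st$esii[["sd"]]
  if (!is.null(newdata$group))
    cov$group <- as.numeric(newdata$group == "HI" | newdata$group == 1)
  cov
}

#' Posterior predictions from a psychometric-model fit
#'
#' @param object a `psychfit`.
#' @param newdata data frame with natural-unit covariates (`pta`, `age`,
#'   `cond`, `gender`, optionally `esii`, `group`, `site`); `NULL` predicts
#'   the fit data.
#' @param type `"response"` (probability correct), `"pprime"` (logistic
#'   component) or `"link"` (log-odds of the logistic component).
#' @param draws return the full posterior draw matrix instead of the
#'   posterior mean.
#' @param ... unused.
#' @return numeric vector (posterior means) or draws-by-observations
#'   matrix.
#' @export
predict.psychfit <- function(object, newdata = NULL,
                             type = c("response", "pprime", "link"),
                             draws = FALSE, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    X <- object$data$X
    site_idx <- object$data$site_idx
    cond <- object$data$cond
  } else {
    cov <- standardize_newdata(object, newdata)
    X <- design_matrix(cov, object$spec$terms)
    site_idx <- if (!is.null(newdata$site))
      match(newdata$site, object$data$site_levels) else NULL
    cond <- cov$cond
  }
  eta <- if (is.null(site_idx)) {
    object$draws[, "beta0"] +
      object$draws[, colnames(X), drop = FALSE] %*% t(X)
  } else eta_draws(object, X, site_idx)
  out <- switch(type,
    link = eta,
    pprime = 1 / (1 + exp(-eta)),
    response = {
      pp <- 1 / (1 + exp(-eta))
      1 / 16 + (1 - outer(object$draws[, "pmiss"], cond) - 1 / 16) * pp
    })
  if (draws) out else colMeans(out)
}

#' Posterior-predictive simulation of score counts
#'
#' Draws `nsim` replicate datasets: for each, one posterior draw is picked
#' at random and binomial counts are generated at that draw's
#' probabilities.
#'
#' @param object a `psychfit`.
#' @param nsim number of replicate datasets.
#' @param seed RNG seed.
#' @param ... unused.
#' @return data frame of `nsim` columns of simulated `n_correct`.
#' @export
simulate.psychfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  P <- prob_draws(object)
  picks <- sample.int(nrow(P), nsim, replace = TRUE)
  out <- as.data.frame(lapply(seq_len(nsim), function(j) {
    stats::rbinom(ncol(P), object$data$n_trials, P[picks[j], ])
  }))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Log-odds prediction errors at the posterior mean
#'
#' Observed proportions are continuity-corrected (0.5 added to successes
#' and failures), inverted through the guess/lapse link at the
#' posterior-mean lapse probability (0 in quiet), clipped into (0, 1), and
#' compared with the posterior-mean linear predictor on the log-odds
#' scale.
#'
#' @param object a `psychfit`.
#' @param ... unused.
#' @return numeric vector of residuals (observed minus predicted
#'   log-odds).
#' @export
residuals.psychfit <- function(object, ...) {
  obs_lo <- observed_logodds(object$data$y, object$data$n_trials,
                             object$data$cond, coef(object)[["pmiss"]])
  obs_lo - colMeans(eta_draws(object))
}

# continuity-corrected observed p' log-odds at a given pmiss
observed_logodds <- function(y, n, cond, pmiss, eps = 1e-3) {
  p_corr <- (y + 0.5) / (n + 1)
  pm <- pmiss * cond
  pp <- (p_corr - 1 / 16) / (1 - pm - 1 / 16)
  logit(pmin(pmax(pp, eps), 1 - eps))
}

#' @export
logLik.psychfit <- function(object, ...) {
  ll <- sum(loglik_at_posterior_mean(object))
  attr(ll, "df") <- count_parameters(object$spec, object$data$n_sites)
  class(ll) <- "logLik"
  ll
}

loglik_at_posterior_mean <- function(fit) {
  est <- colMeans(fit$draws)
  S <- fit$data$n_sites
  gamma <- est[["beta0"]] + est[["sigma0"]] *
    est[paste0("z[", seq_len(S), "]")]
  eta <- gamma[fit$data$site_idx] +
    as.numeric(fit$data$X %*% est[colnames(fit$data$X)])
  p <- 1 / 16 + (1 - est[["pmiss"]] * fit$data$cond - 1 / 16) * inv_logit(eta)
  stats::dbinom(fit$data$y, fit$data$n_trials, p, log = TRUE)
}

#' Plot counterfactual identification curves against the data
#'
#' Draws observed proportions against PTA and overlays the
#' posterior-mean counterfactual curve (effect of varying PTA alone) with
#' its credible band, for quiet and noise.
#'
#' @param x a `psychfit` (a variant with a `pta` term).
#' @param ... passed to [counterfactual_curve()].
#' @export
plot.psychfit <- function(x, ...) {
  if (!"pta" %in% x$spec$terms)
    stop("counterfactual plot requires a variant with a 'pta' term")
  st <- x$standardization
  pta_raw <- x$data$X[, "pta"] * st$pta[["sd"]] + st$pta[["mean"]]
  prop <- x$data$y / x$data$n_trials
  grid <- seq(min(pta_raw), max(pta_raw), length.out = 60)
  graphics::plot(pta_raw, 100 * prop, pch = ifelse(x$data$cond == 1, 1, 16),
                 col = "grey40", xlab = "PTA (dB HL)",
                 ylab = "identification score (%)", ylim = c(0, 100))
  for (cnd in 0:1) {
    cc <- counterfactual_curve(x, condition = cnd, pta_grid = grid, ...)
    graphics::lines(grid, cc$mean, lty = cnd + 1, lwd = 2)
    graphics::lines(grid, cc$lower, lty = cnd + 1, col = "grey60")
    graphics::lines(grid, cc$upper, lty = cnd + 1, col = "grey60")
  }
  graphics::legend("bottomleft", legend = c("quiet", "noise"),
                   lty = 1:2, pch = c(16, 1), bty = "n")
  invisible(x)
}
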