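#' Free-parameter count of a model variant
#'
#' Counts the sampled parameters: one intercept per site, the two
#' hyperparameters (grand mean and between-site SD), one weight per
#' fixed-effect term, and the lapse probability.
#'
#' @param spec a [psych_model_spec()] (or variant name).
#' @param n_sites number of sites (7 in the study design).
#' @return integer parameter count.
#' @examples
#' count_parameters(psych_model_spec("main_effect"))  # 14
#' @export
count_parameters <- function(spec, n_sites = 7) {
  if (is.character(spec)) spec <- psych_model_spec(spec)
  n_sites + 2L + length(spec$terms) + 1L
}

#' Variance explained on the latent log-odds scale
#'
#' A variance-explained analogue for binomial outcomes: observed
#' proportions are continuity-corrected, mapped to the logistic
#' component's log-odds through the inverse guess/lapse link (at the
#' posterior-mean lapse probability; 0 in quiet), and the squared Pearson
#' correlation with the posterior-mean linear predictor is reported in
#' percent, separately per listening condition. Degenerate predictors
#' (zero variance) give 0% by convention.
#'
#' @param fit a `psychfit`.
#' @param condition 0 (quiet) or 1 (noise).
#' @return percentage in `[0, 100]`.
#' @export
rho_squared <- function(fit, condition) {
  sel <- fit$data$cond == condition
  if (sum(sel) < 3) stop("fewer than 3 observations in condition ", condition)
  obs <- observed_logodds(fit$data$y[sel], fit$data$n_trials[sel],
                          fit$data$cond[sel], coef(fit)[["pmiss"]])
  pred <- colMeans(eta_draws(fit))[sel]
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) return(0)
  100 * stats::cor(obs, pred)^2
}

#' Training deviance at the posterior mean
#'
#' `-2` times the summed per-observation binomial log-likelihood evaluated
#' at the posterior-mean parameters (in-sample goodness of fit, on the
#' same deviance scale as LOOIC).
#'
#' @param fit a `psychfit`.
#' @param average evaluate instead the posterior average of the deviance
#'   over draws.
#' @return deviance value.
#' @export
training_deviance <- function(fit, average = FALSE) {
  if (average) return(mean(-2 * rowSums(fit$loglik)))
  -2 * sum(loglik_at_posterior_mean(fit))
}

#' Counterfactual identification curve over PTA
#'
#' Predicted percent-correct as a function of PTA alone, every other
#' covariate held at its reference (age at the fit-sample mean, female,
#' across-site mean intercept), computed per posterior draw through the
#' full guess/lapse link and summarized by the posterior mean and a
#' central credible band. The derivative with respect to PTA in dB HL is
#' computed analytically per draw,
#' `d(100 p)/dPTA = 100 (1 - p_miss cond - 1/16) p'(1 - p') beta_pta / sd_pta`,
#' and the posterior of the maximum absolute slope over the grid is
#' returned, together with the posterior of the quiet-minus-noise maximum
#' slope difference.
#'
#' @param fit a `psychfit` whose variant includes a `pta` term.
#' @param condition condition of the reported curve (0 quiet, 1 noise).
#' @param pta_grid PTA grid in dB HL; default spans the fit sample.
#' @param reference named list overriding reference covariates (natural
#'   units), e.g. `list(age = 75, gender = 1)`.
#' @param prob credible mass of the band.
#' @return list: `pta` (grid), `mean`, `lower`, `upper` (percent-correct
#'   curve), `max_abs_slope` (`c(mean, lower, upper)`, percentage points
#'   per dB HL), `slope` (posterior vector of signed max-|slope| for this
#'   condition), `slope_diff` (posterior vector, quiet minus noise signed
#'   slopes at the grid maximizer).
#' @export
counterfactual_curve <- function(fit, condition = 0, pta_grid = NULL,
                                 reference = list(), prob = 0.95) {
  if (!"pta" %in% fit$spec$terms)
    stop("fit variant has no 'pta' term")
  st <- fit$standardization
  if (is.null(st$pta)) stop("fit lacks PTA standardization constants")
  if (is.null(pta_grid)) {
    raw <- fit$data$X[, "pta"] * st$pta[["sd"]] + st$pta[["mean"]]
    pta_grid <- seq(min(raw), max(raw), length.out = 50)
  }
  ref_age <- reference$age %||% st$age[["mean"]]
  ref_gender <- reference$gender %||% 0
  a <- (1 - prob) / 2
  curve_for <- function(cnd) {
    nd <- data.frame(pta = pta_grid, age = ref_age, cond = cnd,
                     gender = ref_gender)
    cov <- standardize_newdata(fit, nd)
    X <- design_matrix(cov, fit$spec$terms)
    eta <- fit$draws[, "beta0"] +
      fit$draws[, colnames(X), drop = FALSE] %*% t(X)   # draws x grid
    pp <- 1 / (1 + exp(-eta))
    slope_factor <- 1 - fit$draws[, "pmiss"] * cnd - 1 / 16
    p <- 1 / 16 + slope_factor * pp
    # d eta / d pta includes interaction terms containing pta
    dterms <- grep("(^|:)pta($|:)", colnames(X), value = TRUE)
    dcoef <- matrix(0, nrow(fit$draws), length(pta_grid))
    for (tm in dterms) {
      others <- setdiff(strsplit(tm, ":", fixed = TRUE)[[1]], "pta")
      mult <- if (length(others))
        Reduce(`*`, lapply(others, function(o) as.numeric(cov[[o]]))) else 1
      dcoef <- dcoef + outer(fit$draws[, tm], rep(1, length(pta_grid))) *
        matrix(mult, nrow(fit$draws), length(pta_grid), byrow = TRUE)
    }
    dp <- 100 * slope_factor * pp * (1 - pp) * dcoef / st$pta[["sd"]]
    imax <- apply(abs(dp), 1, which.max)
    signed_max <- dp[cbind(seq_len(nrow(dp)), imax)]
    list(p = 100 * p, slope = signed_max)
  }
  this <- curve_for(condition)
  other <- curve_for(1 - condition)
  qslope <- c(mean = mean(abs(this$slope)),
              lower = unname(stats::quantile(abs(this$slope), a)),
              upper = unname(stats::quantile(abs(this$slope), 1 - a)))
  sd_quiet <- if (condition == 0) this$slope else other$slope
  sd_noise <- if (condition == 0) other$slope else this$slope
  list(pta = pta_grid,
       mean = colMeans(this$p),
       lower = apply(this$p, 2, stats::quantile, a),
       upper = apply(this$p, 2, stats::quantile, 1 - a),
       max_abs_slope = qslope,
       slope = this$slope,
       slope_diff = sd_quiet - sd_noise)
}

#' Posterior ratio of two effect magnitudes
#'
#' Per-draw ratio of the absolute weights of two terms, summarized by the
#' posterior mean and a central 95% interval; used to express, e.g., how
#' many times stronger the hearing-loss effect is than the age effect. If
#' the denominator posterior crosses 0 in more than 1% of draws the ratio
#' is unstable and a warning attribute is attached.
#'
#' @param fit a `psychfit`.
#' @param numerator,denominator term names (e.g. `"pta"`, `"age"`).
#' @param prob credible mass.
#' @return list `mean`, `lower`, `upper`, `draws`, and logical `unstable`.
#' @export
effect_ratio <- function(fit, numerator = "pta", denominator = "age",
                         prob = 0.95) {
  if (!all(c(numerator, denominator) %in% colnames(fit$draws)))
    stop("both weights must be sampled in the fit")
  num <- fit$draws[, numerator]
  den <- fit$draws[, denominator]
  sign_flip <- mean(sign(den) != sign(stats::median(den)))
  r <- abs(num) / abs(den)
  a <- (1 - prob) / 2
  out <- list(mean = mean(r),
              lower = unname(stats::quantile(r, a)),
              upper = unname(stats::quantile(r, 1 - a)),
              draws = r, unstable = sign_flip > 0.01)
  if (out$unstable)
    warning("denominator posterior crosses 0 in ",
            round(100 * sign_flip, 1), "% of draws; ratio unstable")
  out
}

#' Residual dispersion of log-odds prediction errors, by group
#'
#' For each posterior draw, observed proportions (continuity-corrected)
#' are inverted through the link at that draw's lapse probability and
#' compared with that draw's linear predictor; the SD of these log-odds
#' errors over the group's observations gives one draw of the dispersion.
#' Larger dispersion in one group means more score variance left
#' unexplained after accounting for the model's predictors.
#'
#' @param fit a `psychfit`.
#' @param group `"NH"` or `"HI"`.
#' @param condition optionally restrict to one condition (0/1).
#' @param prob credible mass.
#' @return list `mean`, `lower`, `upper`, `draws` of the dispersion SD.
#' @export
residual_dispersion <- function(fit, group, condition = NULL, prob = 0.95) {
  sel <- fit$data$group == group
  if (!any(sel)) stop("group ", group, " absent from fit data")
  if (!is.null(condition)) sel <- sel & fit$data$cond == condition
  if (sum(sel) < 2) stop("fewer than 2 observations selected")
  eta <- eta_draws(fit)[, sel, drop = FALSE]
  y <- fit$data$y[sel]; n <- fit$data$n_trials[sel]
  cnd <- fit$data$cond[sel]
  pm <- fit$draws[, "pmiss"]
  p_corr <- (y + 0.5) / (n + 1)
  # per draw: invert link at that draw's pmiss, clip, logit
  sds <- vapply(seq_along(pm), function(d) {
    pp <- (p_corr - 1 / 16) / (1 - pm[d] * cnd - 1 / 16)
    obs <- logit(pmin(pmax(pp, 1e-3), 1 - 1e-3))
    stats::sd(obs - eta[d, ])
  }, 0)
  a <- (1 - prob) / 2
  list(mean = mean(sds),
       lower = unname(stats::quantile(sds, a)),
       upper = unname(stats::quantile(sds, 1 - a)),
       draws = sds)
}

#' SD of raw scores on the log-odds scale
#'
#' Inter-individual variability summary: observed proportions in a subset
#' of score records are continuity-corrected, inverted through the link at
#' a fixed lapse probability, and their log-odds SD is returned.
#'
#' @param scores score data frame.
#' @param subset logical vector (or expression result) selecting records.
#' @param p_miss lapse probability used in the inversion (0 by default so
#'   the summary depends only on the data).
#' @return SD of the subset's log-odds.
#' @export
score_sd_logodds <- function(scores, subset = TRUE, p_miss = 0) {
  s <- scores[subset, , drop = FALSE]
  if (!nrow(s)) stop("empty subset")
  p_corr <- (s$n_correct + 0.5) / (s$n_trials + 1)
  pp <- (p_corr - 1 / 16) / (1 - p_miss - 1 / 16)
  stats::sd(logit(pmin(pmax(pp, 1e-3), 1 - 1e-3)))
}

#' Model-comparison table
#'
#' Compiles, for a set of fits on the same data, the free-parameter count,
#' variance explained per condition, training deviance, LOOIC with SE, and
#' the pointwise predictive-accuracy difference to the reference fit
#' (the first one).
#'
#' @param fits named list of `psychfit` objects.
#' @return data frame with one row per model.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1)
  if (is.null(names(fits))) names(fits) <- paste0("model_", seq_along(fits))
  loos <- lapply(fits, psis_loo)
  ref <- loos[[1]]
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    dl <- if (i == 1) list(value = 0, se = 0) else delta_looic(ref, loos[[i]])
    data.frame(model = names(fits)[i],
               p = count_parameters(f$spec, f$data$n_sites),
               rho2_quiet = rho_squared(f, 0),
               rho2_noise = rho_squared(f, 1),
               D = training_deviance(f),
               looic = loos[[i]]$looic, looic_se = loos[[i]]$looic_se,
               delta = dl$value, delta_se = dl$se)
  })
  do.call(rbind, rows)
}
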