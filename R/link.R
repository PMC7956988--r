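#' Guess/lapse psychometric link for the 16-alternative identification task
#'
#' Maps the logistic component `p_prime` of the model onto the probability
#' of a correct response in a 16-alternative forced-choice task:
#' `p = 1/16 + (1 - p_miss - 1/16) * p_prime`. The lower asymptote is the
#' guessing rate 1/16; the upper asymptote `1 - p_miss` is reduced by the
#' lapse probability `p_miss` (attentional lapses produce an incorrect
#' answer regardless of the stimulus).
#'
#' @param p_prime probability in `[0, 1]` from the logistic regression part.
#' @param p_miss lapse probability in `[0, 1 - 1/16]`; values above
#'   `0.9375` would make the link decreasing and are rejected.
#' @return probability of a correct response, in `[1/16, 1]`.
#' @examples
#' psychometric_link(0, 0)        # chance level, 6.25%
#' psychometric_link(1, 0.172)    # upper asymptote with 17.2% lapses
#' @export
psychometric_link <- function(p_prime, p_miss) {
  if (any(p_prime < 0 | p_prime > 1, na.rm = TRUE))
    stop("p_prime must lie in [0, 1]")
  if (any(p_miss < 0 | p_miss > 1 - 1 / 16, na.rm = TRUE))
    stop("p_miss must lie in [0, 1 - 1/16]")
  1 / 16 + (1 - p_miss - 1 / 16) * p_prime
}

#' Inverse of the guess/lapse link
#'
#' Recovers the logistic component from an observed probability of correct
#' response; used to express observed proportions on the latent log-odds
#' scale (for variance-explained and residual-dispersion summaries). The
#' probability must lie strictly inside the open interval
#' `(1/16, 1 - p_miss)`; observed proportions of 0 or 1 must be given an
#' empirical continuity correction first.
#'
#' @param p probability of a correct response.
#' @param p_miss lapse probability.
#' @return the logistic component `p_prime`.
#' @export
inverse_link <- function(p, p_miss) {
  if (any(p_miss < 0 | p_miss > 1 - 1 / 16, na.rm = TRUE))
    stop("p_miss must lie in [0, 1 - 1/16]")
  lo <- 1 / 16
  hi <- 1 - p_miss
  if (any(p <= lo | p >= hi, na.rm = TRUE))
    stop("p must lie strictly inside (1/16, 1 - p_miss); ",
         "apply a continuity correction first")
  (p - lo) / (hi - lo)
}

# term lists for the six model variants; interaction terms use ":".
variant_terms <- list(
  main_effect = c("pta", "age", "cond", "gender"),
  full        = c("pta", "age", "cond", "gender",
                  "pta:age", "pta:cond", "age:cond", "pta:age:cond"),
  pta_only    = c("pta", "cond", "gender"),
  age_only    = c("age", "cond", "gender"),
  esii_full   = c("esii", "age", "cond", "gender",
                  "esii:age", "esii:cond", "age:cond", "esii:age:cond"),
  esii_group  = c("esii", "age", "cond", "gender",
                  "esii:age", "esii:cond", "age:cond", "esii:age:cond",
                  "group", "group:age", "group:cond")
)

#' Specification of a psychometric model variant
#'
#' The six variants share the same hierarchy (varying site intercepts with
#' hyperparameters `beta0`, `sigma0`, a lapse probability `p_miss` free in
#' noise and structurally 0 in quiet) and differ only in the fixed-effect
#' term list entering the logistic part:
#' \describe{
#'   \item{main_effect}{PTA, age, cond, gender.}
#'   \item{full}{main effects plus all PTA x age x cond interactions.}
#'   \item{pta_only}{PTA, cond, gender (age omitted).}
#'   \item{age_only}{age, cond, gender (PTA omitted).}
#'   \item{esii_full}{as `full` with ESII replacing PTA.}
#'   \item{esii_group}{`esii_full` terms plus group, group x age and
#'     group x cond (for joint NH/HI fits); no group x ESII term and no
#'     higher-order group interactions.}
#' }
#' Gender is present in every variant: it is the statistical control needed
#' to block the selection-induced collider path when PTA or age is omitted.
#'
#' @param variant one of `"main_effect"`, `"full"`, `"pta_only"`,
#'   `"age_only"`, `"esii_full"`, `"esii_group"`.
#' @param beta_sd prior SD for the weights and the grand intercept.
#' @param sigma0_sd scale of the half-normal prior on the between-site SD.
#' @param pmiss_shape two Beta shape parameters for the prior on
#'   `p_miss / 0.9375` (default flat).
#' @return an object of class `psych_model_spec`.
#' @export
psych_model_spec <- function(variant = c("main_effect", "full", "pta_only",
                                         "age_only", "esii_full", "esii_group"),
                             beta_sd = 1, sigma0_sd = 0.05,
                             pmiss_shape = c(1, 1)) {
  variant <- match.arg(variant)
  structure(list(variant = variant,
                 terms = variant_terms[[variant]],
                 beta_sd = beta_sd, sigma0_sd = sigma0_sd,
                 pmiss_shape = pmiss_shape,
                 pmiss_upper = 1 - 1 / 16),
            class = "psych_model_spec")
}

#' @export
print.psych_model_spec <- function(x, ...) {
  cat("Psychometric model spec:", x$variant, "\n terms:",
      paste(x$terms, collapse = " + "), "\n")
  invisible(x)
}

# build the fixed-effect design matrix from standardized covariates
design_matrix <- function(covariates, terms) {
  cols <- lapply(terms, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    miss <- setdiff(parts, names(covariates))
    if (length(miss))
      stop("missing covariate(s) for term '", tm, "': ",
           paste(miss, collapse = ", "))
    Reduce(`*`, lapply(parts, function(p) as.numeric(covariates[[p]])))
  })
  m <- do.call(cbind, cols)
  colnames(m) <- terms
  m
}

#' Linear predictor of the logistic component
#'
#' Evaluates `logit(p_prime) = gamma_0[site] + sum(beta * terms)` for a set
#' of standardized covariates under a model variant. Covariates `pta`,
#' `age` (and `esii`) must already be standardized with the constants of
#' the fit sample; `cond`, `gender` and `group` are 0/1 coded (quiet = 0,
#' female = 0, NH = 0).
#'
#' @param covariates data frame (or list) of covariate columns, plus a
#'   `site` column of integer site indices (used when `params$gamma_site`
#'   is a vector of per-site intercepts).
#' @param params a [generative_params()] list.
#' @param spec a [psych_model_spec()] (its term list selects the weights).
#' @return numeric vector of log-odds.
#' @export
linear_predictor <- function(covariates, params, spec) {
  X <- design_matrix(covariates, spec$terms)
  beta <- params$beta[spec$terms]
  if (anyNA(beta))
    stop("params$beta lacks weight(s): ",
         paste(spec$terms[is.na(beta)], collapse = ", "))
  icpt <- if (!is.null(covariates$site) && length(params$gamma_site) > 1)
    params$gamma_site[as.integer(covariates$site)] else params$beta0
  as.numeric(icpt + X %*% beta)
}

#' True parameter set for simulating binomial identification scores
#'
#' Defaults are the point estimates of the study's main-effect analysis:
#' strong negative weights of noise (`cond`) and hearing loss (`pta`), a
#' smaller negative age weight, an essentially null gender weight, a lapse
#' probability of 17.2% in noise, and seven site intercepts with mean
#' `beta0` and SD 0.5 (the two extreme sites sit roughly +0.5 and -0.9
#' log-odds from the mean, mirroring the between-site spread of scores).
#'
#' @param beta0 grand-mean intercept (log-odds at reference covariates).
#' @param sigma0 between-site SD used to scale the default site offsets.
#' @param beta named vector of weights on standardized/0-1 covariates.
#' @param p_miss lapse probability in noise (structurally 0 in quiet).
#' @param site_offsets unit-SD, zero-mean site offset pattern (length 7).
#' @return a list with class `generative_params`.
#' @export
generative_params <- function(beta0 = 2.1, sigma0 = 0.5,
                              beta = c(pta = -1.36, age = -0.27,
                                       cond = -2.07, gender = -0.03),
                              p_miss = 0.172,
                              site_offsets = c(1.062, 0.262, -0.174, 0.488,
                                               -0.610, 0.836, -1.864)) {
  if (p_miss < 0 || p_miss > 1 - 1 / 16)
    stop("p_miss must lie in [0, 1 - 1/16]")
  if (sigma0 < 0) stop("sigma0 must be nonnegative")
  structure(list(beta0 = beta0, sigma0 = sigma0, beta = beta,
                 p_miss = p_miss,
                 gamma_site = beta0 + sigma0 * site_offsets),
            class = "generative_params")
}
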