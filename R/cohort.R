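#' Configuration of the synthetic presbycusis cohort
#'
#' The generator emulates the demographic, audiometric and selection
#' structure of a multi-site clinical sample of elderly listeners: a
#' hearing-impaired (HI) group whose pure-tone average (PTA) depends on age
#' and gender, a normal-hearing (NH) comparison group, seven recruiting
#' sites, and an inclusion step that conditions on an age- and
#' gender-dependent PTA percentile (creating an Age/Gender collider in the
#' included sample).
#'
#' Age models are truncated normals. Per-participant latent PTA follows
#' `intercept + slope[gender] * age + offset * male + N(0, sd)`; the four
#' audiometric thresholds (0.5, 1, 2, 4 kHz) scatter around it along a
#' sloping high-frequency template whose tilt increases with age, and the
#' recorded PTA is the mean of the four thresholds. The HI inclusion cut
#' approximates the population PTA percentile curve linearly in age with a
#' gender-specific slope.
#'
#' @param n_hi,n_nh number of *included* participants to produce per group.
#' @param age_hi,age_nh `c(mean, sd, lower, upper)` of the truncated-normal
#'   age models (years).
#' @param pta_hi,pta_nh PTA model: `list(intercept, slope_female,
#'   slope_male, male_offset, sd)` (dB HL, dB HL/year).
#' @param inclusion_hi `list(age_min, cut_intercept, cut_slope_female,
#'   cut_slope_male, cut_male_offset, pta_max, thr_max)`: inclusion keeps
#'   HI candidates with `pta > cut(age, gender)`, `pta <= pta_max`, all
#'   four thresholds `<= thr_max`, and `age > age_min`.
#' @param inclusion_nh `list(age_min, pta_max)`.
#' @param p_male probability of a male candidate (pre-selection).
#' @param tilt `list(hi = c(mean, age_slope, sd), nh = ...)`: audiogram
#'   tilt (dB per octave-step around the PTA centre frequency).
#' @param thr_noise_sd per-frequency threshold jitter (dB).
#' @param n_sites number of recruiting sites (uniform assignment).
#' @param params a [generative_params()] set used by [simulate_scores()].
#' @param p_tinnitus probability of a self-reported tinnitus flag
#'   (metadata only; used by no model).
#' @return a list with class `cohort_config`.
#' @export
cohort_config <- function(n_hi = 384, n_nh = 75,
                          age_hi = c(mean = 69, sd = 10, lo = 42, hi = 92),
                          age_nh = c(mean = 69, sd = 7, lo = 58, hi = 86),
                          pta_hi = list(intercept = -26, slope_female = 0.62,
                                        slope_male = 0.82, male_offset = -9,
                                        sd = 16),
                          pta_nh = list(intercept = -3.8, slope_female = 0.2,
                                        slope_male = 0.2, male_offset = 1,
                                        sd = 5),
                          inclusion_hi = list(age_min = 40, cut_intercept = 6.7,
                                              cut_slope_female = 0.32,
                                              cut_slope_male = 1.27,
                                              cut_male_offset = -60.7,
                                              pta_max = 70, thr_max = 85),
                          inclusion_nh = list(age_min = 55, pta_max = 25),
                          p_male = 0.40,
                          tilt = list(hi = c(mean = 4, age_slope = 0.05, sd = 1.5),
                                      nh = c(mean = 1.5, age_slope = 0.02, sd = 1)),
                          thr_noise_sd = 2.5,
                          n_sites = 7,
                          params = generative_params(),
                          p_tinnitus = 0.35) {
  cfg <- list(n_hi = n_hi, n_nh = n_nh, age_hi = age_hi, age_nh = age_nh,
              pta_hi = pta_hi, pta_nh = pta_nh,
              inclusion_hi = inclusion_hi, inclusion_nh = inclusion_nh,
              p_male = p_male, tilt = tilt, thr_noise_sd = thr_noise_sd,
              n_sites = n_sites, params = params, p_tinnitus = p_tinnitus)
  stopifnot(n_hi >= 0, n_nh >= 0, age_hi[["sd"]] > 0, age_nh[["sd"]] > 0,
            pta_hi$sd >= 0, pta_nh$sd >= 0, thr_noise_sd >= 0,
            age_hi[["lo"]] < age_hi[["hi"]], age_nh[["lo"]] < age_nh[["hi"]])
  structure(cfg, class = "cohort_config")
}

pta_freqs_khz <- c(0.5, 1, 2, 4)
extended_freqs_khz <- c(0.25, 0.5, 1, 2, 4, 8)

# truncated normal via inverse-cdf (vectorized, exact)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

site_labels <- function(n) paste0("S", seq_len(n))

#' Simulate a pre-selection candidate population
#'
#' Draws `n_hi + n_nh` candidates (before any inclusion criterion): group,
#' gender, age, site, audiogram and PTA. Age and gender are independent at
#' this stage; dependence between them only appears after
#' [apply_inclusion()] conditions on the selection collider.
#'
#' @param config a [cohort_config()]; its `n_hi`/`n_nh` give the candidate
#'   counts here.
#' @param seed integer RNG seed.
#' @param extended also generate thresholds at 0.25 and 8 kHz (for
#'   audibility-index computation); the PTA remains the mean over 0.5, 1,
#'   2, 4 kHz only.
#' @return data frame with one row per candidate: `id`, `group`, `gender`
#'   (0 female / 1 male), `age`, `site`, `thr_<f>` threshold columns
#'   (dB HL), `pta`, `tinnitus`.
#' @export
simulate_population <- function(config = cohort_config(), seed = 1,
                                extended = FALSE) {
  if (config$n_hi + config$n_nh <= 0) stop("candidate counts must be positive")
  set.seed(seed)
  gen_group <- function(n, group) {
    if (n == 0) return(NULL)
    a <- if (group == "HI") config$age_hi else config$age_nh
    pm <- if (group == "HI") config$pta_hi else config$pta_nh
    tl <- if (group == "HI") config$tilt$hi else config$tilt$nh
    age <- rtruncnorm(n, a[["mean"]], a[["sd"]], a[["lo"]], a[["hi"]])
    gender <- stats::rbinom(n, 1, config$p_male)
    slope <- ifelse(gender == 1, pm$slope_male, pm$slope_female)
    pta_lat <- pm$intercept + slope * age + pm$male_offset * gender +
      stats::rnorm(n, 0, pm$sd)
    tilt <- stats::rnorm(n, tl[["mean"]] + tl[["age_slope"]] * (age - 69),
                         tl[["sd"]])
    freqs <- if (extended) extended_freqs_khz else pta_freqs_khz
    pos <- log2(freqs / sqrt(0.5 * 4))   # octave offsets, 0-centred on PTA band
    thr <- sapply(pos, function(d) pta_lat + tilt * d +
                    stats::rnorm(n, 0, config$thr_noise_sd))
    thr <- pmax(thr, -10)
    colnames(thr) <- paste0("thr_", freqs)
    pta <- rowMeans(thr[, paste0("thr_", pta_freqs_khz), drop = FALSE])
    data.frame(group = group, gender = gender, age = age,
               site = sample(site_labels(config$n_sites), n, replace = TRUE),
               thr, pta = pta,
               tinnitus = stats::rbinom(n, 1, config$p_tinnitus))
  }
  out <- rbind(gen_group(config$n_hi, "HI"), gen_group(config$n_nh, "NH"))
  out <- cbind(id = sprintf("P%05d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Apply the study's inclusion criteria
#'
#' HI candidates are kept when older than `age_min`, when their PTA exceeds
#' the age- and gender-specific percentile cut (linear-in-age
#' approximation of the population reference curve), when the PTA does not
#' exceed `pta_max`, and when every tabulated threshold is at most
#' `thr_max`. NH candidates are kept when older than their `age_min` with
#' PTA at most `pta_max`. Row order is preserved. Conditioning on these
#' criteria is what turns "inclusion" into a collider between age and
#' gender.
#'
#' @param population data frame from [simulate_population()].
#' @param criteria list with elements `hi` and `nh` as in
#'   [cohort_config()]'s `inclusion_hi`/`inclusion_nh`.
#' @return the included subset of `population`.
#' @export
apply_inclusion <- function(population,
                            criteria = list(hi = cohort_config()$inclusion_hi,
                                            nh = cohort_config()$inclusion_nh)) {
  thr_cols <- grep("^thr_", names(population), value = TRUE)
  keep <- logical(nrow(population))
  hi <- population$group == "HI"
  if (any(hi)) {
    cr <- criteria$hi
    cut_slope <- ifelse(population$gender == 1, cr$cut_slope_male,
                        cr$cut_slope_female)
    cut <- cr$cut_intercept + cut_slope * population$age +
      cr$cut_male_offset * population$gender
    ok_thr <- apply(population[, thr_cols, drop = FALSE] <= cr$thr_max, 1, all)
    keep[hi] <- (population$age > cr$age_min & population$pta > cut &
                   population$pta <= cr$pta_max & ok_thr)[hi]
  }
  nh <- population$group == "NH"
  if (any(nh)) {
    cr <- criteria$nh
    keep[nh] <- (population$age > cr$age_min & population$pta <= cr$pta_max)[nh]
  }
  population[keep, , drop = FALSE]
}

#' Covariate standardization constants of a cohort
#'
#' Mean and SD of age and PTA over a reference sample (by default the HI
#' participants, the fit sample of the single-group models); models fitted
#' with these constants must reuse them when back-transforming
#' counterfactual predictions to natural units.
#'
#' @param participants participant data frame.
#' @param group group whose rows define the constants (`"HI"`, `"NH"` or
#'   `"all"`).
#' @return list with `age` and `pta`, each `c(mean, sd)`.
#' @export
standardization_constants <- function(participants, group = "HI") {
  rows <- if (group == "all") rep(TRUE, nrow(participants))
          else participants$group == group
  if (!any(rows)) stop("no participants in group ", group)
  list(age = c(mean = mean(participants$age[rows]),
               sd = stats::sd(participants$age[rows])),
       pta = c(mean = mean(participants$pta[rows]),
               sd = stats::sd(participants$pta[rows])))
}

#' Simulate binomial identification scores for a cohort
#'
#' For every participant and condition (quiet then noise), the logistic
#' component is computed from the generative weights on standardized
#' covariates, mapped through the guess/lapse link (with the lapse
#' probability forced to 0 in quiet), and the number of correct responses
#' out of 48 trials is drawn binomially.
#'
#' @param participants included participant data frame.
#' @param params a [generative_params()].
#' @param seed integer RNG seed.
#' @param standardize standardization constants
#'   ([standardization_constants()]); default computed from
#'   `participants` (HI rows if present, else all).
#' @param n_trials trials per condition (48).
#' @return data frame of score records: `participant_id`, `condition`
#'   (0 quiet / 1 noise), `n_trials`, `n_correct`, `censored` (all `FALSE`
#'   here; see [apply_floor_censoring()]).
#' @export
simulate_scores <- function(participants, params = generative_params(),
                            seed = 1, standardize = NULL, n_trials = 48) {
  set.seed(seed)
  if (is.null(standardize)) {
    grp <- if (any(participants$group == "HI")) "HI" else "all"
    standardize <- standardization_constants(participants, grp)
  }
  spec <- psych_model_spec("main_effect")
  site_idx <- match(participants$site, sort(unique(participants$site)))
  one_cond <- function(cond) {
    cov <- list(
      pta = (participants$pta - standardize$pta[["mean"]]) / standardize$pta[["sd"]],
      age = (participants$age - standardize$age[["mean"]]) / standardize$age[["sd"]],
      cond = rep(cond, nrow(participants)),
      gender = participants$gender,
      site = site_idx)
    eta <- linear_predictor(cov, params, spec)
    p <- psychometric_link(inv_logit(eta), if (cond == 1) params$p_miss else 0)
    if (any(p < 0 | p > 1)) stop("generative parameters yield p outside [0, 1]")
    data.frame(participant_id = participants$id, condition = cond,
               n_trials = n_trials,
               n_correct = stats::rbinom(nrow(participants), n_trials, p),
               censored = FALSE)
  }
  rbind(one_cond(0), one_cond(1))
}

#' Floor-censor scores at chance level
#'
#' Scores below 3 correct responses out of 48 are stored as chance level by
#' the testing software: any record with `n_correct < 3` is replaced by 3
#' and flagged `censored`. The operation is idempotent.
#'
#' @param scores score data frame.
#' @param floor censoring floor (3 = chance count for 48 trials at 1/16).
#' @return the censored score data frame.
#' @export
apply_floor_censoring <- function(scores, floor = 3) {
  hit <- scores$n_correct < floor
  scores$n_correct[hit] <- floor
  scores$censored <- hit | (scores$censored & scores$n_correct == floor)
  scores
}

#' Simulate a complete included cohort with scores
#'
#' Candidate generation, inclusion filtering (repeated in batches until the
#' configured group sizes are reached), score simulation and floor
#' censoring, all driven by one seed.
#'
#' @param config a [cohort_config()].
#' @param seed integer RNG seed.
#' @param extended generate extended-frequency audiograms.
#' @return list with class `presby_cohort`: `participants`, `scores`,
#'   `standardization` (HI constants), `config`, `seed`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1,
                            extended = FALSE) {
  crit <- list(hi = config$inclusion_hi, nh = config$inclusion_nh)
  got_hi <- NULL; got_nh <- NULL
  batch_cfg <- config
  # oversample so one or two batches usually suffice
  batch_cfg$n_hi <- max(200L, config$n_hi * 4L)
  batch_cfg$n_nh <- max(100L, config$n_nh * 2L)
  for (b in 1:50) {
    pop <- simulate_population(batch_cfg, seed = seed + 1000L * (b - 1L),
                               extended = extended)
    inc <- apply_inclusion(pop, crit)
    got_hi <- rbind(got_hi, inc[inc$group == "HI", ])
    got_nh <- rbind(got_nh, inc[inc$group == "NH", ])
    if (nrow(got_hi) >= config$n_hi && nrow(got_nh) >= config$n_nh) break
  }
  if (nrow(got_hi) < config$n_hi || nrow(got_nh) < config$n_nh)
    stop("inclusion rate too low to reach configured group sizes")
  participants <- rbind(utils::head(got_hi, config$n_hi),
                        utils::head(got_nh, config$n_nh))
  participants$id <- sprintf("P%05d", seq_len(nrow(participants)))
  rownames(participants) <- NULL
  std <- standardization_constants(participants,
                                   if (config$n_hi > 0) "HI" else "all")
  scores <- apply_floor_censoring(
    simulate_scores(participants, config$params, seed = seed + 500000L,
                    standardize = std))
  structure(list(participants = participants, scores = scores,
                 standardization = std, config = config, seed = seed),
            class = "presby_cohort")
}

#' @export
print.presby_cohort <- function(x, ...) {
  p <- x$participants
  cat("Synthetic cohort:", sum(p$group == "HI"), "HI +",
      sum(p$group == "NH"), "NH participants,",
      nrow(x$scores), "score records (seed", x$seed, ")\n")
  for (g in unique(p$group)) {
    r <- p[p$group == g, ]
    cat(sprintf("  %s: age %.1f (sd %.1f), PTA %.1f (sd %.1f) dB HL\n",
                g, mean(r$age), stats::sd(r$age), mean(r$pta), stats::sd(r$pta)))
  }
  invisible(x)
}
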