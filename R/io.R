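#' Read a cohort from participant and score CSV files
#'
#' Validates both tables against the record invariants and fails with
#' row-level messages: required columns present, group/gender/condition
#' coded as expected, thresholds within plausible audiometric range,
#' counts within `[0, n_trials]`, PTA consistent with the mean of the four
#' tabulated thresholds, and every score row matched to a participant.
#'
#' @param participants_path CSV with columns `id`, `group` (NH/HI),
#'   `gender` (0/1), `age`, `site`, `thr_0.5`, `thr_1`, `thr_2`, `thr_4`
#'   (dB HL), `pta`.
#' @param scores_path CSV with columns `participant_id`, `condition`
#'   (0/1 or quiet/noise), `n_trials`, `n_correct`, optionally `censored`.
#' @param pta_tol tolerance for the PTA-vs-thresholds consistency check.
#' @return list `participants`, `scores` (condition recoded to 0/1,
#'   `censored` filled with `FALSE` when absent).
#' @export
read_cohort <- function(participants_path, scores_path, pta_tol = 0.51) {
  p <- utils::read.csv(participants_path)
  s <- utils::read.csv(scores_path)
  need_p <- c("id", "group", "gender", "age", "site",
              "thr_0.5", "thr_1", "thr_2", "thr_4", "pta")
  miss <- setdiff(need_p, names(p))
  if (length(miss)) stop("participants file lacks column(s): ",
                         paste(miss, collapse = ", "))
  need_s <- c("participant_id", "condition", "n_trials", "n_correct")
  miss <- setdiff(need_s, names(s))
  if (length(miss)) stop("scores file lacks column(s): ",
                         paste(miss, collapse = ", "))
  bad_row <- function(ok, what, where) {
    if (all(ok)) return(invisible())
    stop(where, " row(s) ", paste(utils::head(which(!ok), 5), collapse = ", "),
         ": ", what)
  }
  bad_row(p$group %in% c("NH", "HI"), "group must be NH or HI", "participants")
  bad_row(p$gender %in% c(0, 1), "gender must be 0 (female) or 1 (male)",
          "participants")
  bad_row(!duplicated(p$id), "duplicated id", "participants")
  thr <- as.matrix(p[, c("thr_0.5", "thr_1", "thr_2", "thr_4")])
  bad_row(apply(thr > -20 & thr < 130, 1, all),
          "threshold outside plausible dB HL range", "participants")
  bad_row(abs(p$pta - rowMeans(thr)) <= pta_tol,
          "pta is not the mean of the four thresholds", "participants")
  if (is.character(s$condition) || is.factor(s$condition)) {
    cv <- c(quiet = 0, noise = 1)[as.character(s$condition)]
    bad_row(!is.na(cv), "condition must be quiet/noise or 0/1", "scores")
    s$condition <- as.numeric(cv)
  }
  bad_row(s$condition %in% c(0, 1), "condition must be 0 or 1", "scores")
  bad_row(s$n_correct >= 0 & s$n_correct <= s$n_trials,
          "n_correct outside [0, n_trials]", "scores")
  bad_row(s$participant_id %in% p$id, "unknown participant_id", "scores")
  if (is.null(s$censored)) s$censored <- FALSE
  list(participants = p, scores = s)
}

#' Write a cohort to CSV files
#'
#' @param cohort a `presby_cohort` (or a list with `participants` and
#'   `scores`).
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pp <- file.path(dir, "participants.csv")
  sp <- file.path(dir, "scores.csv")
  utils::write.csv(cohort$participants, pp, row.names = FALSE)
  utils::write.csv(cohort$scores, sp, row.names = FALSE)
  invisible(c(participants = pp, scores = sp))
}

run_manifest <- function(seed, inputs = character(), extra = list()) {
  c(list(seed = seed,
         package = "presbyfit",
         version = as.character(utils::packageVersion("presbyfit")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         input_md5 = as.list(tools::md5sum(inputs))),
    extra)
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, fits the requested model variants on the
#' HI participants, compiles the model-comparison table and the headline
#' posterior summaries (effect ratio, lapse probability, counterfactual
#' slopes), and optionally writes everything plus a run manifest to a
#' directory. Deterministic given the seed.
#'
#' @param config a [cohort_config()] (used when `participants` is `NULL`).
#' @param participants,scores optional pre-loaded data (from
#'   [read_cohort()]); when `NULL` a cohort is simulated from `config`.
#' @param variants model variants to fit (PTA/age variants only here; the
#'   ESII variants need per-record ESII values, see [esii_for_cohort()]).
#' @param chains,iter,warmup sampler settings passed to
#'   [fit_psychometric()].
#' @param seed master seed for simulation and sampling.
#' @param out_dir optional output directory.
#' @param ... further arguments to [fit_psychometric()].
#' @return list `cohort`, `fits`, `comparison`, `report`, `manifest`.
#' @export
run_pipeline <- function(config = cohort_config(), participants = NULL,
                         scores = NULL,
                         variants = c("main_effect", "full", "pta_only",
                                      "age_only"),
                         chains = 2, iter = 1500, warmup = 1000, seed = 1,
                         out_dir = NULL, ...) {
  if (is.null(participants)) {
    cohort <- simulate_cohort(config, seed = seed)
    participants <- cohort$participants
    scores <- cohort$scores
  } else cohort <- list(participants = participants, scores = scores)
  hi <- participants[participants$group == "HI", ]
  hi_scores <- scores[scores$participant_id %in% hi$id, ]
  fits <- lapply(variants, function(v) {
    fit_psychometric(hi, hi_scores, variant = v, chains = chains,
                     iter = iter, warmup = warmup, seed = seed, ...)
  })
  names(fits) <- variants
  comparison <- compare_models(fits)
  main <- fits[[1]]
  report <- list(
    coefficients = as.list(coef(main)),
    p_miss = unname(coef(main)[["pmiss"]]))
  if (all(c("pta", "age") %in% main$spec$terms)) {
    er <- effect_ratio(main, "pta", "age")
    report$effect_ratio_pta_age <- er[c("mean", "lower", "upper")]
    ccq <- counterfactual_curve(main, condition = 0)
    ccn <- counterfactual_curve(main, condition = 1)
    report$max_slope_quiet <- ccq$max_abs_slope
    report$max_slope_noise <- ccn$max_abs_slope
  }
  manifest <- run_manifest(seed, extra = list(
    variants = variants,
    sampler = list(chains = chains, iter = iter, warmup = warmup)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort(cohort, out_dir)
    utils::write.csv(comparison, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  list(cohort = cohort, fits = fits, comparison = comparison,
       report = report, manifest = manifest)
}
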