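# Analysis configuration: covariate specifications, model terms, follow-up
# structure, and Monte Carlo settings.

#' Specify one time-varying covariate model
#'
#' @param name Covariate name (a column of the interval table).
#' @param family One of `"visit"` (the measurement-attendance process,
#'   binary, drawn only at scheduled visit intervals), `"binary"`,
#'   `"continuous"` (linear model with normal residual draws truncated at the
#'   observed range), `"absorbing"` (binary that never reverts from 1 to 0),
#'   or `"smoking"` (three categories never/former/current with structural
#'   zeros: never->former and any->never transitions are impossible).
#' @param terms Character vector of design-column names (see [build_design()])
#'   forming the linear predictor. `NULL` requests the package default:
#'   all baseline terms, the interval-index terms, lag-1 values of every
#'   time-varying covariate, and current-interval values of covariates
#'   earlier in the simulation order.
#' @param bounds Optional length-2 numeric truncation bounds for continuous
#'   draws; default is the observed sample range at fit time.
#' @return A `gf_covariate_spec` object.
#' @export
covariate_spec <- function(name, family = c("binary", "continuous", "absorbing",
                                            "smoking", "visit"),
                           terms = NULL, bounds = NULL) {
  family <- match.arg(family)
  structure(list(name = name, family = family, terms = terms,
                 auto_terms = is.null(terms), bounds = bounds),
            class = "gf_covariate_spec")
}

# Default covariate set for the blood-pressure/smoking analysis, in
# simulation order. The visit
# process comes first and is never intervened on; smoking transition models
# use a parsimonious term set because two of the three origin strata (smoking
# initiation, relapse) are rare transitions.
default_covariates <- function() {
  smoking_terms <- c("age", "age2", "sex", "tt", "lag_inc_heart_disease")
  list(
    covariate_spec("visit", "visit"),
    covariate_spec("smoking", "smoking", terms = smoking_terms),
    covariate_spec("sbp", "continuous"),
    covariate_spec("total_cholesterol", "continuous"),
    covariate_spec("bmi", "continuous"),
    covariate_spec("alcohol", "continuous"),
    covariate_spec("ht_med", "binary"),
    covariate_spec("inc_heart_disease", "absorbing"),
    covariate_spec("inc_diabetes", "absorbing"),
    covariate_spec("inc_cancer", "absorbing"),
    covariate_spec("inc_tia", "absorbing"),
    covariate_spec("inc_parkinsonism", "absorbing"),
    covariate_spec("other_outcome", "absorbing")
  )
}

default_baseline_terms <- function() {
  c("age", "age2", "sex", "edu_further", "edu_higher", "apoe4_carrier",
    "apoe4_missing", "diabetes0", "heart_disease0",
    "sbp0", "sbp0_2", "sbp0_3")
}

# All lag_/cur_ design names over the non-visit covariates.
tv_term_names <- function(covs, prefix, before = NULL) {
  nms <- character(0)
  for (cv in covs) {
    if (identical(cv$family, "visit")) next
    if (!is.null(before) && cv$name == before) break
    nms <- c(nms, paste0(prefix, tv_design_names(cv$name, cv$family)))
  }
  nms
}

# Fill in default terms for covariate, event and death models.
finalize_config <- function(config) {
  covs <- config$covariates
  for (i in seq_along(covs)) {
    cv <- covs[[i]]
    if (!cv$auto_terms) next
    if (identical(cv$family, "visit")) {
      cv$terms <- c(config$baseline_terms, config$time_terms,
                    tv_term_names(covs, "lag_"))
    } else {
      cv$terms <- c(config$baseline_terms, config$time_terms,
                    tv_term_names(covs, "lag_"),
                    tv_term_names(covs, "cur_", before = cv$name))
    }
    covs[[i]] <- cv
  }
  config$covariates <- covs
  hz <- c(config$baseline_terms, config$time_terms,
          if (any(vapply(covs, function(x) x$family == "visit", TRUE))) "cur_visit",
          tv_term_names(covs, "cur_"))
  if (is.null(config$event_terms)) config$event_terms <- hz
  if (is.null(config$death_terms)) config$death_terms <- hz
  config
}

#' Create an analysis configuration
#'
#' Bundles everything [run_gformula()] needs: the covariate specifications in
#' simulation order (the visit process first), baseline confounder terms,
#' hazard-model terms, the follow-up structure, the competing-event mode, and
#' Monte Carlo settings.
#'
#' Follow-up is discrete: intervals `k = 0, ..., K_max` of roughly one year,
#' with interval 0 the baseline examination, so the default `K_max = 15`
#' gives 16 intervals approximating 15 years of follow-up. Covariates are
#' remeasured only at scheduled visit intervals (default `c(0, 3, 7, 12)`,
#' mimicking four examination rounds) and carried forward in between. A
#' person who misses a scheduled visit is censored at that visit's window-end
#' interval (default: the scheduled interval plus one).
#'
#' @param outcome_name Label for the event of interest.
#' @param covariates List of [covariate_spec()] in simulation order.
#' @param baseline_terms Design-column names of baseline confounder terms
#'   (default: quadratic age, sex, education, APOE-e4, baseline diabetes and
#'   heart disease, cubic baseline SBP).
#' @param time_terms Interval-index terms included in every model
#'   (default linear plus quadratic, `c("tt", "tt2")`).
#' @param event_terms,death_terms Hazard-model terms; default is all baseline
#'   terms, the time terms, and current values of every time-varying
#'   covariate including the visit indicator.
#' @param K_max Last interval index (follow-up spans `K_max + 1` intervals).
#' @param visit_schedule Intervals at which examination visits are scheduled.
#' @param visit_window_end Named or positional integer vector: for each
#'   scheduled visit after baseline, the interval at which a person missing
#'   that visit is censored. Default: scheduled interval + 1 (capped at
#'   `K_max`).
#' @param n_sim Pseudo-population size for the Monte Carlo standardization
#'   (default 10000).
#' @param n_boot Bootstrap replicates for confidence intervals (default 500).
#' @param mode Competing-event handling: `"competing"` (death as competing
#'   event, subdistribution cumulative incidence), `"censor_death"` (death
#'   treated as censoring), or `"composite"` (event-or-death endpoint).
#' @param seed Integer seed controlling all randomness of a run.
#' @param strategies List of [gf_strategy()] objects to evaluate (default:
#'   the ten built-in strategies, natural course first).
#' @param baseline_fields Raw baseline columns expected by [read_cohort()].
#' @return A `gf_config` object.
#' @export
analysis_config <- function(outcome_name = "stroke",
                            covariates = default_covariates(),
                            baseline_terms = default_baseline_terms(),
                            time_terms = c("tt", "tt2"),
                            event_terms = NULL,
                            death_terms = NULL,
                            K_max = 15L,
                            visit_schedule = c(0L, 3L, 7L, 12L),
                            visit_window_end = NULL,
                            n_sim = 10000L,
                            n_boot = 500L,
                            mode = c("competing", "censor_death", "composite"),
                            seed = 1L,
                            strategies = builtin_strategies(),
                            baseline_fields = c("person_id", "age", "sex",
                                                "apoe4", "education",
                                                "diabetes0", "heart_disease0",
                                                "sbp0", "mmse0")) {
  mode <- match.arg(mode)
  if (n_sim < 1L || n_boot < 0L) stop_gf("n_sim must be positive and n_boot non-negative")
  nms <- vapply(covariates, `[[`, "", "name")
  if (anyDuplicated(nms)) stop_gf("duplicate covariate names in config")
  visit_schedule <- sort(unique(as.integer(visit_schedule)))
  sched1 <- visit_schedule[visit_schedule > 0L]
  if (is.null(visit_window_end)) {
    visit_window_end <- pmin(sched1 + 1L, K_max)
  }
  if (length(visit_window_end) != length(sched1)) {
    stop_gf("visit_window_end must have one entry per post-baseline scheduled visit")
  }
  names(visit_window_end) <- as.character(sched1)
  cfg <- structure(list(
    outcome_name = outcome_name, covariates = covariates,
    baseline_terms = baseline_terms, time_terms = time_terms,
    event_terms = event_terms, death_terms = death_terms,
    K_max = as.integer(K_max), visit_schedule = visit_schedule,
    visit_window_end = visit_window_end,
    n_sim = as.integer(n_sim), n_boot = as.integer(n_boot),
    mode = mode, seed = as.integer(seed), strategies = strategies,
    baseline_fields = baseline_fields
  ), class = "gf_config")
  finalize_config(cfg)
}

#' @export
print.gf_config <- function(x, ...) {
  cat(sprintf("<gf_config> outcome: %s | mode: %s | intervals: 0..%d\n",
              x$outcome_name, x$mode, x$K_max))
  cat(sprintf("  covariate order: %s\n",
              paste(vapply(x$covariates, `[[`, "", "name"), collapse = " > ")))
  cat(sprintf("  visits at {%s}; n_sim = %d; n_boot = %d; seed = %d\n",
              paste(x$visit_schedule, collapse = ", "),
              x$n_sim, x$n_boot, x$seed))
  invisible(x)
}

config_covariate_names <- function(config) {
  vapply(config$covariates, `[[`, "", "name")
}

#' Reorder the time-varying covariates of a configuration
#'
#' Returns a copy of `config` with the simulation order permuted. The visit
#' process always stays first. Covariates whose terms were auto-generated are
#' re-specified for the new order (the set of current-interval predictors
#' available to each model depends on its position).
#'
#' @param config A [analysis_config()] object.
#' @param order Character vector: a permutation of the non-visit covariate
#'   names.
#' @return A `gf_config`.
#' @export
set_covariate_order <- function(config, order) {
  covs <- config$covariates
  nms <- vapply(covs, `[[`, "", "name")
  vis <- nms[vapply(covs, function(x) x$family == "visit", TRUE)]
  rest <- setdiff(nms, vis)
  if (!setequal(order, rest)) {
    stop_gf("order must be a permutation of: %s", paste(rest, collapse = ", "))
  }
  reordered <- covs[match(c(vis, order), nms)]
  reordered <- lapply(reordered, function(cv) {
    if (cv$auto_terms) cv$terms <- NULL
    cv
  })
  config$covariates <- reordered
  config$event_terms <- NULL
  config$death_terms <- NULL
  finalize_config(config)
}

#' Eligibility criteria for baseline filtering
#'
#' Defaults mirror a population-based cohort of older adults: age 55-80 at
#' baseline, no cognitive impairment (MMSE at or above 26; persons with a
#' score strictly below 26 are excluded), complete baseline information on
#' SBP, BMI, smoking status and antihypertensive medication, and no prior
#' history flagged in `exclude_flags` columns (values of 1 exclude).
#'
#' @param age_min,age_max Inclusive age bounds.
#' @param mmse_min Minimum MMSE score retained (exclusion is strictly below).
#' @param required_complete Fields (baseline or interval-0) that must be
#'   non-missing.
#' @param exclude_flags Baseline or interval-0 binary columns whose value 1
#'   excludes a person (e.g. prior-event indicators).
#' @return A `gf_criteria` object.
#' @export
eligibility_criteria <- function(age_min = 55, age_max = 80, mmse_min = 26,
                                 required_complete = c("sbp0", "bmi",
                                                       "smoking", "ht_med"),
                                 exclude_flags = character(0)) {
  structure(list(age_min = age_min, age_max = age_max, mmse_min = mmse_min,
                 required_complete = required_complete,
                 exclude_flags = exclude_flags),
            class = "gf_criteria")
}

#' Write / read an analysis configuration as YAML
#'
#' Serializes the scalar settings, covariate specifications and strategy
#' rules; subgroup predicate functions are not serializable and are omitted.
#'
#' @param config A `gf_config`.
#' @param path File path.
#' @return `read_config` returns a `gf_config`; `write_config` returns `path`
#'   invisibly.
#' @export
write_config <- function(config, path) {
  covs <- lapply(config$covariates, function(cv) {
    list(name = cv$name, family = cv$family,
         terms = if (cv$auto_terms) NULL else as.list(cv$terms),
         bounds = if (is.null(cv$bounds)) NULL else as.list(cv$bounds))
  })
  strat <- lapply(config$strategies, strategy_to_list)
  obj <- list(
    outcome_name = config$outcome_name,
    baseline_terms = as.list(config$baseline_terms),
    time_terms = as.list(config$time_terms),
    K_max = config$K_max,
    visit_schedule = as.list(config$visit_schedule),
    visit_window_end = as.list(unname(config$visit_window_end)),
    n_sim = config$n_sim, n_boot = config$n_boot,
    mode = config$mode, seed = config$seed,
    baseline_fields = as.list(config$baseline_fields),
    covariates = covs, strategies = strat
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  covs <- lapply(obj$covariates, function(cv) {
    covariate_spec(cv$name, cv$family,
                   terms = if (length(cv$terms)) unlist(cv$terms),
                   bounds = if (length(cv$bounds)) unlist(cv$bounds))
  })
  strategies <- lapply(obj$strategies, strategy_from_list)
  analysis_config(
    outcome_name = obj$outcome_name,
    covariates = covs,
    baseline_terms = unlist(obj$baseline_terms),
    time_terms = unlist(obj$time_terms),
    K_max = obj$K_max,
    visit_schedule = unlist(obj$visit_schedule),
    visit_window_end = unlist(obj$visit_window_end),
    n_sim = obj$n_sim, n_boot = obj$n_boot,
    mode = obj$mode, seed = obj$seed,
    strategies = strategies,
    baseline_fields = unlist(obj$baseline_fields)
  )
}
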