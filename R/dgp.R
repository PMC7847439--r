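# Synthetic data-generating processes (DGPs) with fully known coefficients:
# the source of validation cohorts and of oracle counterfactual risks.

#' Construct a data-generating process
#'
#' A DGP holds everything needed to simulate a longitudinal cohort: a
#' baseline sampler, per-covariate transition models (named coefficient
#' vectors over the design columns of [build_design()], plus residual scale
#' and truncation bounds for continuous covariates, or `start`/`relapse`/
#' `quit` origin-stratified logits for a smoking covariate), logistic
#' discrete-time event and death hazards, a per-interval loss-to-follow-up
#' probability, and the follow-up structure.
#'
#' @param covariates List of `list(name, family)` in simulation order; the
#'   visit process, if any, must come first.
#' @param baseline_sampler `function(n)` returning a data.frame with the
#'   baseline fields and the interval-0 values of every non-visit covariate;
#'   it may use the ambient RNG (callers seed it).
#' @param models Named list of transition models, one entry per non-baseline
#'   covariate (see Details above).
#' @param event_coefs,death_coefs Named numeric vectors (including
#'   `"(Intercept)"`) defining the logistic hazards on the design columns.
#' @param ltfu_hazard Per-interval probability of loss to follow-up
#'   (drawn independently of future covariates; applies from interval 1 on).
#' @param K_max Last interval index.
#' @param visit_schedule Scheduled examination intervals.
#' @param visit_window_end Censoring interval per missed post-baseline visit
#'   (default scheduled interval + 1).
#' @param baseline_fields Columns of the sampler output forming the baseline
#'   table (the rest are interval-0 covariate values).
#' @param baseline_terms Baseline design terms a correctly specified analysis
#'   would use (consumed by [config_for_dgp()]).
#' @param missing Named numeric vector of measurement-missingness rates:
#'   for covariate `v`, the given fraction of persons has `v` recorded as
#'   `NA` until their first attended post-baseline visit (and `v0` set `NA`
#'   at baseline if such a column exists). The underlying dynamics use the
#'   true values; this emulates item missingness handled by complete-case
#'   eligibility filtering.
#' @param label Description used in printing.
#' @return A `gf_dgp` object.
#' @export
gf_dgp <- function(covariates, baseline_sampler, models, event_coefs,
                   death_coefs, ltfu_hazard = 0, K_max = 15L,
                   visit_schedule = c(0L, 3L, 7L, 12L),
                   visit_window_end = NULL,
                   baseline_fields = NULL, baseline_terms = character(0),
                   missing = numeric(0), label = "custom DGP") {
  visit_schedule <- sort(unique(as.integer(visit_schedule)))
  sched1 <- visit_schedule[visit_schedule > 0L]
  if (is.null(visit_window_end)) visit_window_end <- pmin(sched1 + 1L, K_max)
  names(visit_window_end) <- as.character(sched1)
  nms <- vapply(covariates, `[[`, "", "name")
  need_models <- nms
  miss <- setdiff(need_models, names(models))
  if (length(miss)) stop_gf("DGP lacks transition model(s) for: %s",
                            paste(miss, collapse = ", "))
  structure(list(covariates = covariates, baseline_sampler = baseline_sampler,
                 models = models, event_coefs = event_coefs,
                 death_coefs = death_coefs, ltfu_hazard = ltfu_hazard,
                 K_max = as.integer(K_max), visit_schedule = visit_schedule,
                 visit_window_end = visit_window_end,
                 baseline_fields = baseline_fields,
                 baseline_terms = baseline_terms,
                 missing = missing, label = label),
            class = "gf_dgp")
}

#' @export
print.gf_dgp <- function(x, ...) {
  cat(sprintf("<gf_dgp> %s | %d time-varying covariates | k = 0..%d | visits {%s}\n",
              x$label, length(x$covariates), x$K_max,
              paste(x$visit_schedule, collapse = ", ")))
  invisible(x)
}

# Linear predictor of a named coefficient vector over a design frame.
lp_eval <- function(coefs, frame) {
  n <- nrow(frame)
  lp <- rep(unname(coefs["(Intercept)"]), n)
  if (is.na(lp[1])) lp <- numeric(n)
  for (nm in setdiff(names(coefs), "(Intercept)")) {
    col <- frame[[nm]]
    if (is.null(col)) stop_gf("coefficient references unknown design column '%s'", nm)
    lp <- lp + coefs[[nm]] * col
  }
  lp
}

# One within-interval covariate update from the true DGP: draws the visit
# indicator (at scheduled intervals) and, for attendees, each covariate in
# order given the design frame; others carry forward. Returns the updated
# raw state list and the frame with its cur_ columns updated.
dgp_update_state <- function(dgp, ble, cur, k) {
  lag <- cur
  n <- nrow(ble)
  frame <- make_design_frame(ble, dgp$covariates, cur = lag, lag = lag, k = k)
  has_visit <- dgp$covariates[[1]]$family == "visit"
  if (has_visit && k %in% dgp$visit_schedule) {
    p <- stats::plogis(lp_eval(dgp$models$visit$coef, frame))
    visit <- as.numeric(stats::runif(n) < p)
  } else {
    visit <- numeric(n)
  }
  if (has_visit) {
    cur$visit <- visit
    frame$cur_visit <- visit
  }
  att <- visit == 1
  if (any(att)) {
    for (cv in dgp$covariates) {
      if (cv$family == "visit") next
      m <- dgp$models[[cv$name]]
      if (cv$family == "continuous") {
        mu <- lp_eval(m$coef, frame)
        new <- mu + stats::rnorm(n, sd = m$sigma)
        if (!is.null(m$bounds)) new <- clamp(new, m$bounds[1], m$bounds[2])
        cur[[cv$name]] <- ifelse(att, new, lag[[cv$name]])
      } else if (cv$family == "binary") {
        p <- stats::plogis(lp_eval(m$coef, frame))
        new <- as.numeric(stats::runif(n) < p)
        cur[[cv$name]] <- ifelse(att, new, lag[[cv$name]])
      } else if (cv$family == "absorbing") {
        p <- stats::plogis(lp_eval(m$coef, frame))
        new <- as.numeric(stats::runif(n) < p)
        v <- lag[[cv$name]]
        upd <- att & v == 0
        v[upd] <- new[upd]
        cur[[cv$name]] <- v
      } else if (cv$family == "smoking") {
        v <- lag[[cv$name]]
        u <- stats::runif(n)
        p_start <- stats::plogis(lp_eval(m$start, frame))
        p_rel <- stats::plogis(lp_eval(m$relapse, frame))
        p_quit <- stats::plogis(lp_eval(m$quit, frame))
        new <- v
        i <- att & v == "never" & u < p_start
        new[i] <- "current"
        i <- att & v == "former" & u < p_rel
        new[i] <- "current"
        i <- att & v == "current" & u < p_quit
        new[i] <- "former"
        cur[[cv$name]] <- new
      }
      for (cn in names(expand_tv(cv$name, cv$family, cur[[cv$name]], "cur_"))) {
        frame[[cn]] <- expand_tv(cv$name, cv$family, cur[[cv$name]], "cur_")[[cn]]
      }
    }
  }
  list(cur = cur, frame = frame, visit = visit)
}

#' Generate a synthetic cohort from a known DGP
#'
#' Simulates person histories sequentially: a baseline draw, then per interval
#' the visit indicator, covariate updates for attendees (carry-forward
#' otherwise), and exit draws — death first, then the event, then loss to
#' follow-up (from interval 1 on). Exit indicators appear only in a person's
#' final record. Reproducible given `seed`.
#'
#' @param dgp A [gf_dgp()].
#' @param n Number of persons.
#' @param seed Integer seed.
#' @return A `gf_cohort`.
#' @export
generate_cohort <- function(dgp, n, seed) {
  if (n < 1L) stop_gf("n must be at least 1")
  with_seed(seed, {
    raw <- dgp$baseline_sampler(n)
    raw$person_id <- seq_len(n)
    bfields <- dgp$baseline_fields %||%
      setdiff(names(raw), vapply(dgp$covariates, `[[`, "", "name"))
    bfields <- union("person_id", bfields)
    baseline <- raw[, intersect(bfields, names(raw)), drop = FALSE]
    tv_names <- setdiff(vapply(dgp$covariates, `[[`, "", "name"), "visit")
    cur <- lapply(raw[tv_names], identity)
    cur$visit <- rep(1, n)
    ble <- expand_baseline(baseline)

    masked <- list()
    for (mv in names(dgp$missing)) {
      masked[[mv]] <- stats::runif(n) < dgp$missing[[mv]]
      b0col <- paste0(mv, "0")
      if (b0col %in% names(baseline)) baseline[[b0col]][masked[[mv]]] <- NA
    }

    active <- rep(TRUE, n)
    rows <- vector("list", dgp$K_max + 1L)
    for (k in 0:dgp$K_max) {
      idx <- which(active)
      if (length(idx) == 0L) break
      if (k == 0L) {
        visit <- rep(1, n)
        frame <- make_design_frame(ble, dgp$covariates, cur = cur,
                                   lag = NULL, k = 0)
      } else {
        st <- dgp_update_state(dgp, ble, cur, k)
        cur <- st$cur
        frame <- st$frame
        visit <- st$visit
        for (mv in names(masked)) {
          masked[[mv]] <- masked[[mv]] & !(visit == 1)
        }
      }
      he <- stats::plogis(lp_eval(dgp$event_coefs, frame))[idx]
      hd <- stats::plogis(lp_eval(dgp$death_coefs, frame))[idx]
      death <- stats::runif(length(idx)) < hd
      event <- !death & stats::runif(length(idx)) < he
      cens <- if (k > 0L && dgp$ltfu_hazard > 0) {
        !death & !event & stats::runif(length(idx)) < dgp$ltfu_hazard
      } else rep(FALSE, length(idx))

      rec <- data.frame(person_id = idx, k = k, visit = visit[idx])
      for (nm in tv_names) {
        v <- cur[[nm]][idx]
        if (!is.null(masked[[nm]])) v[masked[[nm]][idx]] <- NA
        rec[[nm]] <- v
      }
      rec$event <- as.integer(event)
      rec$death <- as.integer(death)
      rec$censored <- as.integer(cens)
      rows[[k + 1L]] <- rec
      active[idx[death | event | cens]] <- FALSE
    }
    intervals <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    as_cohort(baseline, intervals, K_max = dgp$K_max, validate = FALSE)
  })
}

#' Zero a covariate out of the true hazards
#'
#' Returns a copy of the DGP in which every event- and death-hazard
#' coefficient involving the named time-varying covariate (its current or
#' lagged design columns) is set to zero, so the covariate has no direct
#' effect on either hazard. Transition models are untouched. Applying twice
#' equals applying once.
#'
#' @param dgp A [gf_dgp()].
#' @param covariate Name of a time-varying covariate of the DGP.
#' @return A `gf_dgp`.
#' @export
null_dgp <- function(dgp, covariate) {
  nms <- vapply(dgp$covariates, `[[`, "", "name")
  if (!covariate %in% nms) stop_gf("unknown covariate '%s'", covariate)
  fam <- dgp$covariates[[match(covariate, nms)]]$family
  targets <- as.vector(outer(c("cur_", "lag_", ""),
                             tv_design_names(covariate, fam), paste0))
  for (fld in c("event_coefs", "death_coefs")) {
    hit <- intersect(names(dgp[[fld]]), targets)
    dgp[[fld]][hit] <- 0
  }
  dgp$label <- paste0(dgp$label, sprintf(" [null: %s]", covariate))
  dgp
}

#' Analysis configuration matching a DGP
#'
#' Builds an [analysis_config()] whose covariate set, simulation order,
#' follow-up structure and visit schedule mirror the DGP, with default
#' (correctly specified) model terms.
#'
#' @param dgp A [gf_dgp()].
#' @param ... Passed on to [analysis_config()] (e.g. `n_sim`, `mode`, `seed`).
#' @return A `gf_config`.
#' @export
config_for_dgp <- function(dgp, ...) {
  covs <- lapply(dgp$covariates, function(cv) {
    if (cv$family == "smoking") {
      terms <- c(intersect(c("age", "age2", "sex"), dgp$baseline_terms), "tt")
      if ("inc_heart_disease" %in% vapply(dgp$covariates, `[[`, "", "name")) {
        terms <- c(terms, "lag_inc_heart_disease")
      }
      covariate_spec(cv$name, cv$family, terms = terms)
    } else {
      covariate_spec(cv$name, cv$family)
    }
  })
  dots <- list(...)
  if (is.null(dots$strategies)) {
    # keep only built-in strategies whose rules target covariates the DGP has
    nms <- vapply(dgp$covariates, `[[`, "", "name")
    dots$strategies <- Filter(function(s) {
      all(vapply(s$rules, function(r) r$target %in% nms, TRUE))
    }, builtin_strategies())
  }
  do.call(analysis_config,
          c(list(covariates = covs, baseline_terms = dgp$baseline_terms,
                 K_max = dgp$K_max, visit_schedule = dgp$visit_schedule,
                 visit_window_end = dgp$visit_window_end,
                 baseline_fields = dgp$baseline_fields %||%
                   eval(formals(analysis_config)$baseline_fields)),
            dots))
}

#' The default synthetic cohort DGP
#'
#' Emulates a population-based cohort of adults aged 55-80 followed for 16
#' yearly intervals with four examination rounds (intervals 0, 3, 7, 12):
#' baseline SBP normal with mean 137.3 and SD 21.5 mmHg, smoking
#' never/former/current at 31.5/44.5/24.1%, and transition, visit-attendance
#' and discrete-time hazard models whose coefficients are listed in the
#' methods vignette. Hazard intercepts are calibrated so that the 15-year
#' natural-course event risk is roughly 10% and the death risk roughly 25%.
#' A small fraction of persons has SBP or BMI unrecorded at baseline
#' (complete-case eligibility filtering removes them).
#'
#' @return A `gf_dgp`.
#' @export
default_dgp <- function() {
  covariates <- list(
    list(name = "visit", family = "visit"),
    list(name = "smoking", family = "smoking"),
    list(name = "sbp", family = "continuous"),
    list(name = "total_cholesterol", family = "continuous"),
    list(name = "bmi", family = "continuous"),
    list(name = "alcohol", family = "continuous"),
    list(name = "ht_med", family = "binary"),
    list(name = "inc_heart_disease", family = "absorbing"),
    list(name = "inc_diabetes", family = "absorbing"),
    list(name = "inc_cancer", family = "absorbing"),
    list(name = "inc_tia", family = "absorbing"),
    list(name = "inc_parkinsonism", family = "absorbing"),
    list(name = "other_outcome", family = "absorbing")
  )
  sampler <- function(n) {
    sbp0 <- clamp(stats::rnorm(n, 137.3, 21.5), 80, 240)
    data.frame(
      age = stats::runif(n, 55, 80),
      sex = stats::rbinom(n, 1, 0.573),
      education = sample(c("primary", "further", "higher"), n, TRUE,
                         prob = c(0.486, 0.418, 0.096)),
      apoe4 = sample(c("noncarrier", "carrier", "missing"), n, TRUE,
                     prob = c(0.687, 0.268, 0.045)),
      diabetes0 = stats::rbinom(n, 1, 0.129),
      heart_disease0 = stats::rbinom(n, 1, 0.077),
      sbp0 = sbp0,
      mmse0 = clamp(round(stats::rnorm(n, 28.2, 1.2)), 20, 30),
      smoking = sample(SMOKING_LEVELS, n, TRUE,
                       prob = c(0.315, 0.445, 0.241)),
      sbp = sbp0,
      total_cholesterol = clamp(stats::rnorm(n, 6.7, 1.2), 2.5, 12),
      bmi = clamp(stats::rnorm(n, 26.3, 3.6), 15, 45),
      alcohol = clamp(stats::rgamma(n, shape = 0.489, scale = 21.86), 0, 120),
      ht_med = stats::rbinom(n, 1, stats::plogis(-0.97 + 0.02 * (sbp0 - 137))),
      inc_heart_disease = 0, inc_diabetes = 0, inc_cancer = 0,
      inc_tia = 0, inc_parkinsonism = 0, other_outcome = 0
    )
  }
  models <- list(
    visit = list(coef = c("(Intercept)" = 3.78, age = -0.03, tt = -0.02)),
    smoking = list(
      start = c("(Intercept)" = -6.0),
      relapse = c("(Intercept)" = -3.2),
      quit = c("(Intercept)" = -1.8, lag_inc_heart_disease = 0.5)
    ),
    sbp = list(coef = c("(Intercept)" = 17.5, age = 0.25, lag_sbp = 0.75,
                        lag_ht_med = -2.0, tt = 0.3),
               sigma = 9, bounds = c(70, 260)),
    total_cholesterol = list(coef = c("(Intercept)" = 2.01,
                                      lag_total_cholesterol = 0.7),
                             sigma = 0.7, bounds = c(2, 13)),
    bmi = list(coef = c("(Intercept)" = 3.16, lag_bmi = 0.88),
               sigma = 1.1, bounds = c(14, 48)),
    alcohol = list(coef = c("(Intercept)" = 2.14, lag_alcohol = 0.8),
                   sigma = 6, bounds = c(0, 120)),
    ht_med = list(coef = c("(Intercept)" = -8.8, cur_sbp = 0.04,
                           lag_ht_med = 6.0)),
    inc_heart_disease = list(coef = c("(Intercept)" = -9.38, age = 0.07,
                                      lag_smoking_current = 0.5,
                                      lag_sbp = 0.008)),
    inc_diabetes = list(coef = c("(Intercept)" = -8.63, age = 0.04,
                                 lag_bmi = 0.08)),
    inc_cancer = list(coef = c("(Intercept)" = -7.19, age = 0.05,
                               lag_smoking_current = 0.6)),
    inc_tia = list(coef = c("(Intercept)" = -9.74, age = 0.06,
                            lag_sbp = 0.01)),
    inc_parkinsonism = list(coef = c("(Intercept)" = -9.44, age = 0.07)),
    other_outcome = list(coef = c("(Intercept)" = -12.24, age = 0.13,
                                  apoe4_carrier = 0.8, edu_further = -0.3,
                                  edu_higher = -0.5))
  )
  event_coefs <- c("(Intercept)" = -12.04, age = 0.07, sex = -0.25,
                   cur_sbp = 0.015, cur_smoking_current = 0.45,
                   cur_smoking_former = 0.10, cur_ht_med = 0.15,
                   cur_inc_heart_disease = 0.30, cur_inc_diabetes = 0.35,
                   cur_inc_tia = 0.50, cur_other_outcome = 0.20, tt = 0.02)
  death_coefs <- c("(Intercept)" = -11.25, age = 0.09, sex = -0.35,
                   cur_smoking_current = 0.50, cur_smoking_former = 0.20,
                   cur_sbp = 0.004, cur_inc_heart_disease = 0.50,
                   cur_inc_diabetes = 0.30, cur_inc_cancer = 0.80,
                   cur_other_outcome = 0.50, tt = 0.05)
  gf_dgp(covariates, sampler, models, event_coefs, death_coefs,
         ltfu_hazard = 0.004, K_max = 15L,
         visit_schedule = c(0L, 3L, 7L, 12L),
         baseline_fields = c("person_id", "age", "sex", "education", "apoe4",
                             "diabetes0", "heart_disease0", "sbp0", "mmse0"),
         baseline_terms = default_baseline_terms(),
         missing = c(sbp = 0.02, bmi = 0.03),
         label = "default cohort (13 time-varying covariates, K = 0..15)")
}

#' A reduced DGP for nested-simulation studies
#'
#' Three time-varying covariates (visit process, SBP, antihypertensive
#' medication), eight yearly intervals with visits at 0, 2 and 5, and the
#' same qualitative structure as [default_dgp()]: SBP raises the event
#' hazard, medication lowers SBP. Intended for designs that refit the whole
#' pipeline many times (bootstrap coverage studies), where the full
#' 13-covariate DGP would be needlessly slow.
#'
#' @return A `gf_dgp`.
#' @export
small_dgp <- function() {
  covariates <- list(
    list(name = "visit", family = "visit"),
    list(name = "sbp", family = "continuous"),
    list(name = "ht_med", family = "binary")
  )
  sampler <- function(n) {
    sbp0 <- clamp(stats::rnorm(n, 137.3, 21.5), 80, 240)
    data.frame(
      age = stats::runif(n, 55, 80),
      sex = stats::rbinom(n, 1, 0.573),
      sbp0 = sbp0,
      mmse0 = clamp(round(stats::rnorm(n, 28.2, 1.2)), 20, 30),
      sbp = sbp0,
      ht_med = stats::rbinom(n, 1, stats::plogis(-0.97 + 0.02 * (sbp0 - 137)))
    )
  }
  models <- list(
    visit = list(coef = c("(Intercept)" = 3.78, age = -0.03, tt = -0.02)),
    sbp = list(coef = c("(Intercept)" = 17.5, age = 0.25, lag_sbp = 0.75,
                        lag_ht_med = -2.0, tt = 0.3),
               sigma = 9, bounds = c(70, 260)),
    ht_med = list(coef = c("(Intercept)" = -8.8, cur_sbp = 0.04,
                           lag_ht_med = 6.0))
  )
  event_coefs <- c("(Intercept)" = -10.43, age = 0.06, sex = -0.20,
                   cur_sbp = 0.015, tt = 0.03)
  death_coefs <- c("(Intercept)" = -9.18, age = 0.07, sex = -0.30,
                   cur_sbp = 0.004, tt = 0.04)
  gf_dgp(covariates, sampler, models, event_coefs, death_coefs,
         ltfu_hazard = 0.004, K_max = 7L, visit_schedule = c(0L, 2L, 5L),
         baseline_fields = c("person_id", "age", "sex", "sbp0", "mmse0"),
         baseline_terms = c("age", "age2", "sex", "sbp0"),
         label = "reduced cohort (3 time-varying covariates, K = 0..7)")
}
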