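# Longitudinal cohort container: validation, file I/O, eligibility filtering,
# and protocol censoring at missed visits.

#' Construct a cohort table
#'
#' A cohort couples a baseline table (one row per person) with a long-format
#' person-interval table. Interval rows carry the time-varying covariates as
#' of interval `k` (updated at attended visits, carried forward otherwise)
#' and the exit indicators `event`, `death`, `censored`, of which at most one
#' equals 1 and only in a person's final record.
#'
#' @param baseline data.frame with a unique `person_id` column.
#' @param intervals data.frame with `person_id`, `k`, `visit`, the
#'   time-varying covariates, and `event`/`death`/`censored`.
#' @param K_max Administrative end interval (follow-up covers `0..K_max`).
#' @param config Optional [analysis_config()]; when supplied, validation also
#'   checks covariate-specific invariants (absorbing indicators, smoking
#'   transitions, carry-forward between visits).
#' @param validate Run [validate_cohort()] (default `TRUE`).
#' @return A `gf_cohort` object.
#' @export
as_cohort <- function(baseline, intervals, K_max, config = NULL,
                      validate = TRUE) {
  intervals <- intervals[order(intervals$person_id, intervals$k), ,
                         drop = FALSE]
  rownames(intervals) <- NULL
  rownames(baseline) <- NULL
  x <- structure(list(baseline = baseline, intervals = intervals,
                      K_max = as.integer(K_max)),
                 class = "gf_cohort")
  if (validate) validate_cohort(x, config)
  x
}

#' @export
print.gf_cohort <- function(x, ...) {
  cat(sprintf("<gf_cohort> %d persons, %d person-intervals, k = 0..%d\n",
              nrow(x$baseline), nrow(x$intervals), x$K_max))
  ev <- sum(x$intervals$event)
  de <- sum(x$intervals$death)
  ce <- sum(x$intervals$censored)
  cat(sprintf("  exits: %d events, %d deaths, %d censored\n", ev, de, ce))
  invisible(x)
}

# NA-safe "value changed between consecutive rows".
value_changed <- function(now, before) {
  both_na <- is.na(now) & is.na(before)
  one_na <- xor(is.na(now), is.na(before))
  diff <- !is.na(now) & !is.na(before) & (now != before)
  (one_na | diff) & !both_na
}

#' Validate a cohort table
#'
#' Checks the structural invariants: interval indices consecutive from 0
#' within person; at most one exit indicator set, and only in a person's last
#' record; every person in the interval table present at baseline; positive
#' baseline SBP where recorded. With a `config`, additionally checks that
#' absorbing indicators never revert, that smoking never transitions
#' never->former or back to never, and that covariates change between
#' intervals only at attended visits.
#'
#' @inheritParams as_cohort
#' @param cohort A `gf_cohort`.
#' @return The cohort, invisibly; errors name the offending person and
#'   interval.
#' @export
validate_cohort <- function(cohort, config = NULL) {
  bl <- cohort$baseline
  iv <- cohort$intervals
  need <- c("person_id", "k", "visit", "event", "death", "censored")
  miss <- setdiff(need, names(iv))
  if (length(miss)) stop_gf("interval table lacks column(s): %s",
                            paste(miss, collapse = ", "))
  if (anyDuplicated(bl$person_id)) stop_gf("duplicate person_id at baseline")
  unknown <- setdiff(unique(iv$person_id), bl$person_id)
  if (length(unknown)) {
    stop_gf("person %s has intervals but no baseline record", unknown[[1]])
  }
  if (!is.null(bl$sbp0) && any(!is.na(bl$sbp0) & bl$sbp0 <= 0)) {
    bad <- bl$person_id[which(!is.na(bl$sbp0) & bl$sbp0 <= 0)][1]
    stop_gf("person %s: baseline SBP must be positive", bad)
  }
  if (nrow(iv) == 0L) return(invisible(cohort))

  first <- !duplicated(iv$person_id)
  last <- !duplicated(iv$person_id, fromLast = TRUE)
  if (any(iv$k[first] != 0L)) {
    stop_gf("person %s: intervals must start at k = 0",
            iv$person_id[first][which(iv$k[first] != 0L)[1]])
  }
  dk <- c(1L, diff(iv$k))
  dk[first] <- 1L
  if (any(dk != 1L)) {
    i <- which(dk != 1L)[1]
    stop_gf("person %s: interval index not consecutive at k = %d",
            iv$person_id[i], iv$k[i])
  }
  nexit <- iv$event + iv$death + iv$censored
  if (any(nexit > 1L)) {
    i <- which(nexit > 1L)[1]
    stop_gf("person %s, k = %d: more than one exit indicator set",
            iv$person_id[i], iv$k[i])
  }
  if (any(nexit > 0L & !last)) {
    i <- which(nexit > 0L & !last)[1]
    stop_gf("person %s, k = %d: records exist after an exit record",
            iv$person_id[i], iv$k[i])
  }
  if (any(iv$k > cohort$K_max)) {
    i <- which(iv$k > cohort$K_max)[1]
    stop_gf("person %s, k = %d: interval beyond K_max = %d",
            iv$person_id[i], iv$k[i], cohort$K_max)
  }

  if (!is.null(config)) {
    within <- !first
    for (cv in config$covariates) {
      nm <- cv$name
      if (identical(cv$family, "visit") || is.null(iv[[nm]])) next
      now <- iv[[nm]]
      prev <- c(now[1], now[-length(now)])
      changed <- value_changed(now, prev) & within
      if (identical(cv$family, "absorbing")) {
        revert <- within & !is.na(now) & !is.na(prev) & prev == 1 & now == 0
        if (any(revert)) {
          i <- which(revert)[1]
          stop_gf("person %s, k = %d: absorbing covariate '%s' reverted 1->0",
                  iv$person_id[i], iv$k[i], nm)
        }
      }
      if (identical(cv$family, "smoking")) {
        bad_lvl <- !is.na(now) & !now %in% SMOKING_LEVELS
        if (any(bad_lvl)) {
          i <- which(bad_lvl)[1]
          stop_gf("person %s, k = %d: invalid smoking value '%s'",
                  iv$person_id[i], iv$k[i], now[i])
        }
        forb <- within & !is.na(now) & !is.na(prev) &
          ((prev == "never" & now == "former") |
             (prev != "never" & now == "never"))
        if (any(forb)) {
          i <- which(forb)[1]
          stop_gf("person %s, k = %d: forbidden smoking transition %s->%s",
                  iv$person_id[i], iv$k[i], prev[i], now[i])
        }
      }
      offvisit <- changed & iv$visit != 1
      if (any(offvisit)) {
        i <- which(offvisit)[1]
        stop_gf("person %s, k = %d: covariate '%s' changed without a visit",
                iv$person_id[i], iv$k[i], nm)
      }
    }
  }
  invisible(cohort)
}

#' Read a cohort from baseline and interval CSV files
#'
#' @param path_baseline,path_intervals Paths to comma-separated files with a
#'   header row.
#' @param config An [analysis_config()]; its `baseline_fields` and covariate
#'   names define the expected columns.
#' @return A validated `gf_cohort`.
#' @export
read_cohort <- function(path_baseline, path_intervals, config) {
  bl <- utils::read.csv(path_baseline, stringsAsFactors = FALSE)
  iv <- utils::read.csv(path_intervals, stringsAsFactors = FALSE)
  miss_b <- setdiff(config$baseline_fields, names(bl))
  if (length(miss_b)) {
    stop_gf("baseline file lacks column(s): %s", paste(miss_b, collapse = ", "))
  }
  need_iv <- c("person_id", "k", "visit", config_covariate_names(config),
               "event", "death", "censored")
  need_iv <- setdiff(need_iv, "visit")  # visit covariate == visit column
  miss_i <- setdiff(need_iv, names(iv))
  if (length(miss_i)) {
    stop_gf("interval file lacks column(s): %s", paste(miss_i, collapse = ", "))
  }
  as_cohort(bl, iv, K_max = config$K_max, config = config)
}

#' Write a cohort to CSV files
#'
#' @param cohort A `gf_cohort`.
#' @param path_baseline,path_intervals Output paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, path_baseline, path_intervals) {
  utils::write.csv(cohort$baseline, path_baseline, row.names = FALSE)
  utils::write.csv(cohort$intervals, path_intervals, row.names = FALSE)
  invisible(c(path_baseline, path_intervals))
}

# Baseline joined with the interval-0 record (for eligibility predicates and
# baseline resampling, which need the interval-0 covariate values).
baseline0 <- function(cohort) {
  iv0 <- cohort$intervals[cohort$intervals$k == 0L, , drop = FALSE]
  iv0 <- iv0[, setdiff(names(iv0), c("k", "event", "death", "censored")),
             drop = FALSE]
  merge(cohort$baseline, iv0, by = "person_id", sort = TRUE,
        suffixes = c("", ".iv0"))
}

#' Apply eligibility criteria to a cohort
#'
#' Persons failing any criterion are removed together with all their interval
#' records. Criteria are applied sequentially (age bounds, MMSE threshold,
#' exclusion flags, complete-case fields), and the count removed at each step
#' is recorded in a flowchart-style report attached as attribute
#' `eligibility_report`.
#'
#' @param cohort A `gf_cohort`.
#' @param criteria An [eligibility_criteria()] object.
#' @return The filtered `gf_cohort`; errors if no one remains eligible.
#' @export
apply_eligibility <- function(cohort, criteria = eligibility_criteria()) {
  b0 <- baseline0(cohort)
  keep <- rep(TRUE, nrow(b0))
  report <- data.frame(criterion = character(0), n_excluded = integer(0))
  note <- function(label, drop) {
    report <<- rbind(report, data.frame(criterion = label,
                                        n_excluded = sum(drop & keep)))
    keep <<- keep & !drop
  }
  if (!is.null(b0$age)) {
    note(sprintf("age outside [%s, %s]", criteria$age_min, criteria$age_max),
         is.na(b0$age) | b0$age < criteria$age_min | b0$age > criteria$age_max)
  }
  if (!is.null(b0$mmse0) && !is.null(criteria$mmse_min)) {
    note(sprintf("MMSE below %s", criteria$mmse_min),
         !is.na(b0$mmse0) & b0$mmse0 < criteria$mmse_min)
  }
  for (fl in criteria$exclude_flags) {
    if (is.null(b0[[fl]])) stop_gf("exclusion flag '%s' not found", fl)
    note(sprintf("prior %s", fl), !is.na(b0[[fl]]) & b0[[fl]] == 1)
  }
  if (length(criteria$required_complete)) {
    fields <- intersect(criteria$required_complete, names(b0))
    incomplete <- Reduce(`|`, lapply(fields, function(f) is.na(b0[[f]])),
                         rep(FALSE, nrow(b0)))
    note("incomplete baseline information", incomplete)
  }
  ids <- b0$person_id[keep]
  if (length(ids) == 0L) stop_gf("no persons remain after eligibility filtering")
  out <- as_cohort(
    cohort$baseline[cohort$baseline$person_id %in% ids, , drop = FALSE],
    cohort$intervals[cohort$intervals$person_id %in% ids, , drop = FALSE],
    K_max = cohort$K_max, validate = FALSE
  )
  attr(out, "eligibility_report") <- report
  out
}

#' Censor persons at missed scheduled visits
#'
#' Implements the protocol rule that a person who skips a scheduled
#' examination is censored at the last interval in which that visit could
#' have taken place (the visit's window end, from the configuration). Records
#' after the censoring interval are dropped; the record at the censoring
#' interval receives `censored = 1` unless an event or death already occurred
#' there (exits within an interval precede censoring).
#'
#' @param cohort A `gf_cohort`.
#' @param config An [analysis_config()] supplying `visit_schedule` and
#'   `visit_window_end`.
#' @return A `gf_cohort`, never with more person-intervals than the input.
#' @export
censor_at_missed_visit <- function(cohort, config) {
  iv <- cohort$intervals
  sched1 <- config$visit_schedule[config$visit_schedule > 0L]
  if (length(sched1) == 0L || nrow(iv) == 0L) return(cohort)
  wend <- config$visit_window_end
  missed <- iv$k %in% sched1 & iv$visit == 0
  if (!any(missed)) return(cohort)
  # earliest missed scheduled visit per person
  mrows <- iv[missed, c("person_id", "k")]
  mrows <- mrows[order(mrows$person_id, mrows$k), ]
  mrows <- mrows[!duplicated(mrows$person_id), ]
  censor_k <- wend[as.character(mrows$k)]
  ck <- censor_k[match(iv$person_id, mrows$person_id)]
  ck[is.na(ck)] <- .Machine$integer.max
  keep <- iv$k <= ck
  iv <- iv[keep, , drop = FALSE]
  cki <- ck[keep]
  at_cut <- iv$k == cki & iv$event == 0 & iv$death == 0
  iv$censored[at_cut] <- 1L
  as_cohort(cohort$baseline, iv, K_max = cohort$K_max, validate = FALSE)
}

#' Nonparametric observed cumulative incidence
#'
#' Discrete-time Aalen-Johansen-style estimate of the risk of the event from
#' the observed person-interval records: per interval, the death hazard is
#' estimated among those at risk and the event hazard among those at risk who
#' did not die that interval (death precedes the event within an interval);
#' censored persons leave the risk set after their censoring interval.
#'
#' @param cohort A `gf_cohort`.
#' @param mode Competing-event handling, as in [analysis_config()].
#' @return List with `risk_by_interval` (cumulative, one entry per interval
#'   `0..K_max`), `risk` (the final value), and `n_events`, `n_deaths`.
#' @export
observed_risk <- function(cohort, mode = c("competing", "censor_death",
                                           "composite")) {
  mode <- match.arg(mode)
  iv <- cohort$intervals
  K <- cohort$K_max
  risk <- 0
  surv <- 1
  out <- numeric(K + 1L)
  for (k in 0:K) {
    rows <- iv$k == k
    n_k <- sum(rows)
    if (n_k == 0L) {
      out[k + 1L] <- risk
      next
    }
    d_k <- sum(iv$death[rows])
    e_k <- sum(iv$event[rows])
    hd <- d_k / n_k
    he <- if (n_k - d_k > 0) e_k / (n_k - d_k) else 0
    if (mode == "competing") {
      risk <- risk + surv * (1 - hd) * he
      surv <- surv * (1 - hd) * (1 - he)
    } else if (mode == "censor_death") {
      risk <- risk + surv * he
      surv <- surv * (1 - he)
    } else {
      hc <- 1 - (1 - hd) * (1 - he)
      risk <- risk + surv * hc
      surv <- surv * (1 - hc)
    }
    out[k + 1L] <- risk
  }
  list(risk_by_interval = out, risk = risk,
       n_events = sum(iv$event), n_deaths = sum(iv$death))
}
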