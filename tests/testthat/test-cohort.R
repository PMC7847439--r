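smoke_config <- function() {
  analysis_config(
    covariates = list(covariate_spec("visit", "visit", terms = "tt"),
                      covariate_spec("smoking", "smoking", terms = "tt"),
                      covariate_spec("sbp", "continuous", terms = "lag_sbp"),
                      covariate_spec("inc_tia", "absorbing", terms = "tt")),
    baseline_terms = character(0), K_max = 4L, visit_schedule = c(0L, 2L),
    baseline_fields = c("person_id", "age", "sbp0", "mmse0")
  )
}

mini_intervals <- function(smoking, visit = c(1, 0, 1, 0, 0),
                           inc_tia = c(0, 0, 0, 0, 0), event = c(0, 0, 0, 0, 1)) {
  data.frame(person_id = 1, k = 0:4, visit = visit, smoking = smoking,
             sbp = 130, inc_tia = inc_tia, event = event, death = 0,
             censored = 0)
}

mini_baseline <- data.frame(person_id = 1, age = 60, sbp0 = 130, mmse0 = 28)

test_that("a valid single-person cohort round-trips through CSV", {
  cfg <- smoke_config()
  bl <- mini_baseline
  iv <- data.frame(person_id = 1, k = 0:1, visit = c(1, 0),
                   smoking = "never", sbp = 130, inc_tia = 0,
                   event = c(0, 1), death = 0, censored = 0)
  fb <- tempfile(fileext = ".csv")
  fi <- tempfile(fileext = ".csv")
  utils::write.csv(bl, fb, row.names = FALSE)
  utils::write.csv(iv, fi, row.names = FALSE)
  ch <- read_cohort(fb, fi, cfg)
  expect_s3_class(ch, "gf_cohort")
  expect_equal(nrow(ch$baseline), 1L)
  expect_equal(nrow(ch$intervals), 2L)
})

test_that("write_cohort then read_cohort reproduces a synthetic cohort", {
  dgp <- small_dgp()
  cfg <- config_for_dgp(dgp)
  ch <- generate_cohort(dgp, 80, seed = 21)
  fb <- tempfile(fileext = ".csv")
  fi <- tempfile(fileext = ".csv")
  write_cohort(ch, fb, fi)
  back <- read_cohort(fb, fi, cfg)
  expect_equal(back$baseline, ch$baseline, tolerance = 1e-12)
  expect_equal(back$intervals, ch$intervals, tolerance = 1e-12)
  expect_equal(back$K_max, ch$K_max)
})

test_that("schema errors name the missing column", {
  cfg <- smoke_config()
  fb <- tempfile(fileext = ".csv")
  fi <- tempfile(fileext = ".csv")
  utils::write.csv(mini_baseline, fb, row.names = FALSE)
  iv <- mini_intervals("never")
  utils::write.csv(iv[, setdiff(names(iv), "sbp")], fi, row.names = FALSE)
  expect_error(read_cohort(fb, fi, cfg), "sbp")
})

test_that("forbidden smoking transitions fail validation", {
  cfg <- smoke_config()
  iv <- mini_intervals(c("never", "never", "former", "former", "former"))
  expect_error(as_cohort(mini_baseline, iv, K_max = 4L, config = cfg),
               "forbidden smoking transition")
  iv <- mini_intervals(c("current", "current", "never", "never", "never"))
  expect_error(as_cohort(mini_baseline, iv, K_max = 4L, config = cfg),
               "forbidden smoking transition")
  # quitting (current -> former) at a visit is legitimate
  iv <- mini_intervals(c("current", "current", "former", "former", "former"))
  expect_silent(as_cohort(mini_baseline, iv, K_max = 4L, config = cfg))
})

test_that("absorbing indicators may not revert and covariates may not change off-visit", {
  cfg <- smoke_config()
  iv <- mini_intervals("never", inc_tia = c(0, 0, 1, 1, 0))
  expect_error(as_cohort(mini_baseline, iv, K_max = 4L, config = cfg),
               "reverted")
  iv <- mini_intervals("never")
  iv$sbp <- c(130, 150, 150, 150, 150)  # change at k = 1 without a visit
  expect_error(as_cohort(mini_baseline, iv, K_max = 4L, config = cfg),
               "without a visit")
})

test_that("records after an exit and non-consecutive intervals fail validation", {
  iv <- mini_intervals("never", event = c(0, 1, 0, 0, 0))
  expect_error(as_cohort(mini_baseline, iv, K_max = 4L),
               "after an exit")
  iv <- mini_intervals("never")
  iv$k <- c(0, 1, 3, 4, 5)
  expect_error(as_cohort(mini_baseline, iv, K_max = 5L), "consecutive")
})

test_that("eligibility filtering applies each criterion and reports counts", {
  bl <- data.frame(person_id = 1:5,
                   age = c(60, 82, 70, 65, 75),
                   sbp0 = c(130, 125, NA, 140, 150),
                   mmse0 = c(28, 29, 27, 26, 25))
  iv <- data.frame(person_id = 1:5, k = 0, visit = 1,
                   smoking = "never", sbp = c(130, 125, 135, 140, 150),
                   bmi = 26, ht_med = 0, event = 0, death = 0, censored = 0)
  ch <- as_cohort(bl, iv, K_max = 4L)
  out <- apply_eligibility(ch)
  # person 2 (age 82), person 3 (missing sbp0), person 5 (MMSE 25) excluded;
  # person 4 with MMSE exactly 26 retained (exclusion is strictly below 26)
  expect_setequal(out$baseline$person_id, c(1, 4))
  rep <- attr(out, "eligibility_report")
  expect_equal(rep$n_excluded[rep$criterion == "age outside [55, 80]"], 1L)
  expect_equal(rep$n_excluded[rep$criterion == "MMSE below 26"], 1L)
  expect_equal(rep$n_excluded[rep$criterion == "incomplete baseline information"], 1L)
  # idempotence
  again <- apply_eligibility(out)
  expect_equal(again$baseline, out$baseline)
  expect_equal(again$intervals, out$intervals)
})

test_that("eligibility is a no-op when everyone qualifies and errors when no one does", {
  bl <- data.frame(person_id = 1:2, age = c(60, 70), sbp0 = c(130, 140),
                   mmse0 = c(28, 29))
  iv <- data.frame(person_id = 1:2, k = 0, visit = 1, smoking = "never",
                   sbp = c(130, 140), bmi = 26, ht_med = 0,
                   event = 0, death = 0, censored = 0)
  ch <- as_cohort(bl, iv, K_max = 2L)
  out <- apply_eligibility(ch)
  expect_equal(out$baseline, ch$baseline)
  expect_equal(out$intervals, ch$intervals)
  expect_error(apply_eligibility(ch, eligibility_criteria(age_min = 90)),
               "no persons remain")
})

test_that("missed scheduled visits censor at the window end", {
  cfg <- mini_censor_config()
  ch <- mini_censor_cohort()
  out <- censor_at_missed_visit(ch, cfg)
  # P1 fully observed: unchanged
  expect_equal(out$intervals[out$intervals$person_id == 1, ],
               ch$intervals[ch$intervals$person_id == 1, ],
               ignore_attr = TRUE)
  # P2 missed the k = 2 visit: truncated at window end 3, censored there
  p2 <- out$intervals[out$intervals$person_id == 2, ]
  expect_equal(max(p2$k), 3)
  expect_equal(p2$censored, c(0, 0, 0, 1))
  # P3 had the event before the missed visit could matter: unchanged
  expect_equal(out$intervals[out$intervals$person_id == 3, ],
               ch$intervals[ch$intervals$person_id == 3, ],
               ignore_attr = TRUE)
  # person-intervals never increase, and the result is a valid cohort
  expect_lte(nrow(out$intervals), nrow(ch$intervals))
  expect_silent(validate_cohort(out))
})

test_that("fully observed cohorts pass censoring unchanged", {
  cfg <- mini_censor_config()
  iv <- data.frame(person_id = 1, k = 0:4, visit = c(1, 0, 1, 0, 0),
                   sbp = 130, event = 0, death = 0, censored = 0)
  ch <- as_cohort(data.frame(person_id = 1), iv, K_max = 4L)
  out <- censor_at_missed_visit(ch, cfg)
  expect_equal(out$intervals, ch$intervals, ignore_attr = TRUE)
})
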