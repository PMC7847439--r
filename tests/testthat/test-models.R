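make_fit <- function(coef, family = "binomial") {
  terms <- setdiff(names(coef), "(Intercept)")
  f <- if (length(terms)) stats::reformulate(terms, ".y") else .y ~ 1
  structure(list(name = "m", family = family, degenerate = FALSE,
                 coef = coef, terms_obj = stats::delete.response(stats::terms(f)),
                 sigma = 0, n = 0L, converged = TRUE),
            class = "gf_fit")
}

test_that("predict_probability is the inverse logit of the linear predictor", {
  f <- make_fit(c("(Intercept)" = 0, x = 0))
  expect_equal(predict_probability(f, data.frame(x = c(-5, 0, 17))),
               c(0.5, 0.5, 0.5))
  f9 <- make_fit(c("(Intercept)" = log(9)))
  expect_equal(predict_probability(f9, data.frame(x = 1)), 0.9)
  fx <- make_fit(c("(Intercept)" = -1, x = 2))
  p <- predict_probability(fx, data.frame(x = c(0, 1, 2)))
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0 & p < 1))
})

test_that("matrix designs must conform to the coefficient vector", {
  fx <- make_fit(c("(Intercept)" = -1, x = 2))
  expect_equal(predict_probability(fx, cbind(1, c(0, 1))),
               stats::plogis(c(-1, 1)))
  expect_error(predict_probability(fx, cbind(1, 0, 0)), "coefficients")
})

test_that("event-model fits recover the true hazard coefficients", {
  dgp <- small_dgp()
  cfg <- config_for_dgp(dgp)
  ch <- censor_at_missed_visit(apply_eligibility(
    generate_cohort(dgp, 5000, seed = 101),
    eligibility_criteria(required_complete = "sbp0")), cfg)
  fits <- fit_gformula_models(ch, cfg)
  ev <- fits$event
  for (nm in c("age", "sex", "cur_sbp", "tt")) {
    truth <- dgp$event_coefs[[nm]]
    expect_lt(abs(ev$coef[[nm]] - truth), 3 * ev$se[[nm]])
  }
})

test_that("covariate transition fits recover the true coefficients", {
  dgp <- small_dgp()
  cfg <- config_for_dgp(dgp)
  ch <- generate_cohort(dgp, 5000, seed = 102)
  fits <- fit_covariate_models(ch, cfg)
  sbp <- fits$sbp
  for (nm in c("lag_sbp", "age", "lag_ht_med", "tt")) {
    expect_lt(abs(sbp$coef[[nm]] - dgp$models$sbp$coef[[nm]]),
              3 * sbp$se[[nm]])
  }
  expect_lt(abs(sbp$sigma - dgp$models$sbp$sigma), 0.5)
  hm <- fits$ht_med
  for (nm in c("cur_sbp", "lag_ht_med")) {
    expect_lt(abs(hm$coef[[nm]] - dgp$models$ht_med$coef[[nm]]),
              3 * hm$se[[nm]])
  }
  # continuous truncation bounds come from the observed range
  expect_equal(fits$sbp$bounds, range(ch$intervals$sbp))
})

test_that("fitting is deterministic and respects the risk-set definitions", {
  dgp <- small_dgp()
  cfg <- config_for_dgp(dgp)
  ch <- generate_cohort(dgp, 1000, seed = 103)
  f1 <- fit_gformula_models(ch, cfg)
  f2 <- fit_gformula_models(ch, cfg)
  expect_identical(f1$event$coef, f2$event$coef)
  expect_identical(f1$covariates$sbp$coef, f2$covariates$sbp$coef)
})

test_that("constant covariates are flagged degenerate and carried", {
  dgp <- small_dgp()
  dgp$models$ht_med$coef <- c("(Intercept)" = -30)  # nobody starts treatment
  sampler0 <- dgp$baseline_sampler
  dgp$baseline_sampler <- function(n) {
    out <- sampler0(n)
    out$ht_med <- 0
    out
  }
  cfg <- config_for_dgp(dgp)
  ch <- generate_cohort(dgp, 800, seed = 104)
  fits <- fit_covariate_models(ch, cfg)
  expect_true(fits$ht_med$degenerate)
  expect_equal(fits$ht_med$constant, 0)
  haz <- fit_event_models(ch, cfg)
  r <- run_gformula(ch, cfg,
                    fits = structure(list(covariates = fits,
                                          event = haz$event,
                                          death = haz$death,
                                          mode = "competing"),
                                     class = "gf_fits"),
                    seed = 9, n_sim = 500)
  expect_s3_class(r, "gf_risk")
})

test_that("a cohort without deaths makes the composite fit equal the event fit", {
  dgp <- small_dgp()
  dgp$death_coefs[] <- 0
  dgp$death_coefs[["(Intercept)"]] <- -Inf
  cfg_comp <- config_for_dgp(dgp, mode = "composite")
  cfg_cens <- config_for_dgp(dgp, mode = "censor_death")
  ch <- generate_cohort(dgp, 2000, seed = 105)
  expect_equal(sum(ch$intervals$death), 0)
  f_comp <- fit_event_models(ch, cfg_comp, mode = "composite")
  f_cens <- fit_event_models(ch, cfg_cens, mode = "censor_death")
  expect_equal(f_comp$composite$coef, f_cens$event$coef, tolerance = 1e-10)
})

test_that("cohorts with no events are rejected", {
  dgp <- small_dgp()
  dgp$event_coefs[] <- 0
  dgp$event_coefs[["(Intercept)"]] <- -Inf
  cfg <- config_for_dgp(dgp)
  ch <- generate_cohort(dgp, 300, seed = 106)
  expect_error(fit_event_models(ch, cfg), "no events")
})

test_that("smoking transition fits respect the structural zeros", {
  dgp <- default_dgp()
  cfg <- config_for_dgp(dgp)
  ch <- generate_cohort(dgp, 4000, seed = 107)
  fits <- fit_covariate_models(ch, cfg)
  smk <- fits$smoking
  expect_named(smk, c("start", "relapse", "quit"))
  # initiation among never-smokers is rare in the DGP; its fitted baseline
  # probability should be far below the quit probability among current smokers
  fr <- data.frame(age = 66, age2 = 66^2, sex = 1, tt = 3,
                   lag_inc_heart_disease = 0)
  p_start <- if (smk$start$degenerate) smk$start$constant else
    predict_probability(smk$start, fr)
  p_quit <- predict_probability(smk$quit, fr)
  expect_lt(p_start, p_quit)
})
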