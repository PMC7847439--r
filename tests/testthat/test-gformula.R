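test_that("cumulative incidence handles the degenerate cases exactly", {
  z <- rep(0, 4)
  for (m in c("competing", "censor_death", "composite")) {
    out <- cumulative_incidence(z, z, mode = m)
    expect_equal(out$risk_event, rep(0, 4))
  }
  # one interval, h_event = 0.1, h_death = 0: all modes agree on 0.1
  expect_equal(cumulative_incidence(0.1, 0, "competing")$risk_event, 0.1)
  expect_equal(cumulative_incidence(0.1, 0, "censor_death")$risk_event, 0.1)
  expect_error(cumulative_incidence(c(0.2, 1.4), c(0, 0), "competing"),
               "\\[0, 1\\]")
})

test_that("the two-interval competing risk matches the outcome-tree enumeration", {
  # four-branch tree: event in interval 1 after surviving death (0.9 * 0.1),
  # or survive both (0.9 * 0.9) then event in interval 2 (0.9 * 0.1)
  by_hand <- 0.9 * 0.1 + (0.9 * 0.9) * (0.9 * 0.1)
  out <- cumulative_incidence(c(0.1, 0.1), c(0.1, 0.1), "competing")
  expect_equal(out$risk_event[2], 0.1629, tolerance = 1e-12)
  expect_equal(out$risk_event[2], by_hand, tolerance = 1e-12)
})

test_that("cumulative incidence agrees with recursive enumeration on random hazards", {
  set.seed(14)
  for (rep in 1:20) {
    K <- sample(2:6, 1)
    he <- runif(K, 0, 0.3)
    hd <- runif(K, 0, 0.3)
    for (m in c("competing", "censor_death", "composite")) {
      got <- cumulative_incidence(he, hd, m)$risk_event[K]
      expect_equal(got, brute_force_cif(he, hd, m), tolerance = 1e-12)
    }
  }
})

test_that("eliminating death never lowers an individual's risk", {
  set.seed(15)
  he <- matrix(runif(200, 0, 0.3), 20, 10)
  hd <- matrix(runif(200, 0, 0.3), 20, 10)
  cmp <- cumulative_incidence(he, hd, "competing")
  cen <- cumulative_incidence(he, hd, "censor_death")
  expect_true(all(cen$per_person_risk >= cmp$per_person_risk - 1e-12))
  expect_true(all(cmp$per_person_risk + cmp$per_person_death <= 1 + 1e-12))
})

test_that("baseline resampling is reproducible and respects the source", {
  dgp <- small_dgp()
  ch <- generate_cohort(dgp, 500, seed = 201)
  a <- sample_baseline(ch, 1000, seed = 3)
  b <- sample_baseline(ch, 1000, seed = 3)
  expect_identical(a, b)
  # resampling CLT: mean age within 3 SEs of the cohort mean
  b0 <- gfemula:::baseline0(ch)
  se <- stats::sd(b0$age) / sqrt(1000)
  expect_lt(abs(mean(a$age) - mean(b0$age)), 3 * se)
  # single-person cohort: every draw is that person
  one <- as_cohort(ch$baseline[1, , drop = FALSE],
                   ch$intervals[ch$intervals$person_id ==
                                  ch$baseline$person_id[1], , drop = FALSE],
                   K_max = ch$K_max, validate = FALSE)
  d <- sample_baseline(one, 50, seed = 1)
  expect_equal(unique(d$person_id), ch$baseline$person_id[1])
  empty <- ch
  empty$baseline <- ch$baseline[0, ]
  empty$intervals <- ch$intervals[0, ]
  expect_error(sample_baseline(empty, 10, seed = 1), "empty")
})

test_that("the g-formula run is deterministic and structurally sound", {
  dgp <- small_dgp()
  cfg <- config_for_dgp(dgp, n_sim = 1500, seed = 4)
  ch <- censor_at_missed_visit(apply_eligibility(
    generate_cohort(dgp, 1500, seed = 202),
    eligibility_criteria(required_complete = "sbp0")), cfg)
  fits <- fit_gformula_models(ch, cfg)
  r1 <- run_gformula(ch, cfg, builtin_strategies()[[2]], fits = fits, seed = 6)
  r2 <- run_gformula(ch, cfg, builtin_strategies()[[2]], fits = fits, seed = 6)
  expect_identical(r1$risk_by_interval, r2$risk_by_interval)
  expect_identical(r1$pct_intervened, r2$pct_intervened)
  expect_true(all(diff(r1$risk_by_interval) >= 0))
  expect_true(all(r1$risk_by_interval >= 0 & r1$risk_by_interval <= 1))
  expect_true(all(r1$risk_by_interval + r1$risk_death_by_interval <= 1 + 1e-12))
})

test_that("simulated histories respect strategy postconditions", {
  dgp <- small_dgp()
  cfg <- config_for_dgp(dgp, n_sim = 1000, seed = 4)
  ch <- generate_cohort(dgp, 1200, seed = 203)
  fits <- fit_gformula_models(ch, cfg)
  nc <- run_gformula(ch, cfg, builtin_strategies()[[1]], fits = fits,
                     seed = 8, collect_diagnostics = TRUE)
  expect_false(any(nc$intervened))
  expect_equal(nc$pct_intervened, rep(0, cfg$K_max + 1L))
  s1 <- run_gformula(ch, cfg, builtin_strategies()[[2]], fits = fits,
                     seed = 8, collect_diagnostics = TRUE)
  max_sbp <- vapply(s1$state_range, function(r) r$sbp[2], 0)
  expect_true(all(max_sbp <= 120))
  s2 <- run_gformula(ch, cfg, builtin_strategies()[[3]], fits = fits,
                     seed = 8, collect_diagnostics = TRUE)
  expect_true(all(vapply(s2$state_range, function(r) r$sbp[2], 0) <= 140))
  # the tighter threshold requires intervening on at least as many people
  expect_true(all(s1$pct_intervened >= s2$pct_intervened - 1e-12))
  expect_true(all(diff(s1$pct_intervened) >= 0))
})

test_that("frozen dynamics carry the baseline state forward", {
  dgp <- small_dgp()
  dgp$models$sbp$sigma <- 1e-12
  dgp$models$sbp$coef <- c("(Intercept)" = 0, lag_sbp = 1)
  dgp$models$ht_med$coef <- c("(Intercept)" = -30, lag_ht_med = 60)
  cfg <- config_for_dgp(dgp, n_sim = 200, seed = 4)
  cfg$covariates[[2]]$bounds <- NULL
  ch <- generate_cohort(dgp, 500, seed = 204)
  fits <- fit_gformula_models(ch, cfg)
  # force exact persistence in the fitted models too
  fits$covariates$sbp$coef[] <- 0
  fits$covariates$sbp$coef[["lag_sbp"]] <- 1
  fits$covariates$sbp$sigma <- 0
  fits$covariates$sbp$bounds <- c(-Inf, Inf)
  fits$covariates$ht_med$degenerate <- TRUE
  fits$covariates$ht_med$constant <- 0
  nc <- run_gformula(ch, cfg, fits = fits, seed = 12,
                     collect_diagnostics = TRUE)
  rng <- vapply(nc$state_range, function(r) r$sbp, c(0, 0))
  expect_equal(rng[1, ], rep(rng[1, 1], ncol(rng)))
  expect_equal(rng[2, ], rep(rng[2, 1], ncol(rng)))
})

test_that("contrast computes RR and RD on the documented scales", {
  ct <- contrast(0.103, 0.103)
  expect_equal(ct$rr, 1)
  expect_equal(ct$rd, 0)
  ct <- contrast(0.085, 0.103)
  expect_equal(ct$rr, 0.085 / 0.103, tolerance = 1e-12)
  expect_equal(ct$rr, 0.825, tolerance = 0.001)
  expect_equal(ct$rd, -1.8, tolerance = 0.01)
  ct0 <- contrast(0, 0.2)
  expect_equal(ct0$rr, 0)
  expect_equal(ct0$rd, -20)
  expect_error(contrast(0.1, 0), "undefined")
})
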