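small_cohort_fixture <- function(n = 800, seed = 301,
                                 cfg = config_for_dgp(small_dgp(),
                                                      n_sim = 800, seed = 2,
                                                      n_boot = 10)) {
  ch <- generate_cohort(small_dgp(), n, seed = seed)
  ch <- apply_eligibility(ch, eligibility_criteria(required_complete = "sbp0"))
  censor_at_missed_visit(ch, cfg)
}

test_that("with two replicates the percentile CI is the min and max", {
  cfg <- config_for_dgp(small_dgp(), n_sim = 400, seed = 2, n_boot = 2)
  ch <- small_cohort_fixture(500, 311, cfg)
  eff <- bootstrap_cis(ch, cfg, strategies = builtin_strategies()[1],
                       B = 2, seed = 13, n_sim_boot = 400)
  reps <- attr(eff, "replicates")
  expect_equal(eff$risk_lo[1], 100 * min(reps[, 1]))
  expect_equal(eff$risk_hi[1], 100 * max(reps[, 1]))
})

test_that("bootstrap CIs contain the point estimate and are seed-stable", {
  cfg <- config_for_dgp(small_dgp(), n_sim = 600, seed = 2, n_boot = 20)
  ch <- small_cohort_fixture(700, 312, cfg)
  strategies <- builtin_strategies()[c(1, 3)]
  eff <- bootstrap_cis(ch, cfg, strategies = strategies, B = 20, seed = 14,
                       n_sim_boot = 600)
  expect_true(all(eff$risk_lo <= eff$risk_pct & eff$risk_pct <= eff$risk_hi))
  expect_true(is.na(eff$rr[1]) && is.na(eff$rd[1]))
  expect_equal(eff$total_intervened_pct[1], 0)
  eff2 <- bootstrap_cis(ch, cfg, strategies = strategies, B = 20, seed = 14,
                        n_sim_boot = 600)
  expect_identical(as.data.frame(eff), as.data.frame(eff2))
})

test_that("bootstrap CIs widen when the cohort shrinks fourfold", {
  cfg <- config_for_dgp(small_dgp(), n_sim = 500, seed = 2, n_boot = 15)
  big <- small_cohort_fixture(1600, 313, cfg)
  small <- small_cohort_fixture(400, 313, cfg)
  e_big <- bootstrap_cis(big, cfg, strategies = builtin_strategies()[1],
                         B = 15, seed = 15, n_sim_boot = 500)
  e_small <- bootstrap_cis(small, cfg, strategies = builtin_strategies()[1],
                           B = 15, seed = 15, n_sim_boot = 500)
  expect_gt(e_small$risk_hi[1] - e_small$risk_lo[1],
            e_big$risk_hi[1] - e_big$risk_lo[1])
})

test_that("natural-course diagnostics calibrate on a saturated toy model", {
  dgp <- toy_dgp()
  cfg <- toy_config(n_sim = 20000)
  ch <- make_toy_cohort(4000, seed = 321)
  d <- natural_course_diagnostics(ch, cfg, min_n = 20)
  a_rows <- d$table[d$table$covariate == "a", ]
  expect_gt(nrow(a_rows), 0)
  # saturated fit: simulated and observed means agree up to MC error
  mc_tol <- 3 * (0.5 / sqrt(4000) + 0.5 / sqrt(20000))
  expect_true(all(abs(a_rows$diff) < mc_tol))
  expect_true(all(d$converged))
})

test_that("subgroup catalog and partition behave as documented", {
  sg <- builtin_subgroups()
  expect_length(sg, 6L)
  ch <- generate_cohort(default_dgp(), 600, seed = 331)
  b0 <- gfemula:::baseline0(ch)
  men <- sum(sg$men$predicate(b0))
  women <- sum(sg$women$predicate(b0))
  expect_equal(men + women, nrow(b0))
  expect_equal(sum(sg$age_55_65$predicate(b0)) +
                 sum(sg$age_66_80$predicate(b0)), nrow(b0))
})

test_that("the identity subgroup reproduces the main analysis", {
  cfg <- config_for_dgp(small_dgp(), n_sim = 500, seed = 2)
  ch <- small_cohort_fixture(600, 332, cfg)
  strategies <- builtin_strategies()[c(1, 3)]
  main <- run_strategies(ch, cfg, strategies, seed = 17)
  all_sg <- list(all = list(name = "All",
                            predicate = function(b0) rep(TRUE, nrow(b0))))
  sub <- subgroup_analysis(ch, cfg, subgroups = all_sg,
                           strategies = strategies, seed = 17)
  expect_equal(sub$risk_pct, main$effects$risk_pct)
  expect_equal(sub$n_subgroup[1], nrow(ch$baseline))
  empty_sg <- list(none = list(name = "None",
                               predicate = function(b0) rep(FALSE, nrow(b0))))
  expect_error(subgroup_analysis(ch, cfg, subgroups = empty_sg,
                                 strategies = strategies, seed = 17),
               "empty")
})

test_that("reordering covariates reruns the pipeline and reports spread", {
  cfg <- config_for_dgp(small_dgp(), n_sim = 400, seed = 2)
  ch <- small_cohort_fixture(600, 333, cfg)
  strategies <- builtin_strategies()[c(1, 3)]
  out <- reorder_sensitivity(ch, cfg,
                             permutations = list(c("sbp", "ht_med"),
                                                 c("ht_med", "sbp")),
                             strategies = strategies, seed = 18)
  expect_equal(nrow(out), 4L)
  expect_length(attr(out, "spread"), 2L)
  # identical permutations give identical estimates
  rep2 <- reorder_sensitivity(ch, cfg,
                              permutations = list(c("sbp", "ht_med"),
                                                  c("sbp", "ht_med")),
                              strategies = strategies, seed = 18)
  expect_equal(rep2$risk_pct[1:2], rep2$risk_pct[3:4])
  expect_error(set_covariate_order(cfg, c("sbp", "bmi")), "permutation")
})

test_that("saturated toy estimates are invariant to covariate order", {
  # with a single time-varying covariate there is only one ordering; the
  # pipeline must return identical results when asked for it repeatedly
  cfg <- toy_config(n_sim = 2000)
  ch <- make_toy_cohort(1500, seed = 334)
  out <- reorder_sensitivity(ch, cfg, permutations = list("a", "a"),
                             strategies = builtin_strategies()[1], seed = 19)
  expect_equal(out$risk_pct[1], out$risk_pct[2])
})
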