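# Shared fixtures, all generated in code.

# A two-interval DGP with a single binary time-varying covariate `a` and a
# fully attended visit process: small enough that the g-formula has a
# closed form by enumeration over the four covariate histories.
toy_dgp <- function(he_int = -2.2, he_a = 0.8, he_t = 0.4,
                    hd_int = -2.5, hd_a = 0.5) {
  covariates <- list(list(name = "visit", family = "visit"),
                     list(name = "a", family = "binary"))
  sampler <- function(n) data.frame(a = stats::rbinom(n, 1, 0.4))
  models <- list(
    visit = list(coef = c("(Intercept)" = 30)),
    a = list(coef = c("(Intercept)" = stats::qlogis(0.3), lag_a = 1.2))
  )
  gf_dgp(covariates, sampler, models,
         event_coefs = c("(Intercept)" = he_int, cur_a = he_a, tt = he_t),
         death_coefs = c("(Intercept)" = hd_int, cur_a = hd_a),
         ltfu_hazard = 0, K_max = 1L, visit_schedule = c(0L, 1L),
         baseline_fields = "person_id", baseline_terms = character(0),
         label = "toy")
}

# Saturated analysis configuration for the toy DGP: the hazard models carry
# a full interaction of the covariate with the interval indicator, and the
# covariate model conditions on its lag — every cell of the (a, k) table has
# its own parameter.
toy_config <- function(mode = "competing", n_sim = 1000L, seed = 1L) {
  analysis_config(
    outcome_name = "toy",
    covariates = list(covariate_spec("visit", "visit", terms = "tt"),
                      covariate_spec("a", "binary", terms = "lag_a")),
    baseline_terms = character(0),
    event_terms = c("cur_a", "tt", "cur_a:tt"),
    death_terms = c("cur_a", "tt", "cur_a:tt"),
    K_max = 1L, visit_schedule = c(0L, 1L),
    n_sim = n_sim, n_boot = 10L, mode = mode, seed = seed,
    baseline_fields = "person_id"
  )
}

# Closed-form g-formula risk for the toy setting by enumeration over the
# (a0, a1) histories, using the fitted models' probabilities. Independent of
# the Monte Carlo engine: plain sums and products.
enum_gformula_risk <- function(fits, p_a0_1, mode) {
  he <- function(a, k) {
    f <- if (mode == "composite") fits$composite else fits$event
    predict_probability(f, data.frame(cur_a = a, tt = k))
  }
  hd <- function(a, k) {
    if (mode != "competing") return(0)
    predict_probability(fits$death, data.frame(cur_a = a, tt = k))
  }
  p_a1 <- function(a0) predict_probability(fits$covariates$a,
                                           data.frame(lag_a = a0, tt = 1))
  risk <- 0
  for (a0 in 0:1) {
    w0 <- if (a0 == 1) p_a0_1 else 1 - p_a0_1
    esc0 <- (1 - he(a0, 0)) * (1 - hd(a0, 0))
    r0 <- he(a0, 0) * (1 - hd(a0, 0))
    for (a1 in 0:1) {
      w1 <- if (a1 == 1) p_a1(a0) else 1 - p_a1(a0)
      r1 <- he(a1, 1) * (1 - hd(a1, 1))
      risk <- risk + w0 * w1 * (r0 + esc0 * r1)
    }
  }
  risk
}

# A toy cohort generated once per test file that sources this helper.
make_toy_cohort <- function(n = 4000, seed = 301) {
  generate_cohort(toy_dgp(), n, seed = seed)
}

# Hand-built three-person cohort exercising the missed-visit censoring rule:
# scheduled visits at 0 and 2, window end 3, K_max = 4.
mini_censor_config <- function() {
  analysis_config(
    covariates = list(covariate_spec("visit", "visit", terms = "tt"),
                      covariate_spec("sbp", "continuous", terms = "lag_sbp")),
    baseline_terms = character(0), K_max = 4L, visit_schedule = c(0L, 2L),
    visit_window_end = 3L, n_sim = 10L, n_boot = 2L,
    baseline_fields = "person_id"
  )
}

mini_censor_cohort <- function() {
  iv <- rbind(
    # P1: attends both visits, reaches K_max
    data.frame(person_id = 1, k = 0:4, visit = c(1, 0, 1, 0, 0),
               sbp = c(130, 130, 135, 135, 135),
               event = 0, death = 0, censored = 0),
    # P2: misses the k = 2 visit, no event
    data.frame(person_id = 2, k = 0:4, visit = c(1, 0, 0, 0, 0),
               sbp = 120, event = 0, death = 0, censored = 0),
    # P3: event at k = 1, before the k = 2 visit
    data.frame(person_id = 3, k = 0:1, visit = c(1, 0), sbp = 150,
               event = c(0, 1), death = 0, censored = 0)
  )
  bl <- data.frame(person_id = 1:3)
  as_cohort(bl, iv, K_max = 4L)
}

# Independent brute-force cumulative incidence: recursive enumeration of the
# outcome tree, one branch per within-interval outcome (death first, then the
# event, then survival into the next interval).
brute_force_cif <- function(h_event, h_death, mode) {
  recurse <- function(k) {
    if (k > length(h_event)) return(0)
    he <- h_event[k]
    hd <- h_death[k]
    if (mode == "competing") {
      # branches: die (counts 0), survive death & have event, or survive both
      (1 - hd) * he + (1 - hd) * (1 - he) * recurse(k + 1)
    } else {
      # censor_death and composite: h_event is the (composite) hazard itself
      he + (1 - he) * recurse(k + 1)
    }
  }
  recurse(1)
}
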