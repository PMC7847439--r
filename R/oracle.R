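# Oracle counterfactual risks: direct Monte Carlo from the true DGP with the
# strategy substituted at every interval — the ground truth the parametric
# g-formula estimator is validated against.

#' Oracle counterfactual risk under a strategy
#'
#' Simulates covariate histories directly from the true DGP with the
#' strategy's assignments substituted into the state at each interval before
#' the hazards are evaluated, and with no loss to follow-up (incomplete
#' follow-up is an exit process, not part of the counterfactual estimand).
#' The visit process is retained: covariates update only at attended visits.
#' Per-interval risks are accumulated analytically from the true hazards
#' along each simulated history (no exit draws), so the only Monte Carlo
#' error comes from the covariate paths.
#'
#' @param dgp A [gf_dgp()].
#' @param strategy A [gf_strategy()].
#' @param mode Competing-event handling (`"competing"`, `"censor_death"`,
#'   `"composite"`).
#' @param n_mc Number of simulated histories (default 200000).
#' @param seed Integer seed.
#' @return A `gf_oracle` object: `risk_by_interval` (cumulative event risk at
#'   intervals `0..K_max`), `risk` (the final value), `risk_death_by_interval`
#'   (under `mode = "competing"`), `mc_se` (Monte Carlo standard error of
#'   `risk`), `n_mc`, `strategy_id`, `mode`.
#' @export
oracle_counterfactual_risk <- function(dgp, strategy,
                                       mode = c("competing", "censor_death",
                                                "composite"),
                                       n_mc = 200000L, seed = 1L) {
  mode <- match.arg(mode)
  with_seed(seed, {
    raw <- dgp$baseline_sampler(n_mc)
    raw$person_id <- seq_len(n_mc)
    bfields <- union("person_id", dgp$baseline_fields %||% names(raw))
    baseline <- raw[, intersect(bfields, names(raw)), drop = FALSE]
    tv_names <- setdiff(vapply(dgp$covariates, `[[`, "", "name"), "visit")
    cur <- lapply(raw[tv_names], identity)
    cur$visit <- rep(1, n_mc)
    ble <- expand_baseline(baseline)

    surv <- rep(1, n_mc)      # P(no exit before interval k), per history
    cum_e <- rep(0, n_mc)     # cumulative event risk, per history
    cum_d <- rep(0, n_mc)
    risk_by_k <- numeric(dgp$K_max + 1L)
    death_by_k <- numeric(dgp$K_max + 1L)

    for (k in 0:dgp$K_max) {
      if (k == 0L) {
        frame <- make_design_frame(ble, dgp$covariates, cur = cur,
                                   lag = NULL, k = 0)
      } else {
        st <- dgp_update_state(dgp, ble, cur, k)
        cur <- st$cur
        frame <- st$frame
      }
      if (!strategy$natural_course) {
        res <- apply_strategy(strategy, cur[tv_names], k)
        for (nm in tv_names) {
          if (!identical(res$state[[nm]], cur[[nm]])) {
            cur[[nm]] <- res$state[[nm]]
            exp_cols <- expand_tv(nm, covariate_family(dgp, nm), cur[[nm]], "cur_")
            for (cn in names(exp_cols)) frame[[cn]] <- exp_cols[[cn]]
          }
        }
      }
      he <- stats::plogis(lp_eval(dgp$event_coefs, frame))
      hd <- stats::plogis(lp_eval(dgp$death_coefs, frame))
      if (mode == "competing") {
        cum_e <- cum_e + surv * (1 - hd) * he
        cum_d <- cum_d + surv * hd
        surv <- surv * (1 - hd) * (1 - he)
      } else if (mode == "censor_death") {
        cum_e <- cum_e + surv * he
        surv <- surv * (1 - he)
      } else {
        hc <- 1 - (1 - hd) * (1 - he)
        cum_e <- cum_e + surv * hc
        surv <- surv * (1 - hc)
      }
      risk_by_k[k + 1L] <- mean(cum_e)
      death_by_k[k + 1L] <- mean(cum_d)
    }
    structure(list(
      strategy_id = strategy$id, mode = mode,
      risk_by_interval = risk_by_k,
      risk_death_by_interval = if (mode == "competing") death_by_k,
      risk = mean(cum_e),
      mc_se = stats::sd(cum_e) / sqrt(n_mc),
      n_mc = n_mc
    ), class = "gf_oracle")
  })
}

covariate_family <- function(dgp, name) {
  nms <- vapply(dgp$covariates, `[[`, "", "name")
  dgp$covariates[[match(name, nms)]]$family
}

#' @export
print.gf_oracle <- function(x, ...) {
  cat(sprintf("<gf_oracle> strategy %s | mode %s | risk %.4f (MC SE %.5f, n = %s)\n",
              x$strategy_id, x$mode, x$risk, x$mc_se,
              format(x$n_mc, big.mark = ",")))
  invisible(x)
}
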