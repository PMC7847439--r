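# The Monte Carlo g-formula engine (steps 3-5): baseline resampling,
# sequential simulation of covariate histories under a strategy, and
# cumulative incidence under the three competing-event modes.

#' Resample baseline records for the pseudo-population
#'
#' Draws `n_sim` baseline records (including the interval-0 values of the
#' time-varying covariates) with replacement from the cohort.
#'
#' @param cohort A `gf_cohort`.
#' @param n_sim Pseudo-population size.
#' @param seed Optional integer seed; if `NULL`, the ambient RNG is used.
#' @return A data.frame of `n_sim` rows.
#' @export
sample_baseline <- function(cohort, n_sim, seed = NULL) {
  b0 <- baseline0(cohort)
  if (nrow(b0) == 0L) stop_gf("cannot resample an empty cohort")
  draw <- function() b0[sample.int(nrow(b0), n_sim, replace = TRUE), ,
                        drop = FALSE]
  out <- if (is.null(seed)) draw() else with_seed(seed, draw())
  rownames(out) <- NULL
  out
}

# Vectorized sequential simulation of the pseudo-population under a strategy.
# Uses the ambient RNG (callers wrap in with_seed). Returns per-interval
# hazard matrices, intervened flags, and (optionally) covariate-mean
# diagnostics weighted by the analytic probability of still being at risk.
simulate_pseudo_population <- function(fits, config, draws, strategy,
                                       collect = FALSE) {
  covs <- config$covariates
  tv_names <- setdiff(vapply(covs, `[[`, "", "name"), "visit")
  n <- nrow(draws)
  K <- config$K_max
  blf <- intersect(config$baseline_fields, names(draws))
  ble <- expand_baseline(draws[, blf, drop = FALSE])
  has_visit <- any(vapply(covs, function(x) x$family == "visit", TRUE))

  cur <- lapply(draws[tv_names], identity)
  he <- matrix(0, n, K + 1L)
  hd <- matrix(0, n, K + 1L)
  intervened <- matrix(FALSE, n, K + 1L)
  diag_rows <- if (collect) vector("list", K + 1L)
  range_rows <- if (collect) vector("list", K + 1L)
  surv <- rep(1, n)

  for (k in 0:K) {
    if (k == 0L) {
      visit <- rep(1, n)
      cur$visit <- visit
      frame <- make_design_frame(ble, covs, cur = cur, lag = NULL, k = 0)
    } else {
      lag <- cur
      frame <- make_design_frame(ble, covs, cur = lag, lag = lag, k = k)
      if (has_visit && k %in% config$visit_schedule) {
        vfit <- fits$covariates$visit
        p <- if (vfit$degenerate) rep(as.numeric(vfit$constant), n) else
          stats::plogis(fit_linpred(vfit, frame))
        visit <- as.numeric(stats::runif(n) < p)
      } else {
        visit <- numeric(n)
      }
      cur$visit <- visit
      frame$cur_visit <- visit
      att <- visit == 1
      if (any(att)) {
        for (cv in covs) {
          if (cv$family == "visit") next
          cur[[cv$name]] <- draw_covariate(fits$covariates[[cv$name]],
                                           cv$family, frame, att,
                                           lag[[cv$name]])
          newcols <- expand_tv(cv$name, cv$family, cur[[cv$name]], "cur_")
          for (cn in names(newcols)) frame[[cn]] <- newcols[[cn]]
        }
      }
    }
    if (!strategy$natural_course) {
      res <- apply_strategy(strategy, cur[tv_names], k)
      intervened[, k + 1L] <- res$intervened
      for (nm in tv_names) {
        if (!identical(res$state[[nm]], cur[[nm]])) {
          cur[[nm]] <- res$state[[nm]]
          fam <- covs[[match(nm, vapply(covs, `[[`, "", "name"))]]$family
          newcols <- expand_tv(nm, fam, cur[[nm]], "cur_")
          for (cn in names(newcols)) frame[[cn]] <- newcols[[cn]]
        }
      }
    }
    if (config$mode == "composite") {
      he[, k + 1L] <- predict_probability(fits$composite, frame)
    } else {
      he[, k + 1L] <- predict_probability(fits$event, frame)
      if (config$mode == "competing") {
        hd[, k + 1L] <- predict_probability(fits$death, frame)
      }
    }
    if (anyNA(he[, k + 1L]) || anyNA(hd[, k + 1L])) {
      stop_gf("strategy '%s', interval %d: hazard evaluated to NA", strategy$label, k)
    }
    if (collect) {
      w <- surv
      vis1 <- cur$visit == 1
      vals <- list()
      rng <- list()
      for (cv in covs) {
        if (cv$family == "visit") next
        cols <- expand_tv(cv$name, cv$family, cur[[cv$name]], "")
        for (cn in names(cols)) {
          wv <- w * vis1
          vals[[cn]] <- if (sum(wv) > 0) sum(wv * cols[[cn]]) / sum(wv) else NA_real_
          rng[[cn]] <- range(cols[[cn]])
        }
      }
      vals$visit <- if (sum(w) > 0) sum(w * cur$visit) / sum(w) else NA_real_
      diag_rows[[k + 1L]] <- unlist(vals)
      range_rows[[k + 1L]] <- rng
    }
    surv <- surv * (1 - he[, k + 1L]) * (1 - hd[, k + 1L])
  }
  list(h_event = he, h_death = hd, intervened = intervened,
       diag = if (collect) do.call(rbind, diag_rows),
       state_range = if (collect) range_rows)
}

#' Simulate a single covariate history
#'
#' Convenience wrapper around the vectorized engine for one baseline record:
#' per interval, the visit indicator is drawn; attendees' covariates are
#' drawn in the configured order (each conditional on already-drawn current
#' values and on history) and carried forward otherwise; the strategy is
#' applied; and the event and death hazards are evaluated from the intervened
#' state. Risks are computed analytically from the stored hazards — no exit
#' is drawn.
#'
#' @param baseline A one-row data.frame as returned by [sample_baseline()].
#' @param fits A `gf_fits` from [fit_gformula_models()].
#' @param strategy A [gf_strategy()].
#' @param config An [analysis_config()].
#' @param seed Optional seed.
#' @return List with `h_event`, `h_death` (vectors over intervals `0..K_max`)
#'   and `intervened` (logical vector).
#' @export
simulate_history <- function(baseline, fits, strategy, config, seed = NULL) {
  run <- function() simulate_pseudo_population(fits, config, baseline, strategy)
  sim <- if (is.null(seed)) run() else with_seed(seed, run())
  list(h_event = drop(sim$h_event), h_death = drop(sim$h_death),
       intervened = drop(sim$intervened))
}

#' Cumulative incidence from discrete-time hazards
#'
#' Converts per-interval hazards into cumulative risks. Under
#' `mode = "competing"`, death acts first within an interval:
#' `risk(K) = sum_k h_e(k) (1 - h_d(k)) prod_{s<k} (1 - h_e(s))(1 - h_d(s))`,
#' and the death risk accumulates `h_d(k)` against the same survival.
#' Under `mode = "censor_death"`, `risk(K) = 1 - prod(1 - h_e)`; under
#' `mode = "composite"` the event hazard is taken as the composite hazard and
#' the same product-limit form applies.
#'
#' @param h_event Event (or composite) hazards: vector over intervals, or a
#'   matrix with one row per individual.
#' @param h_death Death hazards (same shape); ignored unless
#'   `mode = "competing"`.
#' @param mode Competing-event handling.
#' @return For vector input, a list with `risk_event` and `risk_death`
#'   cumulative vectors; for matrix input, additionally `per_person_risk`
#'   (final event risk per individual) with the curve entries averaged over
#'   individuals.
#' @export
cumulative_incidence <- function(h_event, h_death = NULL,
                                 mode = c("competing", "censor_death",
                                          "composite")) {
  mode <- match.arg(mode)
  vec <- !is.matrix(h_event)
  he <- if (vec) matrix(h_event, nrow = 1) else h_event
  if (any(he < 0 | he > 1)) stop_gf("event hazards must lie in [0, 1]")
  hd <- if (mode == "competing") {
    if (is.null(h_death)) stop_gf("mode 'competing' requires death hazards")
    m <- if (vec) matrix(h_death, nrow = 1) else h_death
    if (any(m < 0 | m > 1)) stop_gf("death hazards must lie in [0, 1]")
    m
  } else {
    matrix(0, nrow(he), ncol(he))
  }
  K <- ncol(he)
  n <- nrow(he)
  surv <- rep(1, n)
  cum_e <- rep(0, n)
  cum_d <- rep(0, n)
  curve_e <- numeric(K)
  curve_d <- numeric(K)
  for (k in seq_len(K)) {
    if (mode == "competing") {
      cum_e <- cum_e + surv * (1 - hd[, k]) * he[, k]
      cum_d <- cum_d + surv * hd[, k]
      surv <- surv * (1 - hd[, k]) * (1 - he[, k])
    } else {
      cum_e <- cum_e + surv * he[, k]
      surv <- surv * (1 - he[, k])
    }
    curve_e[k] <- mean(cum_e)
    curve_d[k] <- mean(cum_d)
  }
  out <- list(risk_event = curve_e, risk_death = curve_d)
  if (!vec) {
    out$per_person_risk <- cum_e
    out$per_person_death <- cum_d
  }
  out
}

#' Run the parametric g-formula for one strategy
#'
#' Orchestrates the full estimator: model fitting (unless prefitted models
#' are supplied), baseline resampling, sequential Monte Carlo simulation of
#' `n_sim` histories under the strategy, and analytic cumulative incidence
#' under the configured competing-event mode. Deterministic given `seed`.
#'
#' @param cohort A validated, eligibility-filtered `gf_cohort`.
#' @param config An [analysis_config()].
#' @param strategy A [gf_strategy()] (default: natural course).
#' @param fits Optional prefitted `gf_fits` (fit once, evaluate many
#'   strategies).
#' @param seed Seed for this run (default `config$seed`); using the same seed
#'   across strategies yields common random numbers for their contrasts.
#' @param n_sim Pseudo-population size (default `config$n_sim`).
#' @param collect_diagnostics Record simulated covariate means per interval.
#' @return A `gf_risk` object: `risk` (cumulative event risk at `K_max`),
#'   `risk_by_interval`, `risk_death_by_interval`, `per_person_risk`,
#'   `mc_se`, `pct_intervened` (cumulative, per interval), `total_intervened`,
#'   `intervened` flags, and the diagnostics trace when requested.
#' @export
run_gformula <- function(cohort, config, strategy = builtin_strategies()[[1]],
                         fits = NULL, seed = config$seed,
                         n_sim = config$n_sim, collect_diagnostics = FALSE) {
  fits <- fits %||% fit_gformula_models(cohort, config)
  sim <- with_seed(seed, {
    draws <- sample_baseline(cohort, n_sim)
    simulate_pseudo_population(fits, config, draws, strategy,
                               collect = collect_diagnostics)
  })
  ci <- cumulative_incidence(sim$h_event, sim$h_death, mode = config$mode)
  pct <- percent_intervened(sim$intervened)
  structure(list(
    strategy_id = strategy$id, label = strategy$label, mode = config$mode,
    risk = ci$risk_event[length(ci$risk_event)],
    risk_by_interval = ci$risk_event,
    risk_death_by_interval = if (config$mode == "competing") ci$risk_death,
    per_person_risk = ci$per_person_risk,
    mc_se = stats::sd(ci$per_person_risk) / sqrt(n_sim),
    pct_intervened = pct,
    total_intervened = pct[length(pct)],
    intervened = sim$intervened,
    diag = sim$diag,
    state_range = sim$state_range,
    n_sim = n_sim, seed = seed
  ), class = "gf_risk")
}

#' @export
print.gf_risk <- function(x, ...) {
  cat(sprintf("<gf_risk> strategy %s: %s\n", x$strategy_id, x$label))
  cat(sprintf("  mode %s | risk at K: %.4f (MC SE %.5f) | total intervened %.1f%% | n_sim %d\n",
              x$mode, x$risk, x$mc_se, x$total_intervened, x$n_sim))
  invisible(x)
}

#' Risk ratio and risk difference versus the natural course
#'
#' @param risk_strategy,risk_nc Risks on the probability scale (0-1).
#' @return List with `rr` (risk ratio) and `rd` (risk difference in
#'   percentage points, `(risk_strategy - risk_nc) * 100`).
#' @export
contrast <- function(risk_strategy, risk_nc) {
  if (any(risk_nc == 0)) stop_gf("risk ratio undefined: natural-course risk is 0")
  list(rr = risk_strategy / risk_nc, rd = (risk_strategy - risk_nc) * 100)
}

#' Run the g-formula for a set of strategies
#'
#' Fits all models once, then evaluates each strategy on its own
#' pseudo-population generated with a common seed (common random numbers, so
#' contrasts are not inflated by independent Monte Carlo noise). The first
#' natural-course strategy in the list is the comparator for RR/RD.
#'
#' @inheritParams run_gformula
#' @param strategies List of [gf_strategy()] (default from config).
#' @return A `gf_result`: `risks` (list of `gf_risk`), `effects` (a
#'   Table-2-shaped data.frame: absolute risk in percent, RR, RD in
#'   percentage points, total intervened percent), and `fits`.
#' @export
run_strategies <- function(cohort, config, strategies = config$strategies,
                           fits = NULL, seed = config$seed,
                           n_sim = config$n_sim) {
  fits <- fits %||% fit_gformula_models(cohort, config)
  risks <- lapply(strategies, function(s) {
    run_gformula(cohort, config, s, fits = fits, seed = seed, n_sim = n_sim)
  })
  nc_idx <- which(vapply(strategies, `[[`, TRUE, "natural_course"))[1]
  effects <- effects_table(risks, nc_idx)
  structure(list(risks = risks, effects = effects, fits = fits,
                 mode = config$mode, seed = seed),
            class = "gf_result")
}

effects_table <- function(risks, nc_idx) {
  nc_risk <- if (!is.na(nc_idx)) risks[[nc_idx]]$risk else NA_real_
  rows <- lapply(seq_along(risks), function(i) {
    r <- risks[[i]]
    is_nc <- !is.na(nc_idx) && i == nc_idx
    ct <- if (!is_nc && !is.na(nc_risk)) contrast(r$risk, nc_risk) else
      list(rr = NA_real_, rd = NA_real_)
    data.frame(strategy_id = r$strategy_id, label = r$label,
               risk_pct = 100 * r$risk,
               rr = ct$rr, rd = ct$rd,
               total_intervened_pct = if (is_nc) 0 else r$total_intervened)
  })
  do.call(rbind, rows)
}

#' @export
print.gf_result <- function(x, ...) {
  cat(sprintf("<gf_result> %d strategies, mode = %s\n", length(x$risks), x$mode))
  df <- x$effects
  df$risk_pct <- sprintf("%.1f", df$risk_pct)
  df$rr <- ifelse(is.na(df$rr), "-", sprintf("%.2f", df$rr))
  df$rd <- ifelse(is.na(df$rd), "-", sprintf("%+.1f", df$rd))
  df$total_intervened_pct <- sprintf("%.1f", df$total_intervened_pct)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write risk curves to CSV
#'
#' Long-format export of the standardized cumulative incidence curves
#' (strategy, interval, event risk, death risk, cumulative percent
#' intervened).
#'
#' @param result A `gf_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_risk_curves <- function(result, path) {
  rows <- lapply(result$risks, function(r) {
    data.frame(strategy_id = r$strategy_id, label = r$label,
               k = seq_along(r$risk_by_interval) - 1L,
               risk_event = r$risk_by_interval,
               risk_death = r$risk_death_by_interval %||%
                 rep(NA_real_, length(r$risk_by_interval)),
               cum_pct_intervened = r$pct_intervened)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
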