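# Inference and reporting: person-level bootstrap confidence intervals,
# natural-course calibration diagnostics, covariate-reordering sensitivity
# analyses, and subgroup analyses (g-formula steps 5-6 plus the sensitivity
# apparatus).

# Resample persons with replacement, reindexing person_id so duplicated
# persons remain distinct.
resample_cohort <- function(cohort, ids = NULL) {
  bl <- cohort$baseline
  iv <- cohort$intervals
  if (is.null(ids)) {
    ids <- bl$person_id[sample.int(nrow(bl), nrow(bl), replace = TRUE)]
  }
  rows_by_person <- split(seq_len(nrow(iv)), iv$person_id)
  picked <- rows_by_person[as.character(ids)]
  idx <- unlist(picked, use.names = FALSE)
  new_iv <- iv[idx, , drop = FALSE]
  new_iv$person_id <- rep(seq_along(ids), lengths(picked))
  new_bl <- bl[match(ids, bl$person_id), , drop = FALSE]
  new_bl$person_id <- seq_along(ids)
  as_cohort(new_bl, new_iv, K_max = cohort$K_max, validate = FALSE)
}

#' Bootstrap confidence intervals for all strategy effects
#'
#' Point estimates come from the original sample; confidence intervals are
#' percentile bootstrap (2.5/97.5 empirical quantiles, inverse-ECDF
#' convention, so with `B = 2` the bounds are the min and max of the two
#' replicates). The resampling unit is the person with all their intervals.
#' Each replicate refits every model and reruns every strategy; replicate
#' seeds are derived deterministically from `seed` and the replicate index,
#' so results do not depend on execution order. Replicates whose model
#' fitting fails (e.g. no events after resampling) are flagged, excluded,
#' and counted.
#'
#' @param cohort A `gf_cohort` (eligibility-filtered).
#' @param config An [analysis_config()].
#' @param strategies Strategies to evaluate (default from config; must
#'   include a natural-course strategy).
#' @param B Number of bootstrap replicates (default `config$n_boot`).
#' @param seed Master seed (default `config$seed`).
#' @param n_sim_boot Pseudo-population size per replicate (default
#'   `config$n_sim`).
#' @return A `gf_effects` data.frame: per strategy, absolute risk (percent)
#'   with CI, RR with CI, RD (percentage points) with CI, total intervened
#'   percent. Attributes: `B`, `n_failed`, `replicates` (the replicate risk
#'   matrix).
#' @export
bootstrap_cis <- function(cohort, config, strategies = config$strategies,
                          B = config$n_boot, seed = config$seed,
                          n_sim_boot = config$n_sim) {
  if (B < 2L) stop_gf("bootstrap requires B >= 2")
  point <- run_strategies(cohort, config, strategies, seed = seed)
  seeds <- matrix(derive_seeds(seed, 2L * B), nrow = 2L)
  n_strat <- length(strategies)
  risks <- matrix(NA_real_, B, n_strat)
  failed <- logical(B)
  for (b in seq_len(B)) {
    res <- tryCatch({
      boot <- with_seed(seeds[1L, b], resample_cohort(cohort))
      run_strategies(boot, config, strategies, seed = seeds[2L, b],
                     n_sim = n_sim_boot)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[b] <- TRUE
    } else {
      risks[b, ] <- vapply(res$risks, `[[`, 0, "risk")
    }
  }
  ok <- !failed
  nc_idx <- which(vapply(strategies, `[[`, TRUE, "natural_course"))[1]
  eff <- point$effects
  eff$risk_lo <- eff$risk_hi <- eff$rr_lo <- eff$rr_hi <-
    eff$rd_lo <- eff$rd_hi <- NA_real_
  for (i in seq_len(n_strat)) {
    ci <- pct_ci(100 * risks[ok, i])
    eff$risk_lo[i] <- ci[1]
    eff$risk_hi[i] <- ci[2]
    if (i != nc_idx) {
      rr_b <- risks[ok, i] / risks[ok, nc_idx]
      rd_b <- 100 * (risks[ok, i] - risks[ok, nc_idx])
      ci_rr <- pct_ci(rr_b)
      ci_rd <- pct_ci(rd_b)
      eff$rr_lo[i] <- ci_rr[1]
      eff$rr_hi[i] <- ci_rr[2]
      eff$rd_lo[i] <- ci_rd[1]
      eff$rd_hi[i] <- ci_rd[2]
    }
  }
  eff <- eff[, c("strategy_id", "label", "risk_pct", "risk_lo", "risk_hi",
                 "rr", "rr_lo", "rr_hi", "rd", "rd_lo", "rd_hi",
                 "total_intervened_pct")]
  attr(eff, "B") <- B
  attr(eff, "n_failed") <- sum(failed)
  attr(eff, "replicates") <- risks
  class(eff) <- c("gf_effects", "data.frame")
  eff
}

#' @export
print.gf_effects <- function(x, ...) {
  cat(sprintf("<gf_effects> B = %s bootstrap replicates (%s failed)\n",
              attr(x, "B") %||% "?", attr(x, "n_failed") %||% 0))
  df <- as.data.frame(x)
  fmt <- function(v, d = 1) ifelse(is.na(v), "-", sprintf(paste0("%.", d, "f"), v))
  out <- data.frame(
    id = df$strategy_id, strategy = df$label,
    `risk (95% CI)` = sprintf("%s (%s, %s)", fmt(df$risk_pct),
                              fmt(df$risk_lo), fmt(df$risk_hi)),
    `RR (95% CI)` = ifelse(is.na(df$rr), "-",
                           sprintf("%s (%s, %s)", fmt(df$rr, 2),
                                   fmt(df$rr_lo, 2), fmt(df$rr_hi, 2))),
    `RD (95% CI)` = ifelse(is.na(df$rd), "-",
                           sprintf("%s (%s, %s)", fmt(df$rd), fmt(df$rd_lo),
                                   fmt(df$rd_hi))),
    `intervened %` = fmt(df$total_intervened_pct),
    check.names = FALSE)
  print(out, row.names = FALSE)
  invisible(x)
}

#' Natural-course calibration diagnostics
#'
#' The standard g-formula model check: compare, per time-varying covariate
#' and interval, the observed mean (among at-risk records with an attended
#' visit) against the mean simulated under the natural course (weighted by
#' each pseudo-individual's analytic probability of still being at risk,
#' restricted to simulated visit attendees), plus the observed nonparametric
#' cumulative incidence against the simulated natural-course risk.
#'
#' @param cohort A `gf_cohort`.
#' @param config An [analysis_config()].
#' @param fits Optional prefitted `gf_fits`.
#' @param seed,n_sim Simulation controls (defaults from config).
#' @param min_n Minimum observed records per covariate-interval cell.
#' @return A `gf_diagnostics` object: `table` (covariate, interval, observed
#'   and predicted means, difference, standardized difference),
#'   `max_abs_std_diff`, `obs_risk`, `sim_risk`, and model convergence flags.
#' @export
natural_course_diagnostics <- function(cohort, config, fits = NULL,
                                       seed = config$seed,
                                       n_sim = config$n_sim, min_n = 20L) {
  fits <- fits %||% fit_gformula_models(cohort, config)
  nc <- builtin_strategies()[[1]]
  run <- run_gformula(cohort, config, nc, fits = fits, seed = seed,
                      n_sim = n_sim, collect_diagnostics = TRUE)
  frame <- build_model_frame(cohort, config)
  sched1 <- config$visit_schedule[config$visit_schedule > 0L]
  rows <- list()
  for (cv in config$covariates) {
    nm <- cv$name
    for (k in sched1) {
      if (nm == "visit") {
        sub <- frame[frame$k == k, , drop = FALSE]
        cols <- list(visit = sub$visit)
      } else {
        sub <- frame[frame$k == k & frame$visit == 1, , drop = FALSE]
        cols <- expand_tv(nm, cv$family, sub[[paste0(".raw_", nm)]], "")
      }
      for (cn in names(cols)) {
        v <- cols[[cn]][!is.na(cols[[cn]])]
        if (length(v) < min_n) next
        obs_mean <- mean(v)
        obs_sd <- stats::sd(v)
        pred <- run$diag[k + 1L, cn]
        rows[[length(rows) + 1L]] <- data.frame(
          covariate = cn, k = k, n_obs = length(v),
          obs_mean = obs_mean, pred_mean = pred,
          diff = pred - obs_mean,
          std_diff = if (isTRUE(obs_sd > 0)) (pred - obs_mean) / obs_sd
                     else NA_real_)
      }
    }
  }
  tab <- do.call(rbind, rows)
  conv <- list()
  for (nm in names(fits$covariates)) {
    f <- fits$covariates[[nm]]
    conv[[nm]] <- if (inherits(f, "gf_fit")) f$converged else
      all(vapply(f, `[[`, TRUE, "converged"))
  }
  obs <- observed_risk(cohort, mode = config$mode)
  structure(list(table = tab,
                 max_abs_std_diff = max(abs(tab$std_diff), na.rm = TRUE),
                 obs_risk = obs$risk, sim_risk = run$risk,
                 converged = unlist(conv)),
            class = "gf_diagnostics")
}

#' @export
print.gf_diagnostics <- function(x, ...) {
  cat(sprintf("<gf_diagnostics> observed risk %.4f vs simulated natural course %.4f\n",
              x$obs_risk, x$sim_risk))
  cat(sprintf("  max |standardized obs-vs-predicted difference| = %.3f over %d covariate-interval cells\n",
              x$max_abs_std_diff, nrow(x$table)))
  if (!all(x$converged)) {
    cat("  non-converged models:",
        paste(names(x$converged)[!x$converged], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Covariate-reordering sensitivity analysis
#'
#' Reruns the full pipeline under permutations of the time-varying covariate
#' simulation order (the visit process always first), a standard probe for
#' model misspecification: estimates that move materially under reordering
#' indicate order-dependent misfit.
#'
#' @param cohort A `gf_cohort`.
#' @param config An [analysis_config()].
#' @param permutations List of character vectors, each a permutation of the
#'   non-visit covariate names; invalid permutations error.
#' @param strategies Strategies to evaluate (default from config).
#' @param seed Seed shared across orderings.
#' @return A data.frame of effects per ordering, with an `ordering` column,
#'   plus attribute `spread` (per-strategy SD of the risk across orderings).
#' @export
reorder_sensitivity <- function(cohort, config, permutations,
                                strategies = config$strategies,
                                seed = config$seed) {
  out <- list()
  for (i in seq_along(permutations)) {
    cfg <- set_covariate_order(config, permutations[[i]])
    res <- run_strategies(cohort, cfg, strategies, seed = seed)
    eff <- res$effects
    eff$ordering <- paste(permutations[[i]], collapse = ">")
    out[[i]] <- eff
  }
  df <- do.call(rbind, out)
  spread <- tapply(df$risk_pct, df$strategy_id, stats::sd)
  attr(df, "spread") <- spread
  df
}

#' The six built-in subgroup definitions
#'
#' Age 55-65, age 66-80, women, men, no antihypertensive medication at
#' baseline, and free of heart disease at baseline. Predicates evaluate on
#' the baseline table joined with the interval-0 covariate values.
#'
#' @return Named list of `list(name, predicate)` entries.
#' @export
builtin_subgroups <- function() {
  list(
    age_55_65 = list(name = "Age 55-65",
                     predicate = function(b0) b0$age <= 65),
    age_66_80 = list(name = "Age 66-80",
                     predicate = function(b0) b0$age > 65),
    women = list(name = "Women", predicate = function(b0) b0$sex == 1),
    men = list(name = "Men", predicate = function(b0) b0$sex == 0),
    no_htmed = list(name = "Without hypertensive medication at baseline",
                    predicate = function(b0) b0$ht_med == 0),
    no_hd = list(name = "Free of heart disease at baseline",
                 predicate = function(b0) b0$heart_disease0 == 0)
  )
}

#' Subgroup analyses
#'
#' Restricts the (eligibility-filtered) cohort to each subgroup, refits all
#' models within the subgroup, and reruns the configured strategies —
#' subgroup-specific natural-course risks and contrasts, as in per-subgroup
#' reporting of the main analysis.
#'
#' @param cohort A `gf_cohort`.
#' @param config An [analysis_config()].
#' @param subgroups List as returned by [builtin_subgroups()].
#' @param strategies Strategies to evaluate (default from config).
#' @param seed Seed shared across subgroups.
#' @return A data.frame of effects with `subgroup` and `n_subgroup` columns.
#' @export
subgroup_analysis <- function(cohort, config, subgroups = builtin_subgroups(),
                              strategies = config$strategies,
                              seed = config$seed) {
  b0 <- baseline0(cohort)
  out <- list()
  for (sg in subgroups) {
    keep <- sg$predicate(b0)
    if (is.null(keep) || length(keep) != nrow(b0)) {
      stop_gf("subgroup '%s': predicate could not be evaluated on this cohort (missing baseline field?)",
              sg$name)
    }
    keep[is.na(keep)] <- FALSE
    ids <- b0$person_id[keep]
    if (length(ids) == 0L) stop_gf("subgroup '%s' is empty", sg$name)
    sub <- as_cohort(
      cohort$baseline[cohort$baseline$person_id %in% ids, , drop = FALSE],
      cohort$intervals[cohort$intervals$person_id %in% ids, , drop = FALSE],
      K_max = cohort$K_max, validate = FALSE)
    res <- run_strategies(sub, config, strategies, seed = seed)
    eff <- res$effects
    eff$subgroup <- sg$name
    eff$n_subgroup <- length(ids)
    out[[length(out) + 1L]] <- eff
  }
  do.call(rbind, out)
}
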