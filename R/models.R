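# Fitting the sequence of parametric covariate models and the pooled logistic
# event/death models (g-formula steps 1-2), and evaluating fitted models on
# new design frames.

# One long design frame over all person-intervals, with responses attached.
# Raw current values are stored as `.raw_<name>` and raw lag-1 values as
# `.rawlag_<name>`; `lag_`/`cur_` design columns follow the build_design
# naming so the same term vocabulary serves fitting and simulation.
build_model_frame <- function(cohort, config) {
  iv <- cohort$intervals
  bl <- cohort$baseline[match(iv$person_id, cohort$baseline$person_id), ,
                        drop = FALSE]
  blf <- intersect(config$baseline_fields, names(bl))
  ble <- expand_baseline(bl[, blf, drop = FALSE])
  covs <- config$covariates
  first <- !duplicated(iv$person_id)
  raw_of <- function(nm) if (nm == "visit") iv$visit else iv[[nm]]
  cur <- list()
  lag <- list()
  for (cv in covs) {
    v <- raw_of(cv$name)
    if (is.null(v)) stop_gf("interval table lacks covariate column '%s'", cv$name)
    lv <- c(if (length(v)) v[1], v[-length(v)])
    lv[first] <- NA
    cur[[cv$name]] <- v
    lag[[cv$name]] <- lv
  }
  frame <- make_design_frame(ble, covs, cur = cur, lag = lag, k = iv$k)
  frame$person_id <- iv$person_id
  frame$k <- iv$k
  frame$visit <- iv$visit
  frame$event <- iv$event
  frame$death <- iv$death
  frame$censored <- iv$censored
  for (cv in covs) {
    frame[[paste0(".raw_", cv$name)]] <- cur[[cv$name]]
    frame[[paste0(".rawlag_", cv$name)]] <- lag[[cv$name]]
  }
  frame
}

# Fit one regression model (binomial or gaussian) over a subset of the model
# frame, handling degenerate responses and rank deficiency (aliased
# coefficients are zeroed; prediction then ignores those columns).
fit_one_model <- function(y, terms, data, family, name, bounds = NULL) {
  ok <- !is.na(y)
  y <- y[ok]
  data <- data[ok, , drop = FALSE]
  n <- length(y)
  if (n == 0L) stop_gf("model '%s': empty fitting set", name)
  degenerate <- length(unique(y)) < 2L
  if (degenerate) {
    return(structure(list(name = name, family = family, degenerate = TRUE,
                          constant = y[1], coef = NULL, terms_obj = NULL,
                          sigma = 0, bounds = bounds, n = n,
                          converged = TRUE),
                     class = "gf_fit"))
  }
  df <- data
  df$.y <- y
  f <- if (length(terms)) stats::reformulate(terms, ".y") else .y ~ 1
  fit <- suppressWarnings(stats::glm(f, data = df, family = family))
  beta <- stats::coef(fit)
  aliased <- is.na(beta)
  beta[aliased] <- 0
  se <- rep(NA_real_, length(beta))
  names(se) <- names(beta)
  sm <- suppressWarnings(summary(fit))
  se[rownames(sm$coefficients)] <- sm$coefficients[, "Std. Error"]
  sigma <- if (identical(family, "gaussian")) {
    sqrt(sum(stats::residuals(fit)^2) / max(fit$df.residual, 1L))
  } else 0
  structure(list(name = name, family = family, degenerate = FALSE,
                 constant = NULL, coef = beta, se = se,
                 terms_obj = stats::delete.response(stats::terms(fit)),
                 sigma = sigma, bounds = bounds, n = n,
                 aliased = names(beta)[aliased],
                 converged = isTRUE(fit$converged) || identical(family, "gaussian")),
            class = "gf_fit")
}

#' @export
print.gf_fit <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<gf_fit> %s (%s): degenerate, constant = %s (n = %d)\n",
                x$name, x$family, format(x$constant), x$n))
  } else {
    cat(sprintf("<gf_fit> %s (%s): %d coefficients, n = %d%s\n",
                x$name, x$family, length(x$coef), x$n,
                if (x$converged) "" else " [NOT CONVERGED]"))
  }
  invisible(x)
}

fit_design_matrix <- function(fit, frame) {
  stats::model.matrix(fit$terms_obj, frame)
}

fit_linpred <- function(fit, frame) {
  X <- fit_design_matrix(fit, frame)
  unname(drop(X %*% fit$coef))
}

#' Evaluate a fitted binary model as a probability
#'
#' Inverse-logit evaluation of a fitted model's linear predictor on a design:
#' either a data.frame carrying the design columns the fit's terms reference,
#' or a numeric matrix conformable with the coefficient vector.
#'
#' @param fit A `gf_fit` from [fit_covariate_models()] or
#'   [fit_event_models()].
#' @param design data.frame of design columns or numeric matrix.
#' @return Numeric vector of probabilities in (0, 1) (degenerate fits return
#'   their constant).
#' @export
predict_probability <- function(fit, design) {
  if (!inherits(fit, "gf_fit")) stop_gf("`fit` must be a gf_fit")
  n <- if (is.matrix(design)) nrow(design) else nrow(as.data.frame(design))
  if (fit$degenerate) return(rep(as.numeric(fit$constant), n))
  if (identical(fit$family, "gaussian")) {
    stop_gf("model '%s' is continuous; probabilities are undefined", fit$name)
  }
  lp <- if (is.matrix(design)) {
    if (ncol(design) != length(fit$coef)) {
      stop_gf("design has %d columns but fit '%s' has %d coefficients",
              ncol(design), fit$name, length(fit$coef))
    }
    unname(drop(design %*% fit$coef))
  } else {
    fit_linpred(fit, as.data.frame(design, optional = TRUE))
  }
  stats::plogis(lp)
}

# Draw one covariate's new values for attendee rows of a simulation frame.
draw_covariate <- function(fitrec, family, frame, att, lagval) {
  n <- nrow(frame)
  if (family == "continuous") {
    fit <- fitrec
    if (fit$degenerate) return(ifelse(att, fit$constant, lagval))
    mu <- fit_linpred(fit, frame)
    new <- mu + stats::rnorm(n, sd = fit$sigma)
    if (!is.null(fit$bounds)) new <- clamp(new, fit$bounds[1], fit$bounds[2])
    ifelse(att, new, lagval)
  } else if (family %in% c("binary", "absorbing")) {
    fit <- fitrec
    p <- if (fit$degenerate) rep(as.numeric(fit$constant), n) else
      stats::plogis(fit_linpred(fit, frame))
    new <- as.numeric(stats::runif(n) < p)
    if (family == "absorbing") {
      v <- lagval
      upd <- att & v == 0
      v[upd] <- new[upd]
      v
    } else {
      ifelse(att, new, lagval)
    }
  } else if (family == "smoking") {
    v <- lagval
    u <- stats::runif(n)
    pr <- function(f) if (f$degenerate) rep(as.numeric(f$constant), n) else
      stats::plogis(fit_linpred(f, frame))
    new <- v
    i <- att & v == "never" & u < pr(fitrec$start)
    new[i] <- "current"
    i <- att & v == "former" & u < pr(fitrec$relapse)
    new[i] <- "current"
    i <- att & v == "current" & u < pr(fitrec$quit)
    new[i] <- "former"
    new
  } else {
    stop_gf("unknown covariate family '%s'", family)
  }
}

#' Fit the sequential time-varying covariate models
#'
#' Fits, in the configured simulation order, one parametric model per
#' time-varying covariate among person-intervals still under follow-up:
#' the visit-attendance model on scheduled post-baseline visit intervals, and
#' every other covariate conditionally on having attended the visit
#' (`visit = 1` records only). Absorbing indicators are modeled only among
#' persons with lagged value 0; a three-level smoking covariate is modeled as
#' origin-stratified logits respecting the structural zeros (no initiation
#' of "former", no return to "never"); continuous covariates are linear
#' models whose residual SD and observed range (used to truncate simulated
#' draws) are stored. Covariates constant in the fitting data are flagged
#' degenerate and carried as constants during simulation.
#'
#' @param cohort A validated `gf_cohort`.
#' @param config An [analysis_config()].
#' @param frame Optional precomputed model frame (internal reuse).
#' @return Named list of `gf_fit` objects (smoking: a list with elements
#'   `start`, `relapse`, `quit`), in simulation order.
#' @export
fit_covariate_models <- function(cohort, config, frame = NULL) {
  frame <- frame %||% build_model_frame(cohort, config)
  sched1 <- config$visit_schedule[config$visit_schedule > 0L]
  fits <- list()
  for (cv in config$covariates) {
    nm <- cv$name
    if (cv$family == "visit") {
      sub <- frame[frame$k %in% sched1, , drop = FALSE]
      if (nrow(sub) == 0L) {
        fits[[nm]] <- structure(list(name = nm, family = "binary",
                                     degenerate = TRUE, constant = 1,
                                     sigma = 0, n = 0L, converged = TRUE),
                                class = "gf_fit")
        next
      }
      fits[[nm]] <- fit_one_model(sub$visit, cv$terms, sub, "binomial", nm)
    } else if (cv$family == "smoking") {
      sub <- frame[frame$k > 0L & frame$visit == 1, , drop = FALSE]
      lagv <- sub[[paste0(".rawlag_", nm)]]
      rawv <- sub[[paste0(".raw_", nm)]]
      strat <- function(origin, dest) {
        s <- sub[!is.na(lagv) & lagv == origin, , drop = FALSE]
        yy <- as.numeric(rawv[!is.na(lagv) & lagv == origin] == dest)
        fit_one_model(yy, cv$terms, s, "binomial",
                      paste0(nm, ":", origin))
      }
      fits[[nm]] <- list(start = strat("never", "current"),
                         relapse = strat("former", "current"),
                         quit = strat("current", "former"))
    } else {
      sub <- frame[frame$k > 0L & frame$visit == 1, , drop = FALSE]
      if (cv$family == "absorbing") {
        lagv <- sub[[paste0(".rawlag_", nm)]]
        sub <- sub[!is.na(lagv) & lagv == 0, , drop = FALSE]
      }
      if (nrow(sub) == 0L) stop_gf("covariate '%s': empty fitting set", nm)
      y <- sub[[paste0(".raw_", nm)]]
      fam <- if (cv$family == "continuous") "gaussian" else "binomial"
      bounds <- cv$bounds %||%
        if (cv$family == "continuous") range(frame[[paste0(".raw_", nm)]],
                                             na.rm = TRUE)
      fits[[nm]] <- fit_one_model(y, cv$terms, sub, fam, nm, bounds = bounds)
    }
  }
  fits
}

#' Fit the pooled logistic event and death models
#'
#' Discrete-time hazards approximated by pooled logistic regression over all
#' at-risk person-intervals. Under `mode = "competing"`, a death model is fit
#' on all at-risk records and the event model on records without a death that
#' interval (within an interval, death precedes the event). Under
#' `mode = "censor_death"` the event model alone is used (death leaves the
#' risk set like censoring). Under `mode = "composite"` a single model is fit
#' for the combined endpoint (event or death).
#'
#' @inheritParams fit_covariate_models
#' @param mode Competing-event handling.
#' @return List with elements `event`, `death` (competing only), `composite`
#'   (composite only), and `mode`.
#' @export
fit_event_models <- function(cohort, config, mode = config$mode,
                             frame = NULL) {
  frame <- frame %||% build_model_frame(cohort, config)
  out <- list(mode = mode)
  if (mode == "composite") {
    y <- pmin(frame$event + frame$death, 1)
    if (sum(y) == 0L) stop_gf("no composite events in the cohort")
    out$composite <- fit_one_model(y, config$event_terms, frame, "binomial",
                                   "composite")
    return(out)
  }
  sub <- frame[frame$death == 0, , drop = FALSE]
  if (sum(sub$event) == 0L) stop_gf("no events in the cohort")
  out$event <- fit_one_model(sub$event, config$event_terms, sub, "binomial",
                             "event")
  if (mode == "competing") {
    if (sum(frame$death) == 0L) stop_gf("no deaths in the cohort")
    out$death <- fit_one_model(frame$death, config$death_terms, frame,
                               "binomial", "death")
  }
  out
}

#' Fit all g-formula models
#'
#' Convenience wrapper returning covariate fits and event/death fits together
#' with fit metadata (records used, convergence and degeneracy flags).
#'
#' @inheritParams fit_event_models
#' @return A `gf_fits` object.
#' @export
fit_gformula_models <- function(cohort, config, mode = config$mode) {
  frame <- build_model_frame(cohort, config)
  covs <- fit_covariate_models(cohort, config, frame = frame)
  haz <- fit_event_models(cohort, config, mode = mode, frame = frame)
  structure(list(covariates = covs, event = haz$event, death = haz$death,
                 composite = haz$composite, mode = mode,
                 n_records = nrow(frame)),
            class = "gf_fits")
}

#' @export
print.gf_fits <- function(x, ...) {
  flat <- unlist(list(x$covariates), recursive = FALSE)
  n_deg <- 0L
  for (f in x$covariates) {
    if (inherits(f, "gf_fit")) n_deg <- n_deg + f$degenerate
    else n_deg <- n_deg + sum(vapply(f, `[[`, TRUE, "degenerate"))
  }
  cat(sprintf("<gf_fits> %d covariate models (%d degenerate), mode = %s, %d person-intervals\n",
              length(x$covariates), n_deg, x$mode, x$n_records))
  invisible(x)
}

#' Audit dump of fitted coefficients
#'
#' Writes all fitted coefficients to a plain-text file, one row per
#' model/term.
#'
#' @param fits A `gf_fits`.
#' @param path Output path (CSV).
#' @return `path`, invisibly.
#' @export
write_fits <- function(fits, path) {
  rows <- list()
  grab <- function(f, label) {
    if (is.null(f)) return()
    if (f$degenerate) {
      rows[[length(rows) + 1L]] <<- data.frame(
        model = label, term = "(degenerate constant)",
        estimate = as.numeric(f$constant), sigma = f$sigma, n = f$n)
    } else {
      rows[[length(rows) + 1L]] <<- data.frame(
        model = label, term = names(f$coef), estimate = unname(f$coef),
        sigma = f$sigma, n = f$n)
    }
  }
  for (nm in names(fits$covariates)) {
    f <- fits$covariates[[nm]]
    if (inherits(f, "gf_fit")) grab(f, nm)
    else for (part in names(f)) grab(f[[part]], paste0(nm, ":", part))
  }
  grab(fits$event, "event")
  grab(fits$death, "death")
  grab(fits$composite, "composite")
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
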