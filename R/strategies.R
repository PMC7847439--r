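# Hypothetical sustained treatment strategies: rule sets applied to the
# simulated covariate state at every interval before hazards are evaluated.

#' Define one intervention rule
#'
#' A rule targets one covariate: when the condition holds for a simulated
#' individual at an interval, the assignment is applied. Conditions compare
#' the current (possibly already-intervened) value of `when_var` against
#' `when_value` with operator `when_op`.
#'
#' @param target Covariate to modify.
#' @param when_op Comparison operator: one of `">"`, `">="`, `"<"`, `"<="`,
#'   `"=="`; `NULL` applies unconditionally.
#' @param when_value Comparison value (numeric, or a category for smoking).
#' @param set Value assigned when the condition holds (exclusive with
#'   `scale`).
#' @param scale Multiplicative factor applied when the condition holds.
#' @param when_var Variable tested; defaults to `target`.
#' @return A `gf_rule` object.
#' @export
gf_rule <- function(target, when_op = NULL, when_value = NULL,
                    set = NULL, scale = NULL, when_var = target) {
  if (is.null(set) == is.null(scale)) {
    stop_gf("rule for '%s' must give exactly one of `set` or `scale`", target)
  }
  if (!is.null(when_op) && !when_op %in% c(">", ">=", "<", "<=", "==")) {
    stop_gf("unsupported rule operator '%s'", when_op)
  }
  structure(list(target = target, when_var = when_var, when_op = when_op,
                 when_value = when_value, set = set, scale = scale),
            class = "gf_rule")
}

#' Define a treatment strategy
#'
#' A strategy is an ordered list of [gf_rule()]s applied at every interval of
#' the simulated follow-up, from baseline onward. The natural course carries
#' no rules: covariates evolve as their fitted models dictate.
#'
#' @param id Integer identifier (0 is conventionally the natural course).
#' @param label Human-readable description.
#' @param rules List of [gf_rule()]; must be empty when
#'   `natural_course = TRUE`.
#' @param natural_course Logical flag for the no-intervention reference.
#' @return A `gf_strategy` object.
#' @export
gf_strategy <- function(id, label, rules = list(), natural_course = FALSE) {
  if (natural_course && length(rules)) {
    stop_gf("a natural-course strategy cannot carry rules")
  }
  structure(list(id = id, label = label, rules = rules,
                 natural_course = natural_course),
            class = "gf_strategy")
}

#' @export
print.gf_strategy <- function(x, ...) {
  cat(sprintf("<gf_strategy %s> %s (%d rule%s)\n", x$id, x$label,
              length(x$rules), if (length(x$rules) == 1) "" else "s"))
  invisible(x)
}

#' The ten built-in strategies
#'
#' Returns the natural course (id 0), five single strategies — maintain SBP
#' below 120 mmHg (1), maintain SBP below 140 mmHg (2), reduce SBP by 10%
#' if above 140 mmHg (3), reduce SBP by 20% if above 140 mmHg (4), quit
#' smoking (5) — and the four joint strategies combining smoking cessation
#' with each SBP strategy (6-9). Threshold strategies set SBP to exactly the
#' threshold when the simulated value exceeds it (the minimal intervention
#' consistent with "maintaining SBP below" the threshold); quitting smoking
#' moves current smokers to former (cessation cannot erase smoking history)
#' and leaves never- and former smokers untouched.
#'
#' @return A list of 10 [gf_strategy()] objects, ids 0-9.
#' @export
builtin_strategies <- function() {
  r_sbp <- list(
    gf_rule("sbp", ">", 120, set = 120),
    gf_rule("sbp", ">", 140, set = 140),
    gf_rule("sbp", ">", 140, scale = 0.9),
    gf_rule("sbp", ">", 140, scale = 0.8)
  )
  r_quit <- gf_rule("smoking", "==", "current", set = "former")
  sbp_labels <- c("Maintain SBP below 120 mmHg",
                  "Maintain SBP below 140 mmHg",
                  "Reduce SBP by 10% if above 140 mmHg",
                  "Reduce SBP by 20% if above 140 mmHg")
  out <- list(gf_strategy(0L, "Natural course", natural_course = TRUE))
  for (i in 1:4) out[[i + 1L]] <- gf_strategy(i, sbp_labels[i], list(r_sbp[[i]]))
  out[[6L]] <- gf_strategy(5L, "Quit smoking", list(r_quit))
  for (i in 1:4) {
    out[[6L + i]] <- gf_strategy(5L + i,
                                 paste0(sbp_labels[i], " and quit smoking"),
                                 list(r_sbp[[i]], r_quit))
  }
  out
}

#' Apply a strategy to a simulated covariate state
#'
#' Rules are applied in order to the current state; the intervened indicator
#' is 1 for individuals whose state was actually changed by any rule this
#' interval (rule evaluation without a change does not count). Applying a
#' strategy to its own output changes nothing further.
#'
#' @param strategy A [gf_strategy()].
#' @param state A data.frame (or named list of equal-length vectors) of raw
#'   covariate values for the current interval.
#' @param k Interval index (available to future rule types; unused by the
#'   built-in rules).
#' @return `list(state = modified state, intervened = logical vector)`.
#' @export
apply_strategy <- function(strategy, state, k = 0) {
  state <- as.data.frame(state, optional = TRUE)
  n <- nrow(state)
  changed <- rep(FALSE, n)
  if (strategy$natural_course || length(strategy$rules) == 0L) {
    return(list(state = state, intervened = changed))
  }
  for (rule in strategy$rules) {
    if (is.null(state[[rule$target]]) ||
        (!identical(rule$when_var, rule$target) && is.null(state[[rule$when_var]]))) {
      stop_gf("strategy '%s' references covariate '%s' absent from state",
              strategy$label, rule$target)
    }
    v <- state[[rule$when_var]]
    hit <- if (is.null(rule$when_op)) rep(TRUE, n) else {
      switch(rule$when_op,
             ">"  = v >  rule$when_value,
             ">=" = v >= rule$when_value,
             "<"  = v <  rule$when_value,
             "<=" = v <= rule$when_value,
             "==" = v == rule$when_value)
    }
    hit[is.na(hit)] <- FALSE
    if (!any(hit)) next
    old <- state[[rule$target]][hit]
    new <- if (!is.null(rule$set)) {
      rep(rule$set, sum(hit))
    } else {
      old * rule$scale
    }
    state[[rule$target]][hit] <- new
    changed[hit] <- changed[hit] | (new != old)
  }
  list(state = state, intervened = changed)
}

#' Cumulative percent intervened
#'
#' The cumulative proportion (in percent) of simulated individuals whose
#' covariates a strategy has actually altered at any interval up to and
#' including `k` — how far the strategy departs from the natural course.
#' The value at the final interval is reported as "total intervened".
#'
#' @param x Either the result of [run_gformula()] or a logical matrix of
#'   per-interval intervened flags (individuals in rows).
#' @return Numeric vector of cumulative percentages, one per interval.
#' @export
percent_intervened <- function(x) {
  m <- if (is.matrix(x)) x else x$intervened
  if (is.null(m)) stop_gf("no intervened flags available")
  any_yet <- rep(FALSE, nrow(m))
  out <- numeric(ncol(m))
  for (k in seq_len(ncol(m))) {
    any_yet <- any_yet | m[, k]
    out[k] <- 100 * mean(any_yet)
  }
  out
}

# YAML (de)serialization of strategies.
strategy_to_list <- function(s) {
  list(id = s$id, label = s$label, natural_course = s$natural_course,
       rules = lapply(s$rules, function(r) {
         list(target = r$target, when_var = r$when_var, when_op = r$when_op,
              when_value = r$when_value, set = r$set, scale = r$scale)
       }))
}

strategy_from_list <- function(obj) {
  rules <- lapply(obj$rules, function(r) {
    gf_rule(r$target, when_op = r$when_op, when_value = r$when_value,
            set = r$set, scale = r$scale, when_var = r$when_var %||% r$target)
  })
  gf_strategy(obj$id, obj$label, rules,
              natural_course = isTRUE(obj$natural_course))
}
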