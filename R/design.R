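# Design-frame construction: the single place where raw cohort fields are
# expanded into the numeric columns that model formulas may reference.
#
# Naming scheme (all numeric):
#   baseline:  age, age2, sex, sbp0, sbp0_2, sbp0_3, edu_further, edu_higher,
#              apoe4_carrier, apoe4_missing, diabetes0, heart_disease0, mmse0,
#              plus any other numeric baseline column passed through as-is
#   time:      tt (interval index k), tt2 (= k^2)
#   current:   cur_<name> for each time-varying covariate at interval k
#   lagged:    lag_<name> for its value at interval k - 1
# A three-level smoking-style covariate <name> expands to two indicator
# columns <name>_former and <name>_current (reference level "never").

SMOKING_LEVELS <- c("never", "former", "current")

# Design column names contributed by one time-varying covariate.
tv_design_names <- function(name, family) {
  if (identical(family, "smoking")) paste0(name, c("_former", "_current")) else name
}

# Expand raw values of one time-varying covariate into named numeric columns.
expand_tv <- function(name, family, values, prefix = "") {
  if (identical(family, "smoking")) {
    out <- list(as.numeric(values == "former"), as.numeric(values == "current"))
    names(out) <- paste0(prefix, name, c("_former", "_current"))
  } else {
    out <- list(as.numeric(values))
    names(out) <- paste0(prefix, name)
  }
  out
}

#' Expand a baseline table into numeric design columns
#'
#' Derives the polynomial and indicator columns used by the default model
#' terms: a quadratic in age, a cubic in baseline SBP, dummy coding for
#' education (reference `primary`) and APOE-e4 status (reference
#' `noncarrier`, with `missing` retained as its own category). Numeric
#' columns other than `person_id` are passed through unchanged.
#'
#' @param baseline A baseline data.frame.
#' @return A data.frame of numeric columns, one row per person.
#' @keywords internal
expand_baseline <- function(baseline) {
  out <- list()
  for (nm in setdiff(names(baseline), "person_id")) {
    v <- baseline[[nm]]
    if (nm == "education") {
      out$edu_further <- as.numeric(v == "further")
      out$edu_higher <- as.numeric(v == "higher")
    } else if (nm == "apoe4") {
      out$apoe4_carrier <- as.numeric(v == "carrier")
      out$apoe4_missing <- as.numeric(v == "missing")
    } else if (is.numeric(v) || is.logical(v)) {
      out[[nm]] <- as.numeric(v)
    }
  }
  if (!is.null(out$age)) out$age2 <- out$age^2
  if (!is.null(out$sbp0)) {
    out$sbp0_2 <- out$sbp0^2
    out$sbp0_3 <- out$sbp0^3
  }
  n <- nrow(baseline)
  if (length(out) == 0L) return(data.frame(row.names = seq_len(n)))
  as.data.frame(out, optional = TRUE)
}

# Assemble a design frame from expanded baseline columns, current and lagged
# raw covariate values, and the interval index. `cur`/`lag` are named lists of
# raw vectors (lag may be NULL, e.g. at baseline).
make_design_frame <- function(ble, covs, cur = NULL, lag = NULL, k = 0) {
  n <- nrow(ble)
  cols <- as.list(ble)
  tt <- if (length(k) == 1L) rep(as.numeric(k), n) else as.numeric(k)
  cols$tt <- tt
  cols$tt2 <- tt^2
  add <- function(vals, prefix) {
    for (cv in covs) {
      v <- vals[[cv$name]]
      if (is.null(v)) next
      cols[names(expand_tv(cv$name, cv$family, v, prefix))] <<-
        expand_tv(cv$name, cv$family, v, prefix)
    }
  }
  if (!is.null(cur)) add(cur, "cur_")
  if (!is.null(lag)) add(lag, "lag_")
  out <- as.data.frame(cols, optional = TRUE)
  if (nrow(out) == 0L && n > 0L) out <- data.frame(row.names = seq_len(n))
  out
}

#' Build a model design matrix from covariate history
#'
#' Expands a history record (baseline fields plus `cur_`/`lag_`-prefixed
#' covariate values, or pre-expanded design columns) into the numeric design
#' matrix implied by a term specification. Polynomial baseline terms are
#' derived automatically (`age2`, `sbp0_2`, `sbp0_3`), categorical fields are
#' one-hot coded against their documented reference levels, and the interval
#' index enters through `tt`/`tt2`.
#'
#' @param history A data.frame (or coercible list) holding the fields the
#'   terms reference.
#' @param spec A [covariate_spec()] or any list with a `terms` character
#'   vector; `list(terms = character(0))` yields an intercept-only design.
#' @param k Interval index (scalar or one value per row of `history`).
#' @return A numeric matrix with one row per history row, including an
#'   intercept column.
#' @examples
#' build_design(data.frame(age = 60), list(terms = c("age", "age2")), k = 0)
#' @export
build_design <- function(history, spec, k = 0) {
  history <- as.data.frame(history, optional = TRUE)
  ble <- expand_baseline(history)
  drop <- intersect(names(history), c(names(ble), "person_id", "education", "apoe4"))
  extra <- history[setdiff(names(history), drop)]
  df <- if (ncol(extra)) cbind(ble, extra) else ble
  n <- max(nrow(df), 1L)
  tt <- if (length(k) == 1L) rep(as.numeric(k), n) else as.numeric(k)
  if (is.null(df$tt)) df$tt <- tt
  if (is.null(df$tt2)) df$tt2 <- df$tt^2
  terms <- spec$terms %||% character(0)
  f <- if (length(terms)) stats::reformulate(terms) else ~1
  vars <- all.vars(f)
  missing <- setdiff(vars, names(df))
  if (length(missing)) {
    stop_gf("build_design: term variable(s) not available in history: %s",
            paste(missing, collapse = ", "))
  }
  stats::model.matrix(f, df)
}
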