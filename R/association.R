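#' Derive analysis endpoints from raw patient records
#'
#' Adds the responder indicator (CR or PR; NE responses become NA and are
#' excluded from response analyses) and, when date columns are present
#' (`start_date`, `progression_date`, `death_date`,
#' `last_assessment_date`), computes PFS (time to progression or death,
#' whichever first; otherwise censored at last assessment) and OS (time to
#' death; otherwise censored at last assessment) in months. Precomputed
#' `pfs_time_months`/`os_time_months` columns are kept as-is.
#'
#' @param records per-patient data.frame.
#' @param days_per_month divisor converting day differences to months.
#' @return the records with `responder`, `pfs_time_months`, `pfs_event`,
#'   `os_time_months`, `os_event` populated.
#' @export
derive_endpoints <- function(records, days_per_month = 30.44) {
  records <- as.data.frame(records)
  if ("response" %in% names(records)) {
    r <- as.character(records$response)
    r[r %in% c("NE", "")] <- NA
    records$responder <- ifelse(is.na(r), NA_integer_,
                                as.integer(r %in% c("CR", "PR")))
  }
  has_dates <- all(c("start_date", "last_assessment_date") %in% names(records))
  if (has_dates) {
    months <- function(to) as.numeric(difftime(as.Date(to),
                                               as.Date(records$start_date),
                                               units = "days")) / days_per_month
    prog <- if ("progression_date" %in% names(records))
      months(records$progression_date) else rep(NA_real_, nrow(records))
    death <- if ("death_date" %in% names(records))
      months(records$death_date) else rep(NA_real_, nrow(records))
    last <- months(records$last_assessment_date)
    pfs_ev_time <- pmin(prog, death, na.rm = TRUE)
    records$pfs_event <- as.integer(is.finite(pfs_ev_time))
    records$pfs_time_months <- ifelse(records$pfs_event == 1L,
                                      pfs_ev_time, last)
    records$os_event <- as.integer(!is.na(death))
    records$os_time_months <- ifelse(records$os_event == 1L, death, last)
  }
  for (col in c("pfs_time_months", "os_time_months"))
    if (col %in% names(records) &&
        any(!is.na(records[[col]]) & records[[col]] < 0))
      stop("negative duration in `", col, "`", call. = FALSE)
  records
}

#' Cohort frequency summary
#'
#' Counts and percentages (1 decimal) for categorical cohort variables;
#' denominators are the evaluable (non-missing) patients per variable.
#'
#' @param records per-patient data.frame.
#' @param variables columns to summarise; defaults to all factor/character
#'   columns except `patient_id`.
#' @return data.frame with `variable`, `level`, `n`, `n_evaluable`, `pct`.
#' @export
cohort_summary <- function(records, variables = NULL) {
  records <- as.data.frame(records)
  if (!nrow(records)) stop("empty cohort", call. = FALSE)
  if (is.null(variables))
    variables <- setdiff(names(records)[vapply(records, function(x)
      is.character(x) || is.factor(x) || is.logical(x), TRUE)], "patient_id")
  if (!length(variables)) stop("no categorical variables found", call. = FALSE)
  do.call(rbind, lapply(variables, function(v) {
    x <- records[[v]]
    x <- x[!is.na(x)]
    if (!length(x))
      return(data.frame(variable = v, level = NA_character_, n = 0L,
                        n_evaluable = 0L, pct = NA_real_,
                        stringsAsFactors = FALSE))
    tab <- table(x)
    data.frame(variable = v, level = names(tab), n = as.integer(tab),
               n_evaluable = length(x),
               pct = round(100 * as.integer(tab) / length(x), 1),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

# Reference levels so reported contrasts run in the direction of the
# headline results: combination group 3, low dichotomies, BRAFi, "no",
# non-M1c stage, PS 0 are baselines.
REF_LEVELS <- list(group = "3", cd8_i = "low", cd163_i = "low",
                   stage = "other", ecog_ps = "0", ldh_elevated = "no",
                   treatment = "BRAFi", subsequent_it = "no")

prep_model_frame <- function(records, vars) {
  df <- as.data.frame(records)[, vars, drop = FALSE]
  for (v in vars) {
    x <- df[[v]]
    if (is.character(x) || is.logical(x)) x <- factor(x)
    if (is.factor(x) && !is.null(REF_LEVELS[[v]]) &&
        REF_LEVELS[[v]] %in% levels(x))
      x <- stats::relevel(x, ref = REF_LEVELS[[v]])
    df[[v]] <- x
  }
  df
}

# Covariates constant in the analysis set carry no information and break the
# factor contrasts; drop them (the biomarker term itself must vary).
drop_constant <- function(df, term, covariates) {
  varies <- function(v) {
    x <- df[[v]]
    length(unique(x[!is.na(x)])) >= 2L
  }
  if (!varies(term))
    stop("biomarker term `", term, "` is constant in the analysis set",
         call. = FALSE)
  covariates[vapply(covariates, varies, TRUE)]
}

tidy_fit <- function(fit, n, model) {
  cf <- coef(fit)
  if (model == "logistic") cf <- cf[names(cf) != "(Intercept)"]
  V <- vcov(fit)
  se <- setNames(rep(NA_real_, length(cf)), names(cf))
  hit <- intersect(names(cf), colnames(V))
  se[hit] <- sqrt(diag(V)[hit])
  est <- exp(cf)
  z <- cf / se
  nonest <- is.na(cf) | is.na(se) | !is.finite(se) | se > 10 | abs(cf) > 15
  out <- data.frame(term = names(cf), estimate = est,
                    ci_lo = exp(cf - 1.959964 * se),
                    ci_hi = exp(cf + 1.959964 * se),
                    p = 2 * pnorm(-abs(z)), n = n, model = model,
                    estimable = !nonest, stringsAsFactors = FALSE,
                    row.names = NULL)
  if (any(nonest))
    attr(out, "diagnostic") <-
      paste("possible separation / non-estimable term(s):",
            paste(out$term[nonest], collapse = ", "))
  class(out) <- c("model_result", "data.frame")
  out
}

#' @export
print.model_result <- function(x, ...) {
  print.data.frame(cbind(x[, c("term", "model", "n")],
                         round(x[, c("estimate", "ci_lo", "ci_hi", "p")], 4)),
                   ...)
  d <- attr(x, "diagnostic")
  if (!is.null(d)) cat("note:", d, "\n")
  invisible(x)
}

#' Multivariable logistic response model
#'
#' Maximum-likelihood logistic regression of the responder indicator
#' (CR/PR vs SD/PD) on a biomarker term plus clinical covariates, with
#' Wald 95% confidence intervals on the odds-ratio scale. Complete-case:
#' patients missing the outcome (including NE responses) or any model
#' variable are dropped and the n used is reported. Complete separation is
#' reported as a non-estimable term with a diagnostic, not an error.
#'
#' @param records per-patient data.frame (responder derived from `response`
#'   if absent).
#' @param term biomarker column, e.g. `"group"` or `"cd8_i"`.
#' @param covariates covariate columns.
#' @return a `model_result` data.frame (term, OR `estimate`, `ci_lo`,
#'   `ci_hi`, `p`, `n`, `model`, `estimable`).
#' @export
fit_response_model <- function(records, term = "group",
                               covariates = c("stage", "ecog_ps",
                                              "ldh_elevated", "treatment")) {
  records <- derive_endpoints(records)
  vars <- c(term, covariates)
  df <- prep_model_frame(records, vars)
  df$responder <- records$responder
  df <- df[complete.cases(df), , drop = FALSE]
  if (length(unique(df$responder)) < 2L)
    stop("need both responders and non-responders", call. = FALSE)
  covariates <- drop_constant(df, term, covariates)
  fml <- stats::as.formula(paste("responder ~",
                                 paste(c(term, covariates), collapse = " + ")))
  fit <- suppressWarnings(glm(fml, family = binomial(), data = df))
  tidy_fit(fit, nrow(df), "logistic")
}

#' Multivariable Cox survival model
#'
#' Cox proportional-hazards regression (Efron tie handling) of PFS or OS on
#' a biomarker term plus clinical covariates; OS models additionally adjust
#' for subsequent immunotherapy. Wald 95% confidence intervals on the
#' hazard-ratio scale; complete-case with the n used reported; a fit with
#' no events is reported as non-estimable rather than an error.
#'
#' @param records per-patient data.frame with `<endpoint>_time_months` and
#'   `<endpoint>_event`.
#' @param endpoint `"os"` or `"pfs"`.
#' @param term biomarker column.
#' @param covariates covariate columns; default adds `subsequent_it` for
#'   OS.
#' @return a `model_result` data.frame (HR scale).
#' @export
fit_survival_model <- function(records, endpoint = c("os", "pfs"),
                               term = "group", covariates = NULL) {
  endpoint <- match.arg(endpoint)
  if (is.null(covariates)) {
    covariates <- c("stage", "ecog_ps", "ldh_elevated", "treatment")
    if (endpoint == "os") covariates <- c(covariates, "subsequent_it")
  }
  records <- as.data.frame(records)
  tcol <- paste0(endpoint, "_time_months")
  ecol <- paste0(endpoint, "_event")
  vars <- c(term, covariates)
  df <- prep_model_frame(records, vars)
  df$.time <- records[[tcol]]
  df$.event <- records[[ecol]]
  df <- df[complete.cases(df), , drop = FALSE]
  if (any(df$.time < 0)) stop("negative survival times", call. = FALSE)
  if (sum(df$.event) < 1L) {
    out <- data.frame(term = vars, estimate = NA_real_, ci_lo = NA_real_,
                      ci_hi = NA_real_, p = NA_real_, n = nrow(df),
                      model = "cox", estimable = FALSE,
                      stringsAsFactors = FALSE)
    attr(out, "diagnostic") <- "no events observed"
    class(out) <- c("model_result", "data.frame")
    return(out)
  }
  covariates <- drop_constant(df, term, covariates)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(c(term, covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  tidy_fit(fit, nrow(df), "cox")
}

#' Kaplan-Meier estimate with median and quartiles
#'
#' Product-limit estimate of PFS or OS, overall or by group. Quantiles use
#' the earliest time at which the curve drops to or below the target
#' survival: median at `S(t) <= 0.5`, quartile times at 0.75 and 0.25.
#' Quantiles never reached are NA.
#'
#' @param records per-patient data.frame.
#' @param endpoint `"os"` or `"pfs"`.
#' @param by optional grouping column.
#' @return list with `curve` (data.frame `group`, `time`, `n_risk`,
#'   `n_event`, `survival`) and `quantiles` (data.frame `group`, `q25`,
#'   `median`, `q75`, in months).
#' @export
km_estimate <- function(records, endpoint = c("os", "pfs"), by = NULL) {
  endpoint <- match.arg(endpoint)
  records <- as.data.frame(records)
  time <- records[[paste0(endpoint, "_time_months")]]
  event <- records[[paste0(endpoint, "_event")]]
  grp <- if (is.null(by)) factor(rep("all", nrow(records)))
         else factor(records[[by]])
  curves <- lapply(levels(grp), function(g) {
    i <- grp == g & !is.na(time) & !is.na(event)
    sf <- survival::survfit(survival::Surv(time[i], event[i]) ~ 1)
    data.frame(group = g, time = sf$time, n_risk = sf$n.risk,
               n_event = sf$n.event, survival = sf$surv,
               stringsAsFactors = FALSE)
  })
  qfun <- function(cv, s0) {
    hit <- which(cv$survival <= s0 + 1e-12)
    if (!length(hit)) NA_real_ else cv$time[min(hit)]
  }
  quantiles <- do.call(rbind, lapply(curves, function(cv)
    data.frame(group = cv$group[1], q25 = qfun(cv, 0.75),
               median = qfun(cv, 0.5), q75 = qfun(cv, 0.25),
               stringsAsFactors = FALSE)))
  list(curve = do.call(rbind, curves), quantiles = quantiles)
}

#' Pearson chi-square association test
#'
#' Chi-square test on a two-way contingency table, without continuity
#' correction by default. Tables with an expected cell below 1 are flagged.
#'
#' @param tab matrix of counts (r x c).
#' @param correct apply the Yates continuity correction (2 x 2 only).
#' @return list with `statistic`, `df`, `p`, `expected_min`, `warning`.
#' @export
chi_square_assoc <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || nrow(tab) < 2L || ncol(tab) < 2L)
    stop("`tab` must be an r x c (>= 2 x 2) table of counts", call. = FALSE)
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  emin <- min(ct$expected)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected_min = emin,
       warning = if (emin < 1) "expected cell count below 1" else NULL)
}

#' Kruskal-Wallis test of counts across score groups
#'
#' Rank-based H statistic (tie-corrected) with the chi-square
#' approximation, as used to relate cell counts to the ordinal density
#' score. All-identical values give H = 0 and p = 1.
#'
#' @param values numeric response (e.g. per-patient cell counts).
#' @param groups grouping (e.g. ordinal score), >= 2 non-empty levels.
#' @return list with `statistic`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups[!is.na(values)])
  values <- values[!is.na(values)]
  if (nlevels(groups) < 2L)
    stop("need at least 2 non-empty groups", call. = FALSE)
  if (length(unique(values)) == 1L)
    return(list(statistic = 0, df = nlevels(groups) - 1L, p = 1))
  kt <- kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}
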