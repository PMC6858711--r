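#' Synthetic-cohort configuration
#'
#' Parameters of the patient-cohort generator. Patients receive independent
#' intratumoral CD8 and CD163 dichotomies (their joint law is set by
#' `group_probs`: the middle group's mass is split equally between
#' high/high and low/low), clinical covariates drawn from the stated
#' category probabilities, a best response drawn from a logistic model, and
#' exponential (optionally Weibull) progression and survival times from
#' proportional-hazards models with independent exponential censoring.
#'
#' Coefficient vectors are named; allowed names are `"(Intercept)"` (logit
#' intercept, logistic only), `"group1"`/`"group2"` (contrasts of the
#' CD8xCD163 combination groups versus group 3), `"cd8_high"`/
#' `"cd163_high"` (dichotomy main effects), and the binary covariates
#' `"stage"` (M1c = 1), `"ecog_ps"` (>= 1), `"ldh_elevated"`,
#' `"treatment"` (BRAFi+MEKi = 1), `"subsequent_it"` (yes = 1). Unknown
#' names are a configuration error.
#'
#' Default effect sizes mirror the headline contrasts the pipeline is built
#' to recover: response OR 9.91 and OS HR 0.34 for group 1 versus group 3.
#' Default covariate prevalences follow the training-cohort summaries (M1c
#' 60%, BRAFi monotherapy 60%, subsequent immunotherapy 25%); responder
#' split CR:PR = 26:73 and non-responder split SD:PD = 25:32.
#'
#' @param n_patients cohort size.
#' @param group_probs probabilities of CD8xCD163 groups 1/2/3 (sum to 1).
#' @param covariate_probs named list of category probability vectors for
#'   `stage` (other/M1c), `ecog_ps` (0/1+), `ldh_elevated` (no/yes),
#'   `treatment` (BRAFi/BRAFi+MEKi), `subsequent_it` (no/yes).
#' @param beta_response named log-odds coefficients for the responder
#'   probability.
#' @param log_hr_os,log_hr_pfs named log-hazard coefficients.
#' @param baseline_hazard_os,baseline_hazard_pfs exponential event rates
#'   per month for a patient with zero linear predictor.
#' @param censoring_rate_os,censoring_rate_pfs rates of independent
#'   exponential censoring (0 = no censoring).
#' @param weibull_shape shape of the Weibull baseline (1 = exponential).
#' @param p_cr_given_responder,p_sd_given_nonresponder splits of the
#'   responder/non-responder classes into CR/PR and SD/PD.
#' @param seed integer RNG seed.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 158L,
                          group_probs = c(0.25, 0.50, 0.25),
                          covariate_probs = list(
                            stage = c(other = 0.40, M1c = 0.60),
                            ecog_ps = c("0" = 0.60, "1+" = 0.40),
                            ldh_elevated = c(no = 0.60, yes = 0.40),
                            treatment = c(BRAFi = 0.60, "BRAFi+MEKi" = 0.40),
                            subsequent_it = c(no = 0.75, yes = 0.25)),
                          beta_response = c("(Intercept)" = qlogis(0.35),
                                            group1 = log(9.91),
                                            group2 = log(3)),
                          log_hr_os = c(group1 = log(0.34),
                                        group2 = log(0.60)),
                          log_hr_pfs = c(group1 = log(0.45),
                                         group2 = log(0.70)),
                          baseline_hazard_os = log(2) / 13.7,
                          baseline_hazard_pfs = log(2) / 8.3,
                          censoring_rate_os = 0.3 / 0.7 * baseline_hazard_os,
                          censoring_rate_pfs = 0.3 / 0.7 * baseline_hazard_pfs,
                          weibull_shape = 1,
                          p_cr_given_responder = 26 / 99,
                          p_sd_given_nonresponder = 25 / 57,
                          seed = 1L) {
  if (n_patients < 1L) stop("`n_patients` must be >= 1", call. = FALSE)
  if (length(group_probs) != 3L || any(group_probs < 0) ||
      abs(sum(group_probs) - 1) > 1e-8)
    stop("`group_probs` must be 3 probabilities summing to 1", call. = FALSE)
  need <- c("stage", "ecog_ps", "ldh_elevated", "treatment", "subsequent_it")
  if (!all(need %in% names(covariate_probs)))
    stop("`covariate_probs` must name: ", paste(need, collapse = ", "),
         call. = FALSE)
  for (v in need) {
    p <- covariate_probs[[v]]
    if (length(p) != 2L || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("`covariate_probs$", v, "` must be 2 probabilities summing to 1",
           call. = FALSE)
  }
  allowed <- c("(Intercept)", "group1", "group2", "cd8_high", "cd163_high",
               need)
  for (nm in c("beta_response", "log_hr_os", "log_hr_pfs")) {
    b <- get(nm)
    if (length(b) && (is.null(names(b)) || !all(names(b) %in% allowed)))
      stop("`", nm, "` has coefficient name(s) outside the design: ",
           paste(setdiff(names(b), allowed), collapse = ", "), call. = FALSE)
    if (any(!is.finite(b)))
      stop("`", nm, "` must be finite", call. = FALSE)
  }
  check_number(baseline_hazard_os, "baseline_hazard_os",
               lower = .Machine$double.eps)
  check_number(baseline_hazard_pfs, "baseline_hazard_pfs",
               lower = .Machine$double.eps)
  check_number(censoring_rate_os, "censoring_rate_os", lower = 0)
  check_number(censoring_rate_pfs, "censoring_rate_pfs", lower = 0)
  check_number(weibull_shape, "weibull_shape", lower = .Machine$double.eps)
  structure(list(n_patients = as.integer(n_patients),
                 group_probs = group_probs,
                 covariate_probs = covariate_probs,
                 beta_response = beta_response,
                 log_hr_os = log_hr_os, log_hr_pfs = log_hr_pfs,
                 baseline_hazard_os = baseline_hazard_os,
                 baseline_hazard_pfs = baseline_hazard_pfs,
                 censoring_rate_os = censoring_rate_os,
                 censoring_rate_pfs = censoring_rate_pfs,
                 weibull_shape = weibull_shape,
                 p_cr_given_responder = p_cr_given_responder,
                 p_sd_given_nonresponder = p_sd_given_nonresponder,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Linear predictor for a named coefficient vector over the simulated design.
cohort_lp <- function(b, df) {
  lp <- rep(if ("(Intercept)" %in% names(b)) b[["(Intercept)"]] else 0,
            nrow(df))
  add <- function(lp, nm, x) if (nm %in% names(b)) lp + b[[nm]] * x else lp
  lp <- add(lp, "group1", as.numeric(df$group == "1"))
  lp <- add(lp, "group2", as.numeric(df$group == "2"))
  lp <- add(lp, "cd8_high", as.numeric(df$cd8_i == "high"))
  lp <- add(lp, "cd163_high", as.numeric(df$cd163_i == "high"))
  lp <- add(lp, "stage", as.numeric(df$stage == "M1c"))
  lp <- add(lp, "ecog_ps", as.numeric(df$ecog_ps == "1+"))
  lp <- add(lp, "ldh_elevated", as.numeric(df$ldh_elevated == "yes"))
  lp <- add(lp, "treatment", as.numeric(df$treatment == "BRAFi+MEKi"))
  lp <- add(lp, "subsequent_it", as.numeric(df$subsequent_it == "yes"))
  lp
}

#' Simulate a patient cohort with known ground truth
#'
#' Draws biomarker groups, clinical covariates, best response (CR/PR/SD/PD)
#' and censored PFS/OS times per [cohort_config()]. Deterministic given
#' `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return data.frame with columns `patient_id`, `cd8_i`, `cd163_i`,
#'   `group`, `stage`, `ecog_ps`, `ldh_elevated`, `treatment`,
#'   `subsequent_it`, `response`, `pfs_time_months`, `pfs_event`,
#'   `os_time_months`, `os_event`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  with_seed(config$seed, {
    gp <- config$group_probs
    # group via the underlying dichotomies: 1 = high/low, 3 = low/high,
    # group 2 mass split equally between high/high and low/low
    joint <- c(hl = gp[1], hh = gp[2] / 2, ll = gp[2] / 2, lh = gp[3])
    cls <- sample(names(joint), n, replace = TRUE, prob = joint)
    cd8 <- factor(ifelse(cls %in% c("hl", "hh"), "high", "low"),
                  levels = c("low", "high"))
    cd163 <- factor(ifelse(cls %in% c("lh", "hh"), "high", "low"),
                    levels = c("low", "high"))
    draw <- function(p) factor(sample(names(p), n, replace = TRUE, prob = p),
                               levels = names(p))
    cp <- config$covariate_probs
    df <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                     cd8_i = cd8, cd163_i = cd163,
                     group = combine_cd8_cd163(cd8, cd163),
                     stage = draw(cp$stage), ecog_ps = draw(cp$ecog_ps),
                     ldh_elevated = draw(cp$ldh_elevated),
                     treatment = draw(cp$treatment),
                     subsequent_it = draw(cp$subsequent_it),
                     stringsAsFactors = FALSE)
    p_resp <- plogis(cohort_lp(config$beta_response, df))
    responder <- rbinom(n, 1L, p_resp) == 1L
    u <- runif(n)
    df$response <- ifelse(responder,
                          ifelse(u < config$p_cr_given_responder, "CR", "PR"),
                          ifelse(u < config$p_sd_given_nonresponder, "SD", "PD"))
    surv_draw <- function(b, rate0, crate) {
      haz <- rate0 * exp(cohort_lp(b, df))
      # Weibull PH: S(t) = exp(-haz * t^shape); shape 1 = exponential
      t_ev <- (-log(runif(n)) / haz)^(1 / config$weibull_shape)
      t_cn <- if (crate > 0) rexp(n, crate) else rep(Inf, n)
      list(time = pmin(t_ev, t_cn), event = as.integer(t_ev <= t_cn))
    }
    pfs <- surv_draw(config$log_hr_pfs, config$baseline_hazard_pfs,
                     config$censoring_rate_pfs)
    os <- surv_draw(config$log_hr_os, config$baseline_hazard_os,
                    config$censoring_rate_os)
    df$pfs_time_months <- pfs$time
    df$pfs_event <- pfs$event
    df$os_time_months <- os$time
    df$os_event <- os$event
    df
  })
}
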