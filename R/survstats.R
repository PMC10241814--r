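#' Apply the administrative censoring rule
#'
#' Follow-up is truncated at the horizon: any record with time beyond it
#' becomes censored at the horizon; events at or before the horizon are
#' untouched (the boundary keeps its event status).
#'
#' @param time event/censoring times in years (>= 0).
#' @param event 0/1 event indicators.
#' @param horizon censoring horizon in years (default 5).
#' @return data.frame with columns `time` and `event`.
#' @export
apply_censoring_rule <- function(time, event, horizon = 5) {
  if (any(time < 0)) stop("negative survival time")
  if (!all(event %in% c(0, 1))) stop("event indicators must be 0/1")
  over <- time > horizon
  data.frame(time = pmin(time, horizon),
             event = as.integer(ifelse(over, 0L, event)))
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator (events precede censorings at tied times, the
#' standard convention), with the median survival and the survival
#' probability at a landmark time (default 5 years).
#'
#' @param time times in years (>= 0).
#' @param event 0/1 event indicators.
#' @param landmark time at which to report survival (default 5).
#' @return object of class `km_estimate`: step function as `time`/`surv`
#'   vectors, `median`, `surv_landmark`, `n`, `n_events`.
#' @export
km_estimate <- function(time, event, landmark = 5) {
  if (length(time) < 1) stop("at least one observation is required")
  if (any(time < 0)) stop("negative survival time")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(list(time = sf$time, surv = sf$surv,
                 median = unname(summary(sf)$table["median"]),
                 surv_landmark = km_surv_at(sf$time, sf$surv, landmark),
                 n = length(time), n_events = sum(event)),
            class = "km_estimate")
}

km_surv_at <- function(times, surv, at) {
  idx <- which(times <= at)
  if (length(idx) == 0) 1 else surv[max(idx)]
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: n=%d, events=%d, median=%s, S=%.3f",
              x$n, x$n_events,
              ifelse(is.na(x$median), "not reached", format(x$median)),
              x$surv_landmark), "\n")
  invisible(x)
}

COVARIATE_SET <- c("age", "sex", "who_ps", "size", "grade", "depth",
                   "margin", "histology")

# Model-frame encodings (reference levels follow the validation study's
# reporting convention): hypoxia high vs low; sex male vs female;
# WHO PS 1/2-3 vs 0; grade I/II vs III (grade III is the reference);
# depth deep vs superficial; margin R1 vs R0; histology dummy-coded vs
# LMS; age and size continuous. Rows with "Unknown" in an included
# categorical covariate are dropped.
encode_covariates <- function(clinical, covariates, hypoxia = NULL) {
  df <- data.frame(row.names = seq_len(nrow(clinical)))
  keep <- rep(TRUE, nrow(clinical))
  for (cv in covariates) {
    col <- switch(cv,
      hypoxia = {
        if (is.null(hypoxia)) stop("hypoxia labels are required")
        lab <- hypoxia[clinical$sample_id]
        if (any(is.na(lab)))
          stop("missing hypoxia label for sample(s): ",
               paste(clinical$sample_id[is.na(lab)], collapse = ", "))
        factor(as.character(lab), levels = c("low", "high"))
      },
      age = clinical$age,
      size = clinical$size_cm,
      sex = factor(clinical$sex, levels = c("Female", "Male")),
      who_ps = {
        x <- as.character(clinical$who_ps)
        keep <- keep & x != "Unknown"
        factor(ifelse(x == "0", "0", "1+"), levels = c("0", "1+"))
      },
      grade = {
        x <- as.character(clinical$grade)
        keep <- keep & x != "Unknown"
        factor(ifelse(x %in% c("1", "2"), "I/II", "III"),
               levels = c("III", "I/II"))
      },
      depth = factor(clinical$depth, levels = c("Superficial", "Deep")),
      margin = {
        x <- as.character(clinical$margin)
        keep <- keep & x != "Unknown"
        factor(x, levels = c("R0", "R1"))
      },
      histology = {
        lev <- c("LMS", setdiff(unique(clinical$histology), "LMS"))
        factor(clinical$histology, levels = lev)
      },
      stop("unknown covariate: ", cv))
    df[[cv]] <- col
  }
  list(frame = df, keep = keep)
}

#' Cox proportional-hazards fit for one endpoint
#'
#' Partial-likelihood fit (Efron tie handling) of a survival endpoint on
#' hypoxia class and/or baseline clinical covariates, with Wald 95%
#' confidence intervals and p values per term. Covariate encodings
#' follow the validation study's reporting convention (see
#' [select_multivariable()]); `"Unknown"` strata of an included
#' categorical covariate are dropped from the fit.
#'
#' @param clinical a validated clinical table (see [read_clinical()]).
#' @param endpoint one of `"lrfs"`, `"mfs"`, `"dfs"`, `"os"`.
#' @param covariates character vector from `"hypoxia"`, `"age"`,
#'   `"sex"`, `"who_ps"`, `"size"`, `"grade"`, `"depth"`, `"margin"`,
#'   `"histology"`.
#' @param hypoxia named `"low"`/`"high"` labels per sample_id, required
#'   when `"hypoxia"` is a covariate.
#' @return object of class `survival_fit`: `terms` data.frame (term, hr,
#'   ci_low, ci_high, p), `loglik`, `loglik_null`, `df`, `n`, `n_events`,
#'   `endpoint`, `covariates` and the underlying `coxph` fit.
#' @export
cox_fit <- function(clinical, endpoint, covariates, hypoxia = NULL) {
  endpoint <- match.arg(endpoint, ENDPOINTS)
  validate_clinical(clinical)
  enc <- encode_covariates(clinical, covariates, hypoxia)
  dat <- enc$frame
  dat$.time <- clinical[[paste0(endpoint, "_time_years")]]
  dat$.event <- clinical[[paste0(endpoint, "_event")]]
  dat <- dat[enc$keep & stats::complete.cases(dat), , drop = FALSE]
  if (sum(dat$.event) < 1)
    stop("no events for endpoint '", endpoint, "'")
  for (cv in covariates) {
    x <- dat[[cv]]
    if ((is.factor(x) && length(unique(as.character(x))) < 2) ||
        (is.numeric(x) && stats::sd(x) == 0))
      stop("covariate '", cv, "' is constant in the analysis set")
  }
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|out of iterations|beta may be",
                conditionMessage(w)))
        stop("Cox fit did not converge (possible separation): ",
             conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  terms <- data.frame(term = rownames(sm$coefficients),
                      hr = sm$coefficients[, "exp(coef)"],
                      ci_low = sm$conf.int[, "lower .95"],
                      ci_high = sm$conf.int[, "upper .95"],
                      p = sm$coefficients[, "Pr(>|z|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(endpoint = endpoint, covariates = covariates,
                 terms = terms, loglik = fit$loglik[2],
                 loglik_null = fit$loglik[1],
                 df = length(stats::coef(fit)),
                 n = nrow(dat), n_events = sum(dat$.event), fit = fit),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("Cox fit, endpoint %s: n=%d, events=%d\n",
              toupper(x$endpoint), x$n, x$n_events))
  tt <- x$terms
  for (i in seq_len(nrow(tt)))
    cat(sprintf("  %-16s HR %.2f (95%% CI %.2f-%.2f), P = %.2g\n",
                tt$term[i], tt$hr[i], tt$ci_low[i], tt$ci_high[i],
                tt$p[i]))
  invisible(x)
}

#' @export
coef.survival_fit <- function(object, ...) stats::coef(object$fit)

#' @export
logLik.survival_fit <- function(object, ...) {
  structure(object$loglik, df = object$df, class = "logLik")
}

#' Univariable-screening rule for the multivariable model
#'
#' Fits each baseline clinical feature alone against the endpoint and
#' keeps those with a univariable likelihood-ratio p below `alpha`; the
#' hypoxia classification always enters. Candidates whose univariable
#' fit is degenerate (no events in the analysis set, constant covariate)
#' are skipped.
#'
#' @param clinical clinical table.
#' @param endpoint endpoint code.
#' @param candidates baseline features to screen.
#' @param alpha inclusion threshold (default 0.05).
#' @return character vector of covariates, starting with `"hypoxia"`.
#' @export
select_multivariable <- function(clinical, endpoint,
                                 candidates = COVARIATE_SET,
                                 alpha = 0.05) {
  keep <- character(0)
  for (cv in candidates) {
    p <- tryCatch({
      f <- cox_fit(clinical, endpoint, cv)
      unname(stats::pchisq(2 * (f$loglik - f$loglik_null), f$df,
                           lower.tail = FALSE))
    }, error = function(e) NA_real_)
    if (!is.na(p) && p < alpha) keep <- c(keep, cv)
  }
  c("hypoxia", keep)
}

#' Harrell's concordance index for a risk score
#'
#' Probability that, of a comparable (usable) patient pair, the one with
#' the higher risk score fails first; ties in the score count one half.
#'
#' @param time times in years.
#' @param event 0/1 event indicators.
#' @param risk per-patient risk score (higher = worse prognosis).
#' @return list with `c` and `se`.
#' @export
c_index <- function(time, event, risk) {
  cc <- survival::concordance(survival::Surv(time, event) ~ risk,
                              reverse = TRUE)
  usable <- sum(cc$count[c("concordant", "discordant", "tied.x")])
  if (usable == 0) stop("no comparable pairs")
  list(c = unname(cc$concordance), se = unname(sqrt(cc$var)))
}

#' Likelihood-ratio test between nested Cox models
#'
#' @param fit_full,fit_reduced `survival_fit` objects on the same
#'   endpoint and data, with the reduced covariates a strict subset of
#'   the full ones.
#' @return list with `delta_deviance`, `df`, `p`.
#' @export
lrt_nested <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "survival_fit"),
            inherits(fit_reduced, "survival_fit"))
  if (fit_full$endpoint != fit_reduced$endpoint)
    stop("models use different endpoints")
  if (!all(fit_reduced$covariates %in% fit_full$covariates))
    stop("models are not nested")
  if (fit_full$n != fit_reduced$n || fit_full$n_events !=
        fit_reduced$n_events)
    stop("models were fit on different analysis sets")
  dd <- 2 * (fit_full$loglik - fit_reduced$loglik)
  df <- fit_full$df - fit_reduced$df
  p <- if (df == 0) 1 else stats::pchisq(dd, df, lower.tail = FALSE)
  list(delta_deviance = dd, df = df, p = p)
}

#' Log-rank test across groups
#'
#' @param groups per-patient group labels (>= 2 non-empty groups).
#' @param time times in years.
#' @param event 0/1 event indicators.
#' @return list with `stat` (chi-square), `df`, `p`.
#' @export
logrank_test <- function(groups, time, event) {
  groups <- as.character(groups)
  k <- length(unique(groups))
  if (k < 2) stop("log-rank needs at least 2 non-empty groups")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ groups)
  list(stat = unname(sd_$chisq), df = k - 1,
       p = unname(stats::pchisq(sd_$chisq, k - 1, lower.tail = FALSE)))
}

#' Stratify patients by hypoxia class and nomogram-predicted survival
#'
#' Crosses the binary hypoxia call with the 10-year predicted overall
#' survival at a cut-off (default 0.60; the boundary counts as low
#' clinical risk, i.e. `pOShigh`), yielding four groups, a K-group
#' log-rank test and a per-group landmark Kaplan-Meier survival.
#' Patients without a `pos10` value are excluded and counted.
#'
#' @param calls class-call data.frame (`sample_id`, `label`).
#' @param clinical clinical table with `pos10` and the endpoint columns.
#' @param cut pOS cut-off as a fraction (default 0.60).
#' @param endpoint endpoint for the survival comparison (default
#'   `"os"`).
#' @param landmark years for the per-group survival summary (default 5).
#' @return list with `groups` (data.frame sample_id, group), `n_excluded`,
#'   `logrank`, and `km_landmark` (named per-group survival).
#' @export
stratify_pos <- function(calls, clinical, cut = 0.60, endpoint = "os",
                         landmark = 5) {
  endpoint <- match.arg(endpoint, ENDPOINTS)
  idx <- match(calls$sample_id, clinical$sample_id)
  if (any(is.na(idx)))
    stop("class calls for sample(s) absent from the clinical table: ",
         paste(calls$sample_id[is.na(idx)], collapse = ", "))
  pos10 <- clinical$pos10[idx]
  ok <- !is.na(pos10)
  n_excluded <- sum(!ok)
  lab <- calls$label[ok]
  hi_pos <- pos10[ok] >= cut
  group <- sprintf("hypoxia%s_pOS%s",
                   ifelse(lab == "high", "High", "Low"),
                   ifelse(hi_pos, "high", "low"))
  time <- clinical[[paste0(endpoint, "_time_years")]][idx][ok]
  event <- clinical[[paste0(endpoint, "_event")]][idx][ok]
  lr <- logrank_test(group, time, event)
  km5 <- vapply(sort(unique(group)), function(g) {
    km_estimate(time[group == g], event[group == g],
                landmark = landmark)$surv_landmark
  }, numeric(1))
  list(groups = data.frame(sample_id = calls$sample_id[ok],
                           group = group, stringsAsFactors = FALSE),
       n_excluded = n_excluded, logrank = lr, km_landmark = km5)
}
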