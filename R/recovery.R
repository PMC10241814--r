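#' Hazard-ratio recovery study
#'
#' Simulates replicate cohorts under a configured true hazard ratio for
#' hypoxia-high versus low, fits the Cox model to each, and aggregates
#' the fitted hazard ratios. Replicates are aggregated on the log scale
#' (the reported `mean_hr` is `exp(mean(log HR))`): a hazard ratio is an
#' exponentiated coefficient, and the arithmetic mean of the ratio is
#' inflated by Jensen's inequality when per-cohort event counts are low.
#'
#' @param endpoint endpoint code (`"lrfs"`, `"mfs"`, `"dfs"`, `"os"`).
#' @param true_hr the generating hazard ratio.
#' @param n_patients cohort size per replicate.
#' @param prevalence hypoxia-high mixing fraction.
#' @param n_reps number of replicate cohorts.
#' @param seed master seed; per-replicate generator seeds are drawn from
#'   it.
#' @param covariates Cox model terms (default univariable hypoxia).
#' @param confounded if `TRUE` the generator's grade/size hazard effects
#'   stay on (class-associated confounding, so the marginal and
#'   conditional hypoxia HR differ and `true_hr` is the conditional
#'   one); if `FALSE` (default) they are zeroed so survival depends on
#'   class alone and `true_hr` is also the marginal HR.
#' @param baseline_hazard optional override of the endpoint's baseline
#'   event rate (events/year in the hypoxia-low class).
#' @return list: `mean_hr`, `se_log` (Monte-Carlo SE of the mean log HR),
#'   `hrs` (per-replicate), `mean_events` and the inputs.
#' @export
hr_recovery <- function(endpoint, true_hr, n_patients, prevalence,
                        n_reps = 200, seed = 1, covariates = "hypoxia",
                        confounded = FALSE, baseline_hazard = NULL) {
  endpoint <- match.arg(endpoint, ENDPOINTS)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  cm <- if (confounded) list() else list(hr_grade3 = 1, beta_size = 0)
  hrs <- events <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    hr <- c(lrfs = 2.17, mfs = 1.92, dfs = 2.00, os = 2.38)
    hr[endpoint] <- true_hr
    bh <- c(lrfs = 0.016, mfs = 0.055, dfs = 0.065, os = 0.075)
    if (!is.null(baseline_hazard)) bh[endpoint] <- baseline_hazard
    cfg <- sim_config(seed = rep_seeds[r], n_patients = n_patients,
                      prevalence_high = prevalence, hr = hr,
                      baseline_hazard = bh, covariate_model = cm)
    co <- simulate_cohort(cfg, lanes = FALSE)
    lab <- stats::setNames(as.character(co$true_class),
                           names(co$true_class))
    fit <- cox_fit(co$clinical, endpoint, covariates, hypoxia = lab)
    hrs[r] <- fit$terms$hr[fit$terms$term == "hypoxiahigh"]
    events[r] <- fit$n_events
  }
  lg <- log(hrs)
  list(mean_hr = exp(mean(lg)), se_log = stats::sd(lg) / sqrt(n_reps),
       hrs = hrs, mean_events = mean(events), endpoint = endpoint,
       true_hr = true_hr, n_patients = n_patients, n_reps = n_reps)
}

#' Classifier prevalence recovery study
#'
#' Fits centroids on a disjoint seeded synthetic training cohort, then
#' classifies replicate cohorts generated at a given hypoxia-high mixing
#' fraction through the full normalization + classification path and
#' averages the called prevalence.
#'
#' @param prevalence generating mixing fraction.
#' @param n_patients cohort size per replicate.
#' @param n_reps number of replicate cohorts.
#' @param seed master seed (training cohort and replicates derive from
#'   it).
#' @param n_train training cohort size (balanced classes).
#' @return list: `mean_prevalence` (fraction called high, averaged over
#'   replicates), `per_rep`, `accuracy` (mean agreement with the hidden
#'   truth).
#' @export
prevalence_recovery <- function(prevalence, n_patients = 126,
                                n_reps = 50, seed = 1, n_train = 100) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_reps + 1)
  train <- simulate_cohort(sim_config(seed = seeds[1],
                                      n_patients = n_train,
                                      prevalence_high = 0.5),
                           lanes = FALSE)
  model <- fit_centroids(normalize_counts(train$expression),
                         train$true_class)
  prev <- acc <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    co <- simulate_cohort(sim_config(seed = seeds[r + 1],
                                     n_patients = n_patients,
                                     prevalence_high = prevalence),
                          lanes = FALSE)
    res <- classify_matrix(normalize_counts(co$expression), model)
    prev[r] <- res$prevalence_high
    acc[r] <- mean(res$calls$label ==
                     as.character(co$true_class[res$calls$sample_id]))
  }
  list(mean_prevalence = mean(prev), per_rep = prev,
       accuracy = mean(acc))
}
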