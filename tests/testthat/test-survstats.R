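# minimal clinical table: one endpoint's data copied across all four
make_clinical <- function(time, event, ...) {
  n <- length(time)
  df <- data.frame(sample_id = sprintf("P%03d", seq_len(n)),
                   stringsAsFactors = FALSE)
  for (ep in c("lrfs", "mfs", "dfs", "os")) {
    df[[paste0(ep, "_time_years")]] <- time
    df[[paste0(ep, "_event")]] <- event
  }
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df
}

test_that("administrative censoring truncates at the horizon", {
  out <- apply_censoring_rule(c(7.2, 4.9, 5.0, 0), c(1, 1, 1, 0))
  expect_equal(out$time, c(5, 4.9, 5.0, 0))
  # beyond the horizon -> censored; at the horizon -> event kept
  expect_equal(out$event, c(0L, 1L, 1L, 0L))
  expect_error(apply_censoring_rule(-1, 1), "negative")
  expect_error(apply_censoring_rule(1, 2), "0/1")
})

test_that("Kaplan-Meier matches hand-computed product limits", {
  # no events: survival stays at 1, median never reached
  km0 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(km0$surv_landmark, 1)
  expect_true(is.na(km0$median))
  # times 1 (event), 2 (censored), 3 (event):
  # S(1) = 2/3; at t=3 one at risk, one event -> S(3) = 0
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km_surv_at(km$time, km$surv, 1), 2 / 3)
  expect_equal(km_surv_at(km$time, km$surv, 3), 0)
  expect_equal(km$median, 3)
  expect_equal(km$surv_landmark, 0)
  # everyone fails at 0.5 -> S(0.5) = 0
  expect_equal(km_estimate(rep(0.5, 4), rep(1, 4))$surv_landmark, 0)
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
  expect_output(print(km), "events=2")
})

test_that("the Cox estimate matches a grid-search partial-likelihood
           oracle to 1e-4", {
  # 6 patients, untied event times, binary covariate interleaved with
  # the failure order so the partial likelihood has an interior maximum
  x <- c(1, 0, 1, 0, 1, 0)
  cl <- make_clinical(time = c(1, 2, 3, 4, 5, 6), event = rep(1, 6))
  lab <- stats::setNames(ifelse(x == 1, "high", "low"), cl$sample_id)
  fit <- cox_fit(cl, "os", "hypoxia", hypoxia = lab)
  beta_hat <- unname(coef(fit))
  beta_oracle <- oracle_cox_beta(c(1, 2, 3, 4, 5, 6), rep(1, 6), x)
  expect_equal(beta_hat, beta_oracle, tolerance = 1e-4)
  # and the maximized partial likelihood agrees
  expect_equal(fit$loglik,
               oracle_cox_pl(beta_hat, c(1, 2, 3, 4, 5, 6), rep(1, 6), x),
               tolerance = 1e-8)
  expect_equal(fit$loglik_null,
               oracle_cox_pl(0, c(1, 2, 3, 4, 5, 6), rep(1, 6), x),
               tolerance = 1e-8)
  expect_identical(fit$terms$term, "hypoxiahigh")
  expect_equal(fit$terms$hr, exp(beta_hat))
  expect_output(print(fit), "HR")
})

test_that("the Cox score test reproduces the log-rank statistic", {
  # with no tied event times the score test at beta = 0 is the log-rank
  time <- c(1, 3, 5, 2, 4, 6)
  event <- c(1, 1, 0, 1, 0, 1)
  grp <- rep(c("A", "B"), each = 3)
  cl <- make_clinical(time, event)
  lab <- stats::setNames(ifelse(grp == "A", "high", "low"), cl$sample_id)
  fit <- cox_fit(cl, "os", "hypoxia", hypoxia = lab)
  lr <- logrank_test(grp, time, event)
  expect_equal(unname(summary(fit$fit)$sctest["test"]), lr$stat,
               tolerance = 1e-6)
})

test_that("log-rank matches a hand-computed two-group fixture", {
  # group A: 1 (e), 3 (e), 5 (c); group B: 2 (e), 4 (c), 6 (e)
  # O_A = 2, E_A = 3/6 + 2/5 + 2/4 = 1.4,
  # V = 9/36 + 6/25 + 4/16 = 0.74 -> chi2 = 0.36/0.74
  lr <- logrank_test(rep(c("A", "B"), each = 3),
                     c(1, 3, 5, 2, 4, 6), c(1, 1, 0, 1, 0, 1))
  expect_equal(lr$stat, 0.36 / 0.74, tolerance = 1e-10)
  expect_equal(lr$df, 1)
  expect_equal(lr$p, stats::pchisq(0.36 / 0.74, 1, lower.tail = FALSE))
  # duplicating one group into two identical ones: no separation
  lr2 <- logrank_test(rep(c("A", "B"), times = 3),
                      rep(c(1, 2, 3), each = 2), rep(1, 6))
  expect_equal(lr2$stat, 0, tolerance = 1e-10)
  expect_error(logrank_test(rep("A", 4), 1:4, rep(1, 4)), "2 non-empty")
})

test_that("a null simulation keeps the hazard ratio near one", {
  set.seed(523)
  n <- 500
  cl <- make_clinical(time = stats::rexp(n), event = rep(1, n))
  lab <- stats::setNames(sample(c("low", "high"), n, TRUE), cl$sample_id)
  fit <- cox_fit(cl, "os", "hypoxia", hypoxia = lab)
  expect_gt(fit$terms$hr, 0.8)
  expect_lt(fit$terms$hr, 1.25)
  expect_true(fit$terms$ci_low < 1 && fit$terms$ci_high > 1)
})

test_that("degenerate Cox inputs error clearly", {
  cl <- make_clinical(time = 1:6, event = rep(1, 6))
  lab <- stats::setNames(rep("high", 6), cl$sample_id)
  expect_error(cox_fit(cl, "os", "hypoxia", hypoxia = lab), "constant")
  expect_error(cox_fit(cl, "os", "hypoxia"), "labels are required")
  expect_error(cox_fit(cl, "os", "hypoxia",
                       hypoxia = lab[-1]), "P001")
  cl0 <- make_clinical(time = 1:6, event = rep(0, 6))
  lab2 <- stats::setNames(rep(c("low", "high"), 3), cl$sample_id)
  expect_error(cox_fit(cl0, "os", "hypoxia", hypoxia = lab2),
               "no events")
  expect_error(cox_fit(cl, "os", "nonsense"), "unknown covariate")
})

test_that("Unknown covariate strata are dropped from the analysis set", {
  set.seed(541)
  n <- 40
  cl <- make_clinical(time = stats::rexp(n), event = rep(1, n),
                      grade = c(rep("Unknown", 4),
                                sample(1:3, n - 4, TRUE)))
  fit <- cox_fit(cl, "os", "grade")
  expect_equal(fit$n, n - 4)
  # grade I/II is contrasted against the grade III reference
  expect_identical(fit$terms$term, "gradeI/II")
})

test_that("univariable screening keeps prognostic covariates and always
           includes the hypoxia classification", {
  set.seed(547)
  n <- 150
  grade <- sample(1:3, n, TRUE)
  # grade III strongly prognostic; sex is pure noise
  time <- stats::rexp(n, rate = ifelse(grade == 3, 0.8, 0.1))
  cl <- make_clinical(time = time, event = rep(1, n), grade = grade,
                      sex = rep(c("Female", "Male"), length.out = n))
  sel <- select_multivariable(cl, "os", candidates = c("grade", "sex"))
  expect_identical(sel[1], "hypoxia")
  expect_true("grade" %in% sel)
  expect_false("sex" %in% sel)
  # nothing prognostic: only hypoxia survives
  cl2 <- make_clinical(time = 1:20, event = rep(1, 20),
                       sex = rep(c("Female", "Male"), 10))
  expect_identical(select_multivariable(cl2, "os", candidates = "sex"),
                   "hypoxia")
})

test_that("concordance matches exhaustive pair enumeration", {
  # perfect ordering: higher risk always fails earlier
  perf <- c_index(time = 1:10, event = rep(1, 10), risk = 10:1)
  expect_equal(perf$c, 1)
  set.seed(557)
  for (i in 1:10) {
    time <- round(stats::rexp(5), 3)
    event <- stats::rbinom(5, 1, 0.7)
    if (sum(event) == 0) event[1] <- 1
    risk <- sample(1:3, 5, TRUE)  # forces some risk ties
    got <- c_index(time, event, risk)
    expect_equal(got$c, oracle_c_index(time, event, risk),
                 tolerance = 1e-12)
  }
  # invariant under strictly increasing transforms of the score
  time <- stats::rexp(50); event <- stats::rbinom(50, 1, 0.6)
  risk <- stats::runif(50, 0.1, 4)
  expect_equal(c_index(time, event, risk)$c,
               c_index(time, event, risk^3)$c, tolerance = 1e-12)
  # a random score sits near one half
  set.seed(563)
  cs <- replicate(100, c_index(stats::rexp(40), rep(1, 40),
                               stats::rnorm(40))$c)
  expect_lt(abs(mean(cs) - 0.5), 0.02)
  # all censored: no pair is usable
  expect_error(c_index(c(1, 2), c(0, 0), c(2, 1)), "no comparable")
})

test_that("nested likelihood-ratio tests behave at the boundaries and
           detect real signal", {
  set.seed(569)
  n <- 200
  grade <- sample(1:3, n, TRUE)
  lab <- stats::setNames(sample(c("low", "high"), n, TRUE),
                         sprintf("P%03d", 1:n))
  time <- stats::rexp(n, rate = 0.1 * ifelse(grade == 3, 4, 1) *
                        ifelse(lab == "high", 2, 1))
  cl <- make_clinical(time = time, event = rep(1, n), grade = grade)
  full <- cox_fit(cl, "os", c("hypoxia", "grade"), hypoxia = lab)
  red <- cox_fit(cl, "os", "hypoxia", hypoxia = lab)
  lrt <- lrt_nested(full, red)
  expect_equal(lrt$df, 1)
  expect_lt(lrt$p, 0.001)
  expect_gt(lrt$delta_deviance, 0)
  # identical models: zero deviance change, p = 1 by convention
  same <- lrt_nested(full, full)
  expect_equal(same$delta_deviance, 0)
  expect_equal(same$p, 1)
  other <- cox_fit(make_clinical(time = time, event = rep(1, n),
                                 grade = grade),
                   "dfs", "hypoxia", hypoxia = lab)
  expect_error(lrt_nested(full, other), "different endpoints")
  expect_error(lrt_nested(red, full), "not nested")
})

test_that("pOS stratification crosses the class call with the nomogram
           cut-off", {
  time <- c(1, 2, 3, 4, 5, 6, 7, 8)
  event <- c(1, 1, 1, 1, 0, 0, 0, 0)
  cl <- make_clinical(time = time, event = event,
                      pos10 = c(0.5, 0.7, 0.60, 0.2, 0.9, NA, 0.3, 0.8))
  calls <- data.frame(sample_id = cl$sample_id,
                      label = c("low", "low", "high", "high",
                                "low", "low", "high", "high"),
                      stringsAsFactors = FALSE)
  res <- stratify_pos(calls, cl)
  grp <- stats::setNames(res$groups$group, res$groups$sample_id)
  expect_identical(unname(grp["P001"]), "hypoxiaLow_pOSlow")
  expect_identical(unname(grp["P002"]), "hypoxiaLow_pOShigh")
  # pos10 exactly at the cut counts as high predicted survival
  expect_identical(unname(grp["P003"]), "hypoxiaHigh_pOShigh")
  expect_identical(unname(grp["P004"]), "hypoxiaHigh_pOSlow")
  expect_equal(res$n_excluded, 1)
  expect_false("P006" %in% res$groups$sample_id)
  expect_equal(res$logrank$df, length(unique(grp)) - 1)
  expect_true(all(names(res$km_landmark) %in% unique(grp)))
  # all patients in one cell: no comparison is possible
  one <- data.frame(sample_id = cl$sample_id[c(1, 4)],
                    label = c("low", "low"), stringsAsFactors = FALSE)
  expect_error(stratify_pos(one, cl), "2 non-empty")
  bad <- calls; bad$sample_id[1] <- "ZZZ"
  expect_error(stratify_pos(bad, cl), "ZZZ")
})

test_that("the least hypoxic, best-nomogram group has the most
           favourable landmark survival", {
  set.seed(577)
  n <- 400
  label <- sample(c("low", "high"), n, TRUE)
  pos10 <- stats::runif(n)
  risk <- 0.08 * ifelse(label == "high", 3, 1) *
    ifelse(pos10 >= 0.6, 1, 2.5)
  time <- stats::rexp(n, rate = risk)
  cens <- apply_censoring_rule(time, rep(1, n))
  cl <- make_clinical(time = cens$time, event = cens$event, pos10 = pos10)
  calls <- data.frame(sample_id = cl$sample_id, label = label,
                      stringsAsFactors = FALSE)
  res <- stratify_pos(calls, cl)
  km <- res$km_landmark
  expect_identical(names(which.max(km)), "hypoxiaLow_pOShigh")
  expect_identical(names(which.min(km)), "hypoxiaHigh_pOSlow")
  expect_lt(res$logrank$p, 1e-6)
})
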