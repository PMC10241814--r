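make_model <- function(seed = 101, g = 24) {
  set.seed(seed)
  new_model_from <- function(lo, hi) {
    m <- fit_centroids(cbind(a = lo, b = lo, c = hi, d = hi),
                       c("low", "low", "high", "high"))
    m
  }
  lo <- rnorm(g, 8, 1.5)
  hi <- lo + rep_len(c(0.5, 1.5), g)
  names(lo) <- names(hi) <- sprintf("G%02d", 1:g)
  new_model_from(lo, hi)
}

test_that("unshrunken centroids are per-class per-gene means", {
  set.seed(55)
  v <- matrix(rnorm(24 * 8, 8, 1), 24, 8,
              dimnames = list(sprintf("G%02d", 1:24), paste0("s", 1:8)))
  lab <- rep(c("low", "high"), each = 4)
  m <- fit_centroids(v, lab)
  # independent per-gene loop
  for (g in rownames(v)) {
    expect_equal(m$centroid_low[[g]], mean(v[g, lab == "low"]),
                 tolerance = 1e-12)
    expect_equal(m$centroid_high[[g]], mean(v[g, lab == "high"]),
                 tolerance = 1e-12)
  }
  # identical samples within class reproduce those samples
  v2 <- cbind(a = v[, 1], b = v[, 1], c = v[, 2], d = v[, 2])
  m2 <- fit_centroids(v2, c("low", "low", "high", "high"))
  expect_equal(unname(m2$centroid_low), unname(v[, 1]))
  expect_equal(unname(m2$centroid_high), unname(v[, 2]))
})

test_that("degenerate training inputs are rejected", {
  v <- matrix(rnorm(24 * 3), 24, 3,
              dimnames = list(sprintf("G%02d", 1:24), paste0("s", 1:3)))
  expect_error(fit_centroids(v, c("low", "low", "high")), ">= 2")
  expect_error(fit_centroids(v, c("low", "low", "bad")), "labels")
  vconst <- matrix(1, 4, 4, dimnames = list(paste0("g", 1:4),
                                            paste0("s", 1:4)))
  expect_error(fit_centroids(vconst, rep(c("low", "high"), each = 2)),
               "constant centroid")
})

test_that("a sample equal to a centroid is called with distance zero", {
  m <- make_model()
  call_h <- classify(m$centroid_high, m)
  expect_equal(call_h$dist_high, 0)
  expect_identical(call_h$label, "high")
  # identical rank order to the low centroid -> rho = 1, label low
  call_l <- classify(m$centroid_low * 2 + 5, m)
  expect_equal(call_l$dist_low, 0)
  expect_identical(call_l$label, "low")
})

test_that("classification is shift- and monotone-invariant", {
  m <- make_model()
  set.seed(9)
  for (i in 1:10) {
    x <- stats::setNames(rnorm(24, 8, 1.5), m$genes)
    base <- classify(x, m)
    shifted <- classify(x + 7.3, m)
    expect_identical(shifted$label, base$label)
    expect_equal(shifted$dist_low, base$dist_low, tolerance = 1e-12)
    mono <- classify(exp(x / 4), m)  # strictly increasing transform
    expect_identical(mono$label, base$label)
  }
})

test_that("calls match the rank-then-Pearson oracle to 1e-12", {
  m <- make_model()
  set.seed(17)
  for (i in 1:20) {
    x <- stats::setNames(rnorm(24, 8, 2), m$genes)
    got <- classify(x, m)
    want <- oracle_classify(x, m)
    expect_identical(got$label, want$label)
    expect_equal(got$dist_low, want$dist_low, tolerance = 1e-12)
    expect_equal(got$dist_high, want$dist_high, tolerance = 1e-12)
    expect_true(got$dist_low >= 0 && got$dist_low <= 2)
  }
})

test_that("swapping the centroids flips every non-tied label", {
  m <- make_model()
  sw <- m
  sw$centroid_low <- m$centroid_high
  sw$centroid_high <- m$centroid_low
  set.seed(29)
  for (i in 1:10) {
    x <- stats::setNames(rnorm(24, 8, 2), m$genes)
    a <- classify(x, m); b <- classify(x, sw)
    if (a$dist_low != a$dist_high)
      expect_false(a$label == b$label)
  }
})

test_that("missing genes and degenerate profiles error without imputation", {
  m <- make_model()
  x <- m$centroid_low[-1]
  expect_error(classify(x, m), "G01")
  expect_error(classify(stats::setNames(rep(1, 24), m$genes), m),
               "constant")
  x2 <- m$centroid_low
  x2[3] <- NA
  expect_error(classify(x2, m), "G03")
})

test_that("matrix classification reports prevalence", {
  m <- make_model()
  v <- matrix(rep(m$centroid_high, 5), ncol = 5,
              dimnames = list(m$genes, paste0("s", 1:5)))
  res <- classify_matrix(v, m)
  expect_equal(res$prevalence_high, 1)
  empty <- classify_matrix(v[, 0], m)
  expect_equal(nrow(empty$calls), 0)
  expect_true(is.na(empty$prevalence_high))
  # scale tags must agree between model and matrix
  raw <- simulate_cohort(sim_config(seed = 61, n_patients = 3),
                         lanes = FALSE)$expression
  expect_error(classify_matrix(raw, m), "scale")
})

test_that("a separable synthetic cohort recovers truth almost perfectly", {
  tr <- simulate_cohort(sim_config(seed = 71, n_patients = 80,
                                   prevalence_high = 0.5), lanes = FALSE)
  m <- fit_centroids(normalize_counts(tr$expression), tr$true_class)
  te <- simulate_cohort(sim_config(seed = 72, n_patients = 150),
                        lanes = FALSE)
  res <- classify_matrix(normalize_counts(te$expression), m)
  acc <- mean(res$calls$label == true_labels(te)[res$calls$sample_id])
  expect_gte(acc, 0.95)
})

test_that("model files round-trip and refuse broken centroids", {
  m <- make_model()
  path <- withr::local_tempfile(fileext = ".csv")
  write_centroid_model(m, path)
  back <- read_centroid_model(path)
  expect_equal(back$centroid_low, m$centroid_low)
  expect_identical(back$scale, "log2")
  expect_identical(predict(back, m$centroid_high)$label, "high")
})

test_that("biopsy concordance counts tumours with unanimous calls", {
  calls <- data.frame(sample_id = paste0("b", 1:6),
                      label = c("high", "high", "high",
                                "high", "low", "low"))
  tum <- stats::setNames(rep(c("T1", "T2"), each = 3), calls$sample_id)
  res <- biopsy_concordance(calls, tum)
  expect_equal(res$fraction, 0.5)
  expect_true(res$per_tumour[["T1"]])
  expect_false(res$per_tumour[["T2"]])
  # single-biopsy tumours are trivially concordant
  singles <- biopsy_concordance(calls, stats::setNames(paste0("T", 1:6),
                                                       calls$sample_id))
  expect_equal(singles$fraction, 1)
  expect_error(biopsy_concordance(calls, tum[-1]), "not mapped")
})

test_that("zero within-tumour noise yields fully concordant calls", {
  cfg <- sim_config(seed = 81, within_tumour_sd = 0, sigma_tech = 0,
                    libsize_spread = 0)
  co <- simulate_multibiopsy(cfg, n_tumours = 10, total_biopsies = 45,
                             lanes = FALSE)
  m <- synthetic_centroid_model(seed = 82)
  res <- classify_matrix(normalize_counts(co$expression), m)
  conc <- biopsy_concordance(res$calls, co$tumour_id)
  expect_equal(conc$fraction, 1)
})
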