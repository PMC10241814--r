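POS_CONC <- c(A = 128, B = 32, C = 8, D = 2, E = 0.5, F = 0.125)
POS_SCALE <- 30    # expected counts per fM at the top of the titration
N_NEG <- 8
NEG_LAMBDA <- 2    # mean background count of a negative probe

panel_names <- function(config) {
  c(hypoxia_gene_names(config$n_hypoxia_genes),
    control_gene_names(config$n_candidate_controls))
}

panel_roles <- function(config) {
  g <- hypoxia_gene_names(config$n_hypoxia_genes)
  ctl <- control_gene_names(config$n_candidate_controls)
  stats::setNames(c(rep("hypoxia", length(g)),
                    rep("control", config$n_controls),
                    rep("candidate_control",
                        config$n_candidate_controls - config$n_controls)),
                  c(g, ctl))
}

vendor_probe_names <- function() {
  c(sprintf("POS_%s(%s)", names(POS_CONC), format(POS_CONC, trim = TRUE)),
    sprintf("NEG_%s", LETTERS[seq_len(N_NEG)]))
}

# log2 expression (biology + technical noise) for endogenous panel probes;
# class is 0/1 per sample
panel_log2 <- function(config, class) {
  n <- length(class)
  g <- config$n_hypoxia_genes
  k <- config$n_candidate_controls
  hyp <- config$mu_low +
    outer(config$delta, class) +
    matrix(stats::rnorm(g * n, 0, config$sigma_gene), g, n) +
    matrix(stats::rnorm(g * n, 0, config$sigma_tech), g, n)
  ctl <- config$mu_control +
    matrix(stats::rnorm(k * n, 0, config$sigma_control), k, n) +
    matrix(stats::rnorm(k * n, 0, config$sigma_tech), k, n)
  rbind(hyp, ctl)
}

# raw count matrix including vendor positive/negative probes
counts_with_vendor <- function(config, log2_panel, lane_shift) {
  n <- ncol(log2_panel)
  counts <- round(2^(sweep(log2_panel, 2, lane_shift, "+")))
  pos <- t(vapply(POS_CONC, function(conc) {
    round(POS_SCALE * conc *
            2^(lane_shift + stats::rnorm(n, 0, config$sigma_tech)))
  }, numeric(n)))
  if (n == 1) pos <- matrix(pos, ncol = 1)
  neg <- matrix(stats::rpois(N_NEG * n, NEG_LAMBDA), N_NEG, n)
  v <- rbind(counts, pos, neg)
  rownames(v) <- c(rownames(log2_panel), vendor_probe_names())
  v
}

build_expr_matrix <- function(config, v) {
  roles <- c(panel_roles(config),
             stats::setNames(rep(c("positive", "negative"),
                                 c(length(POS_CONC), N_NEG)),
                             vendor_probe_names()))
  expr_matrix(v, roles = roles[rownames(v)], scale = "raw")
}

build_lanes <- function(config, v) {
  role <- c(panel_roles(config),
            stats::setNames(rep(c("positive", "negative"),
                                c(length(POS_CONC), N_NEG)),
                            vendor_probe_names()))[rownames(v)]
  code <- c(hypoxia = "Endogenous", control = "Housekeeping",
            candidate_control = "Housekeeping", positive = "Positive",
            negative = "Negative")[role]
  n <- ncol(v)
  fov_count <- 555L
  fov_counted <- as.integer(round(fov_count * stats::runif(n, 0.9, 1)))
  bd <- stats::runif(n, 0.3, 1.8)
  lapply(seq_len(n), function(i) {
    rcc_lane(lane_id = sprintf("%d", i), sample_id = colnames(v)[i],
             fov_count = fov_count, fov_counted = fov_counted[i],
             binding_density = bd[i],
             probes = data.frame(code_class = unname(code),
                                 name = rownames(v),
                                 accession = paste0("SYN_", rownames(v)),
                                 count = as.integer(v[, i]),
                                 stringsAsFactors = FALSE))
  })
}

# exponential event times under the configured proportional-hazards model,
# censored by loss to follow-up and the administrative horizon
simulate_survival <- function(config, class, grade, size) {
  cm <- config$covariate_model
  n <- length(class)
  dropout <- if (config$dropout_rate > 0)
    stats::rexp(n, config$dropout_rate) else rep(Inf, n)
  cens <- pmin(dropout, config$censor_horizon)
  out <- list()
  for (e in ENDPOINTS) {
    rate <- config$baseline_hazard[[e]] *
      config$hr[[e]]^class *
      cm$hr_grade3^(grade == 3) *
      exp(cm$beta_size * (size - cm$size_center))
    t_event <- stats::rexp(n, rate)
    out[[paste0(e, "_time_years")]] <- pmin(t_event, cens)
    out[[paste0(e, "_event")]] <- as.integer(t_event <= cens)
  }
  out
}

simulate_covariates <- function(config, class) {
  cm <- config$covariate_model
  n <- length(class)
  grade <- integer(n)
  low <- class == 0
  if (any(low))
    grade[low] <- sample.int(3, sum(low), replace = TRUE,
                             prob = cm$grade_probs_low)
  if (any(!low))
    grade[!low] <- sample.int(3, sum(!low), replace = TRUE,
                              prob = cm$grade_probs_high)
  size <- exp(stats::rnorm(n, cm$size_meanlog + cm$size_shift_high * class,
                           cm$size_sdlog))
  age <- pmin(pmax(round(stats::rnorm(n, 60, 14)), 18), 95)
  sex <- sample(c("Male", "Female"), n, replace = TRUE,
                prob = c(0.57, 0.43))
  who_ps <- sample(c("0", "1", "2/3", "Unknown"), n, replace = TRUE,
                   prob = c(0.55, 0.30, 0.10, 0.05))
  depth <- sample(c("Deep", "Superficial"), n, replace = TRUE,
                  prob = c(0.8, 0.2))
  margin <- sample(c("R0", "R1", "Unknown"), n, replace = TRUE,
                   prob = c(0.75, 0.10, 0.15))
  histology <- sample(c("LMS", "MFS", "MLPS", "MPNST", "SS", "UPS",
                        "Other"),
                      n, replace = TRUE,
                      prob = c(0.09, 0.14, 0.12, 0.04, 0.05, 0.33, 0.23))
  # nomogram-predicted 10-year overall survival: worse with grade 3,
  # larger tumours and hypoxia-high class
  lp <- stats::qlogis(0.65) - 0.8 * (grade == 3) -
    0.05 * (size - cm$size_center) - 0.3 * class +
    stats::rnorm(n, 0, 0.4)
  pos10 <- round(stats::plogis(lp), 3)
  caix <- stats::rbinom(n, 1, 0.25 + 0.45 * class)
  hif1a <- stats::rbinom(n, 1, 0.30 + 0.30 * class)
  data.frame(age = age, sex = sex, who_ps = who_ps, size_cm = round(size, 1),
             grade = grade, depth = depth, margin = margin,
             histology = histology, pos10 = pos10,
             caix_pos = caix, hif1a_pos = hif1a,
             stringsAsFactors = FALSE)
}

new_synthetic_cohort <- function(expression, lanes, clinical, true_class,
                                 tumour_id) {
  ids <- em_samples(expression)
  stopifnot(identical(ids, clinical$sample_id),
            identical(ids, names(true_class)),
            identical(ids, names(tumour_id)))
  structure(list(expression = expression, lanes = lanes,
                 clinical = clinical, true_class = true_class,
                 tumour_id = tumour_id),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("synthetic_cohort: %d samples, %d tumours, ",
                     "%d probes, %.0f%% hypoxia-high (truth)\n"),
              ncol(x$expression$values), length(unique(x$tumour_id)),
              nrow(x$expression$values),
              100 * mean(x$true_class == "high")))
  invisible(x)
}

#' Simulate a clinical validation cohort
#'
#' Draws a hidden hypoxia class per patient, class-conditional log-normal
#' expression of the signature genes (controls unshifted), per-lane count
#' scaling, vendor positive/negative control probes, class-associated
#' clinical covariates (hypoxia-high tumours tend to be larger and of
#' higher grade), and exponential proportional-hazards survival per
#' endpoint with loss to follow-up and administrative censoring at the
#' configured horizon.
#'
#' @param config a [sim_config()].
#' @param lanes if `TRUE` (default) also build per-sample [rcc_lane()]
#'   records; skip for speed in large replicate studies.
#' @param cohort_label cohort name written into the clinical table.
#' @return an object of class `synthetic_cohort` with elements
#'   `expression` (raw [expr_matrix()] including vendor control probes),
#'   `lanes`, `clinical`, `true_class` (named factor low/high) and
#'   `tumour_id`.
#' @export
simulate_cohort <- function(config, lanes = TRUE,
                            cohort_label = "synthetic") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  ids <- sprintf("S%03d", seq_len(n))
  class <- stats::rbinom(n, 1, config$prevalence_high)
  cov <- simulate_covariates(config, class)
  log2e <- panel_log2(config, class)
  rownames(log2e) <- panel_names(config)
  colnames(log2e) <- ids
  shift <- stats::rnorm(n, 0, config$libsize_spread)
  v <- counts_with_vendor(config, log2e, shift)
  colnames(v) <- ids
  expression <- build_expr_matrix(config, v)
  surv <- simulate_survival(config, class, cov$grade, cov$size_cm)
  clinical <- cbind(data.frame(sample_id = ids, tumour_id = ids,
                               cohort = cohort_label,
                               stringsAsFactors = FALSE),
                    cov, as.data.frame(surv))
  validate_clinical(clinical)
  true_class <- stats::setNames(factor(c("low", "high")[class + 1],
                                       levels = c("low", "high")), ids)
  lane_list <- if (lanes) build_lanes(config, v) else list()
  new_synthetic_cohort(expression, lane_list, clinical, true_class,
                       stats::setNames(ids, ids))
}

#' Simulate an in-vitro oxygen titration experiment
#'
#' Cell-line replicates cultured at a decreasing series of oxygen
#' fractions. The expected log2 expression of every hypoxia gene
#' increases strictly as oxygen falls (scaled by each gene's `delta`);
#' control genes stay flat.
#'
#' @param config a [sim_config()].
#' @param levels oxygen percentages, strictly decreasing
#'   (default `c(21, 1, 0.2)`).
#' @param replicates biological replicates per level (>= 2).
#' @return a log2-scale [expr_matrix()]; the oxygen level of each sample
#'   is attached as the `"oxygen"` attribute (named numeric vector).
#' @export
simulate_oxygen_series <- function(config, levels = c(21, 1, 0.2),
                                   replicates = 3) {
  stopifnot(inherits(config, "sim_config"))
  if (length(levels) < 2)
    stop("at least 2 oxygen levels are required")
  if (any(diff(levels) >= 0))
    stop("oxygen levels must be strictly decreasing")
  if (replicates < 2)
    stop("at least 2 replicates per level are required")
  set.seed(config$seed)
  dose <- log(levels[1] / levels) / log(levels[1] / min(levels))
  dose_s <- rep(dose, each = replicates)
  ids <- sprintf("O%s_r%d", rep(gsub("\\.", "p", format(levels,
                                                        trim = TRUE)),
                                each = replicates),
                 rep(seq_len(replicates), length(levels)))
  g <- config$n_hypoxia_genes
  k <- config$n_candidate_controls
  n <- length(ids)
  hyp <- config$mu_low + outer(config$delta, dose_s) +
    matrix(stats::rnorm(g * n, 0, config$sigma_tech), g, n)
  ctl <- config$mu_control +
    matrix(stats::rnorm(k * n, 0, config$sigma_tech), k, n)
  v <- rbind(hyp, ctl)
  dimnames(v) <- list(panel_names(config), ids)
  em <- expr_matrix(v, roles = panel_roles(config), scale = "log2")
  attr(em, "oxygen") <- stats::setNames(rep(levels, each = replicates), ids)
  em
}

# draw per-tumour biopsy counts within the configured range, optionally
# constrained to a fixed total
draw_biopsy_counts <- function(range, n_tumours, total) {
  lo <- range[1]; hi <- range[2]
  b <- sample(seq(lo, hi), n_tumours, replace = TRUE)
  if (is.null(total)) return(b)
  if (total < lo * n_tumours || total > hi * n_tumours)
    stop("total biopsies ", total, " not attainable with ", n_tumours,
         " tumours of ", lo, "-", hi, " biopsies")
  while (sum(b) != total) {
    i <- sample.int(n_tumours, 1)
    if (sum(b) > total && b[i] > lo) b[i] <- b[i] - 1L
    if (sum(b) < total && b[i] < hi) b[i] <- b[i] + 1L
  }
  b
}

#' Simulate a multi-biopsy intra-tumour heterogeneity cohort
#'
#' Every biopsy of a tumour shares the tumour's hidden hypoxia class and
#' its tumour-level expression profile, plus an independent
#' `within_tumour_sd` log2 deviation per biopsy.
#'
#' @param config a [sim_config()].
#' @param n_tumours number of tumours (>= 1).
#' @param total_biopsies optional fixed total number of biopsies; drawn
#'   per tumour within `config$biopsies_per_tumour` otherwise.
#' @param lanes build [rcc_lane()] records (default `TRUE`).
#' @return a `synthetic_cohort` whose `tumour_id` groups biopsies.
#' @export
simulate_multibiopsy <- function(config, n_tumours = 10,
                                 total_biopsies = NULL, lanes = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (n_tumours < 1) stop("n_tumours must be >= 1")
  set.seed(config$seed)
  nb <- draw_biopsy_counts(config$biopsies_per_tumour, n_tumours,
                           total_biopsies)
  t_class <- stats::rbinom(n_tumours, 1, config$prevalence_high)
  t_ids <- sprintf("T%02d", seq_len(n_tumours))
  tum_of <- rep(seq_len(n_tumours), nb)
  ids <- sprintf("%s_B%d", t_ids[tum_of],
                 unlist(lapply(nb, seq_len), use.names = FALSE))
  n <- length(ids)
  # tumour-level biology, then per-biopsy heterogeneity on all panel genes
  tum_log2 <- panel_log2(config, t_class)
  log2e <- tum_log2[, tum_of, drop = FALSE] +
    matrix(stats::rnorm(nrow(tum_log2) * n, 0, config$within_tumour_sd),
           nrow(tum_log2), n)
  rownames(log2e) <- panel_names(config)
  colnames(log2e) <- ids
  shift <- stats::rnorm(n, 0, config$libsize_spread)
  v <- counts_with_vendor(config, log2e, shift)
  colnames(v) <- ids
  expression <- build_expr_matrix(config, v)

  t_cov <- simulate_covariates(config, t_class)
  t_surv <- simulate_survival(config, t_class, t_cov$grade, t_cov$size_cm)
  clinical <- cbind(data.frame(sample_id = ids, tumour_id = t_ids[tum_of],
                               cohort = "heterogeneity",
                               stringsAsFactors = FALSE),
                    t_cov[tum_of, , drop = FALSE],
                    as.data.frame(t_surv)[tum_of, , drop = FALSE])
  rownames(clinical) <- NULL
  validate_clinical(clinical)
  class_s <- t_class[tum_of]
  true_class <- stats::setNames(factor(c("low", "high")[class_s + 1],
                                       levels = c("low", "high")), ids)
  lane_list <- if (lanes) build_lanes(config, v) else list()
  new_synthetic_cohort(expression, lane_list, clinical, true_class,
                       stats::setNames(t_ids[tum_of], ids))
}

#' Write a cohort's lanes as RCC fixture files
#'
#' One file per lane, named `<sample_id>.RCC`; the written files
#' round-trip through [read_rcc()] / [assemble_matrix()] to the cohort's
#' count matrix.
#'
#' @param cohort a `synthetic_cohort` built with `lanes = TRUE`.
#' @param dir output directory (created if missing).
#' @return character vector of file paths, invisibly.
#' @export
write_rcc_fixtures <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  ids <- vapply(cohort$lanes, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids))
    stop("duplicate sample IDs in cohort: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory: ", dir)
  paths <- character(0)
  for (ln in cohort$lanes) {
    p <- file.path(dir, paste0(ln$sample_id, ".RCC"))
    write_rcc(ln, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
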