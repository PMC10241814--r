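#' Configuration for the synthetic cohort generator
#'
#' Bundles every parameter of the generative model: class prevalence,
#' per-gene log2 expression means and hypoxia effect sizes, biological and
#' technical noise, lane scaling, per-endpoint proportional-hazards
#' survival with administrative censoring, class-associated clinical
#' covariates, and the multi-biopsy design. The defaults emulate a
#' single-centre extremity soft-tissue sarcoma cohort: n = 126 with a
#' hypoxia-high mixing fraction of 53/126, a uniform 1 log2 upregulation
#' of the 24 signature genes, and 5-year administrative censoring.
#'
#' @param seed integer seed; the same seed and config give bit-identical
#'   output.
#' @param n_patients number of patients (one lane/sample each).
#' @param prevalence_high fraction of patients whose tumour is
#'   hypoxia-high, in `[0, 1]`.
#' @param n_hypoxia_genes number of signature genes (default 24,
#'   named `G01..`).
#' @param n_controls number of deployed endogenous control genes
#'   (default 5).
#' @param n_candidate_controls candidate control genes screened
#'   (default 7, named `C1..`); the first `n_controls` are the stable
#'   deployed set, the remainder are noisier.
#' @param mu_low per-gene mean log2 expression of hypoxia genes in
#'   hypoxia-low tumours; recycled to `n_hypoxia_genes`. The default spans
#'   6-12 log2 units, matching the dynamic range of a targeted panel.
#' @param delta per-gene log2 upregulation in hypoxia-high tumours
#'   (all >= 0); recycled. The default alternates 0.5 and 1.5 for a
#'   panel mean of 1 log2: per-gene variation in the effect is what
#'   reorders a hypoxia-high profile, and a rank-based classifier can
#'   only see reordering — a perfectly uniform shift is rank-invisible.
#' @param sigma_gene per-gene biological SD on the log2 scale; recycled.
#' @param sigma_tech technical replicate SD (log2).
#' @param libsize_spread SD (log2) of the per-lane scaling shift applied
#'   to every probe of a lane.
#' @param mu_control mean log2 expression of the candidate control genes
#'   (controls sit slightly above the signature genes); recycled to
#'   `n_candidate_controls`.
#' @param sigma_control per-candidate biological SD; the default keeps the
#'   deployed controls tight (0.10) and the surplus candidates loose
#'   (0.45) so stability screening has something to reject.
#' @param hr named vector of true hazard ratios (hypoxia-high vs low) per
#'   endpoint `lrfs`, `mfs`, `dfs`, `os`; all > 0.
#' @param baseline_hazard named vector of hypoxia-low baseline event rates
#'   per year for the same endpoints.
#' @param censor_horizon administrative censoring horizon in years
#'   (default 5).
#' @param dropout_rate exponential loss-to-follow-up rate per year
#'   (default 0.05), applied before the administrative horizon.
#' @param covariate_model list linking grade and size to hypoxia class and
#'   to the hazard: `grade_probs_low`/`grade_probs_high` (length-3
#'   probabilities of grade 1/2/3 by class; the high-class default shifts
#'   mass to grade 3), `size_meanlog`, `size_shift_high` (log-scale
#'   increment of tumour size in hypoxia-high), `size_sdlog`,
#'   `size_center` (cm, centring for the hazard), `hr_grade3`
#'   (hazard ratio of grade 3 vs 1/2) and `beta_size` (log-hazard per cm).
#'   Set `hr_grade3 = 1` and `beta_size = 0` for survival that depends on
#'   hypoxia class only.
#' @param biopsies_per_tumour length-2 integer range of biopsies per
#'   tumour for the multi-biopsy design (within 3-8).
#' @param within_tumour_sd log2 SD across biopsies of one tumour.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_patients = 126L,
                       prevalence_high = 53 / 126,
                       n_hypoxia_genes = 24L,
                       n_controls = 5L,
                       n_candidate_controls = 7L,
                       mu_low = seq(6, 12, length.out = n_hypoxia_genes),
                       delta = rep_len(c(0.5, 1.5), n_hypoxia_genes),
                       sigma_gene = 0.3,
                       sigma_tech = 0.05,
                       libsize_spread = 0.2,
                       mu_control = seq(11, 13,
                                        length.out = n_candidate_controls),
                       sigma_control = c(rep(0.10, n_controls),
                                         rep(0.45, n_candidate_controls -
                                                     n_controls)),
                       hr = c(lrfs = 2.17, mfs = 1.92, dfs = 2.00,
                              os = 2.38),
                       baseline_hazard = c(lrfs = 0.016, mfs = 0.055,
                                           dfs = 0.065, os = 0.075),
                       censor_horizon = 5,
                       dropout_rate = 0.05,
                       covariate_model = list(),
                       biopsies_per_tumour = c(3L, 8L),
                       within_tumour_sd = 0.15) {
  cm_default <- list(grade_probs_low = c(0.15, 0.35, 0.50),
                     grade_probs_high = c(0.03, 0.27, 0.70),
                     size_meanlog = log(8), size_shift_high = 0.25,
                     size_sdlog = 0.5, size_center = 9,
                     hr_grade3 = 2.0, beta_size = 0.03)
  bad_cm <- setdiff(names(covariate_model), names(cm_default))
  if (length(bad_cm))
    stop("unknown covariate_model parameter(s): ",
         paste(bad_cm, collapse = ", "))
  cm <- utils::modifyList(cm_default, covariate_model)

  cfg <- list(seed = as.integer(seed), n_patients = as.integer(n_patients),
              prevalence_high = prevalence_high,
              n_hypoxia_genes = as.integer(n_hypoxia_genes),
              n_controls = as.integer(n_controls),
              n_candidate_controls = as.integer(n_candidate_controls),
              mu_low = rep_len(mu_low, n_hypoxia_genes),
              delta = rep_len(delta, n_hypoxia_genes),
              sigma_gene = rep_len(sigma_gene, n_hypoxia_genes),
              sigma_tech = sigma_tech, libsize_spread = libsize_spread,
              mu_control = rep_len(mu_control, n_candidate_controls),
              sigma_control = rep_len(sigma_control, n_candidate_controls),
              hr = hr, baseline_hazard = baseline_hazard,
              censor_horizon = censor_horizon, dropout_rate = dropout_rate,
              covariate_model = cm,
              biopsies_per_tumour = as.integer(biopsies_per_tumour),
              within_tumour_sd = within_tumour_sd)

  num <- cfg[c("prevalence_high", "mu_low", "delta", "sigma_gene",
               "sigma_tech", "libsize_spread", "mu_control",
               "sigma_control", "hr", "baseline_hazard", "censor_horizon",
               "dropout_rate", "within_tumour_sd")]
  for (nm in names(num))
    if (any(!is.finite(num[[nm]])))
      stop("non-finite value in config parameter '", nm, "'")
  for (nm in c("hr_grade3", "beta_size", "size_meanlog", "size_shift_high",
               "size_sdlog", "size_center"))
    if (!is.finite(cm[[nm]]))
      stop("non-finite value in config parameter 'covariate_model$",
           nm, "'")
  if (cfg$prevalence_high < 0 || cfg$prevalence_high > 1)
    stop("prevalence_high must lie in [0, 1]")
  if (any(cfg$delta < 0)) stop("delta must be >= 0")
  if (any(c(cfg$sigma_gene, cfg$sigma_tech, cfg$libsize_spread,
            cfg$sigma_control, cfg$within_tumour_sd) < 0))
    stop("all SD parameters must be >= 0")
  if (any(cfg$hr <= 0)) stop("hr values must be > 0")
  if (any(cfg$baseline_hazard < 0)) stop("baseline_hazard must be >= 0")
  if (cfg$censor_horizon <= 0) stop("censor_horizon must be > 0")
  if (cfg$n_controls > cfg$n_candidate_controls)
    stop("n_controls cannot exceed n_candidate_controls")
  if (length(cfg$biopsies_per_tumour) != 2 ||
      cfg$biopsies_per_tumour[1] < 3 || cfg$biopsies_per_tumour[2] > 8 ||
      cfg$biopsies_per_tumour[1] > cfg$biopsies_per_tumour[2])
    stop("biopsies_per_tumour must be an ordered range within 3-8")
  setdiffs <- setdiff(ENDPOINTS, names(cfg$hr))
  if (length(setdiffs))
    stop("hr must name every endpoint: missing ",
         paste(setdiffs, collapse = ", "))
  if (length(setdiff(ENDPOINTS, names(cfg$baseline_hazard))))
    stop("baseline_hazard must name every endpoint")
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: n=%d, prevalence(high)=%.3f, ",
                     "%d signature genes, %d/%d controls\n"),
              x$n_patients, x$prevalence_high, x$n_hypoxia_genes,
              x$n_controls, x$n_candidate_controls))
  cat(sprintf("  delta (log2): %s; sigma_gene: %s\n",
              paste(format(range(x$delta)), collapse = "-"),
              paste(format(range(x$sigma_gene)), collapse = "-")))
  cat(sprintf("  HR: %s; horizon %g y\n",
              paste(sprintf("%s=%.2f", names(x$hr), x$hr), collapse = " "),
              x$censor_horizon))
  invisible(x)
}

hypoxia_gene_names <- function(n) sprintf("G%02d", seq_len(n))
control_gene_names <- function(n) sprintf("C%d", seq_len(n))
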