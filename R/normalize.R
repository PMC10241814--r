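#' Lane quality-control thresholds
#'
#' Defaults follow published vendor guidance for nCounter gene-expression
#' lanes: at least 75% of fields of view imaged, binding density within
#' 0.05-2.25 spots/um^2, positive-control log-log linearity R^2 >= 0.95,
#' limit of detection at the negative mean plus 2 SD, and normalization
#' factors within 0.3-3 (positive) and 0.1-10 (content). All values are
#' configurable; none is hard-coded downstream.
#'
#' @param fov_min minimum imaged fraction of fields of view.
#' @param bd_range binding-density acceptance range (spots/um^2).
#' @param poslin_min_r2 minimum R^2 of log2(count+1) against log2(fM) over
#'   the positive titration.
#' @param lod_sd_mult SD multiplier for the limit-of-detection check.
#' @param posfactor_range acceptance range for the positive factor.
#' @param contentfactor_range acceptance range for the content factor.
#' @return an object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(fov_min = 0.75, bd_range = c(0.05, 2.25),
                          poslin_min_r2 = 0.95, lod_sd_mult = 2,
                          posfactor_range = c(0.3, 3),
                          contentfactor_range = c(0.1, 10)) {
  stopifnot(bd_range[1] < bd_range[2],
            posfactor_range[1] < posfactor_range[2],
            contentfactor_range[1] < contentfactor_range[2],
            lod_sd_mult >= 0)
  structure(list(fov_min = fov_min, bd_range = bd_range,
                 poslin_min_r2 = poslin_min_r2, lod_sd_mult = lod_sd_mult,
                 posfactor_range = posfactor_range,
                 contentfactor_range = contentfactor_range),
            class = "qc_thresholds")
}

#' Quality-control checks for a single lane
#'
#' Flags imaging (FOV fraction, binding density), positive-control
#' linearity (R^2 of log2(count+1) against log2 input fM) and the limit
#' of detection (the 0.5 fM positive probe must exceed the negative-probe
#' mean plus `lod_sd_mult` SD). Normalization-factor flags are filled in
#' by [normalize_counts()], which sees all lanes at once.
#'
#' @param lane an [rcc_lane()].
#' @param thr a [qc_thresholds()].
#' @return one-row data.frame of class `qc_report` with a measured value
#'   and pass flag per check, plus `overall` (conjunction of the
#'   single-lane flags).
#' @export
qc_lane <- function(lane, thr = qc_thresholds()) {
  stopifnot(inherits(lane, "rcc_lane"), inherits(thr, "qc_thresholds"))
  pos <- lane$probes[lane$probes$code_class == "Positive", ]
  neg <- lane$probes[lane$probes$code_class == "Negative", ]
  if (nrow(pos) < 4 || nrow(neg) < 1)
    stop("lane ", lane$lane_id,
         ": need >= 4 positive and >= 1 negative probes for QC")
  conc <- pos_concentration(pos$name)
  if (all(is.na(conc)))
    stop("lane ", lane$lane_id,
         ": no parseable positive-control concentrations")
  ok <- !is.na(conc)
  lpos <- log2(pos$count[ok] + 1)
  r2 <- if (stats::sd(lpos) == 0) 0 else
    stats::cor(lpos, log2(conc[ok]))^2
  fov_frac <- lane$fov_counted / lane$fov_count
  lod_probe <- pos$count[ok][which.min(abs(conc[ok] - 0.5))]
  lod_cut <- mean(neg$count) + thr$lod_sd_mult * stats::sd(neg$count)
  if (is.na(lod_cut)) lod_cut <- mean(neg$count)  # single negative probe
  flags <- c(fov = fov_frac >= thr$fov_min,
             binding_density = lane$binding_density >= thr$bd_range[1] &&
               lane$binding_density <= thr$bd_range[2],
             pos_linearity = r2 >= thr$poslin_min_r2,
             lod = lod_probe > lod_cut)
  out <- data.frame(lane_id = lane$lane_id, sample_id = lane$sample_id,
                    fov = fov_frac, fov_pass = flags[["fov"]],
                    binding_density = lane$binding_density,
                    binding_density_pass = flags[["binding_density"]],
                    pos_linearity = r2,
                    pos_linearity_pass = flags[["pos_linearity"]],
                    lod = lod_probe, lod_cut = lod_cut,
                    lod_pass = flags[["lod"]],
                    pos_factor = NA_real_, pos_factor_pass = NA,
                    content_factor = NA_real_, content_factor_pass = NA,
                    overall = all(flags),
                    stringsAsFactors = FALSE)
  class(out) <- c("qc_report", "data.frame")
  out
}

#' QC an entire lane set
#'
#' @param lanes list of [rcc_lane()] objects.
#' @param thr a [qc_thresholds()].
#' @return a `qc_report` data.frame, one row per lane.
#' @export
qc_lanes <- function(lanes, thr = qc_thresholds()) {
  out <- do.call(rbind, lapply(lanes, qc_lane, thr = thr))
  class(out) <- c("qc_report", "data.frame")
  out
}

geo_mean <- function(x) exp(mean(log(x)))

#' Normalize raw counts to a log2 expression matrix
#'
#' The re-specified nSolver-style pipeline:
#' \enumerate{
#'   \item \emph{Positive-control normalization}: each lane's factor is
#'     the across-lane geometric mean of positive-probe geometric means
#'     divided by that lane's own geometric mean, applied
#'     multiplicatively to all probes.
#'   \item \emph{Background thresholding}: per lane, values below the
#'     mean + `lod_sd_mult` SD of that lane's (scaled) negative probes
#'     are raised to that threshold (never subtracted, preserving
#'     positivity for the log step).
#'   \item \emph{Content normalization}: the same geometric-mean factor
#'     construction over the endogenous `controls` genes.
#'   \item \code{log2(x + 1)}.
#' }
#' Geometric means are computed on value + 1 so zero counts are
#' tolerated. Factors are recorded in the `"norm_factors"` attribute and
#' flagged against the configured acceptance ranges.
#'
#' @param matrix a raw [expr_matrix()] whose roles identify `positive`
#'   and `negative` vendor probes.
#' @param lanes optional list of [rcc_lane()]; when given, every lane
#'   must pass [qc_lane()] unless `override = TRUE`.
#' @param controls endogenous control genes for content normalization;
#'   defaults to the genes with role `"control"`.
#' @param thr a [qc_thresholds()].
#' @param override skip the lane QC gate.
#' @return a log2 [expr_matrix()] containing only endogenous and control
#'   genes, with attribute `"norm_factors"` (data.frame: sample,
#'   pos_factor, content_factor, pass flags).
#' @export
normalize_counts <- function(matrix, lanes = NULL, controls = NULL,
                             thr = qc_thresholds(), override = FALSE) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (matrix$scale != "raw")
    stop("normalize_counts expects a raw count matrix, got scale '",
         matrix$scale, "'")
  if (!is.null(lanes) && !override) {
    rep <- qc_lanes(lanes, thr)
    if (!all(rep$overall))
      stop("lane QC failure for lane(s): ",
           paste(rep$lane_id[!rep$overall], collapse = ", "),
           " (use override = TRUE to force)")
  }
  if (is.null(controls)) controls <- em_genes(matrix, "control")
  miss <- setdiff(controls, em_genes(matrix))
  if (length(miss))
    stop("control gene(s) not in matrix: ", paste(miss, collapse = ", "))
  if (length(controls) < 1) stop("at least one control gene is required")
  pos_genes <- em_genes(matrix, "positive")
  neg_genes <- em_genes(matrix, "negative")
  if (length(pos_genes) < 1)
    stop("matrix has no positive-control probes")
  keep <- setdiff(em_genes(matrix), c(pos_genes, neg_genes))

  v <- matrix$values
  ns <- colnames(v)
  # (1) positive factor
  for (s in ns)
    if (all(v[pos_genes, s] == 0))
      stop("all positive-control counts are zero in lane '", s, "'")
  pos_gm <- apply(v[pos_genes, , drop = FALSE] + 1, 2, geo_mean)
  pf <- geo_mean(pos_gm) / pos_gm
  v <- sweep(v, 2, pf, "*")
  # (2) background threshold-raise from the lane's scaled negatives
  if (length(neg_genes)) {
    for (s in ns) {
      nv <- v[neg_genes, s]
      cut <- mean(nv) + thr$lod_sd_mult * stats::sd(nv)
      if (is.na(cut)) cut <- mean(nv)
      lo <- v[keep, s] < cut
      v[keep, s][lo] <- cut
    }
  }
  # (3) content factor from endogenous controls
  for (s in ns)
    if (all(matrix$values[controls, s] == 0))
      stop("all control-gene counts are zero in lane '", s, "'")
  ctl_gm <- apply(v[controls, , drop = FALSE] + 1, 2, geo_mean)
  cf <- geo_mean(ctl_gm) / ctl_gm
  v <- sweep(v, 2, cf, "*")
  # (4) log2
  out <- expr_matrix(log2(v[keep, , drop = FALSE] + 1),
                     roles = matrix$roles[keep], scale = "log2")
  attr(out, "norm_factors") <- data.frame(
    sample_id = ns, pos_factor = unname(pf), content_factor = unname(cf),
    pos_factor_pass = pf >= thr$posfactor_range[1] &
      pf <= thr$posfactor_range[2],
    content_factor_pass = cf >= thr$contentfactor_range[1] &
      cf <= thr$contentfactor_range[2],
    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Spearman correlation between two replicate expression profiles
#'
#' Assay reproducibility metric: rank correlation of the signature-gene
#' profile of two repeats of the same sample (ties get average ranks).
#'
#' @param profile_a,profile_b numeric vectors over the same genes in the
#'   same order (length >= 3); if both are named, names must match.
#' @return Spearman's rho in `[-1, 1]`.
#' @export
replicate_correlation <- function(profile_a, profile_b) {
  if (length(profile_a) != length(profile_b))
    stop("profiles must have equal length")
  if (length(profile_a) < 3)
    stop("profiles must have length >= 3")
  if (!is.null(names(profile_a)) && !is.null(names(profile_b)) &&
      !identical(names(profile_a), names(profile_b)))
    stop("profile gene names disagree")
  if (stats::sd(profile_a) == 0 || stats::sd(profile_b) == 0)
    stop("correlation undefined for a constant profile")
  stats::cor(profile_a, profile_b, method = "spearman")
}
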