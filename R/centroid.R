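#' Fit unshrunken class centroids for the hypoxia signature
#'
#' The deployed classifier uses PAM-style class centroids with zero
#' shrinkage, which reduce to the per-class, per-gene mean log2
#' expression. Prediction (see [predict.centroid_model()]) assigns each
#' sample to the centroid at the shortest Spearman distance
#' (1 - Spearman's rho) after median-centring the sample's profile.
#'
#' @param matrix a log2 [expr_matrix()] (genes with role `"hypoxia"` are
#'   used) or a plain genes x samples log2 matrix.
#' @param labels per-sample class, values `"low"`/`"high"` (factor or
#'   character), aligned with the matrix columns; both classes need at
#'   least 2 samples.
#' @param training_meta optional list of provenance notes stored in the
#'   model (e.g. cohort name).
#' @return an object of class `centroid_model` with elements `genes`,
#'   `centroid_low`, `centroid_high`, `scale` and `training_meta`.
#' @export
fit_centroids <- function(matrix, labels, training_meta = list()) {
  if (inherits(matrix, "expr_matrix")) {
    if (matrix$scale != "log2")
      stop("fit_centroids expects log2 expression, got scale '",
           matrix$scale, "'")
    v <- matrix$values[em_genes(matrix, "hypoxia"), , drop = FALSE]
  } else {
    v <- as.matrix(matrix)
  }
  labels <- as.character(labels)
  if (length(labels) != ncol(v))
    stop("labels must align with the matrix columns")
  bad <- setdiff(unique(labels), c("low", "high"))
  if (length(bad))
    stop("labels must be 'low'/'high'; found: ",
         paste(bad, collapse = ", "))
  n_low <- sum(labels == "low"); n_high <- sum(labels == "high")
  if (n_low < 2 || n_high < 2)
    stop("each class needs >= 2 training samples (low: ", n_low,
         ", high: ", n_high, ")")
  c_low <- rowMeans(v[, labels == "low", drop = FALSE])
  c_high <- rowMeans(v[, labels == "high", drop = FALSE])
  new_centroid_model(rownames(v), c_low, c_high, scale = "log2",
                     training_meta = utils::modifyList(
                       list(n_low = n_low, n_high = n_high),
                       training_meta))
}

new_centroid_model <- function(genes, centroid_low, centroid_high,
                               scale = "log2", training_meta = list()) {
  if (any(!is.finite(centroid_low)) || any(!is.finite(centroid_high)))
    stop("centroids must be finite")
  if (stats::sd(centroid_low) == 0 || stats::sd(centroid_high) == 0)
    stop("a constant centroid has no rank order; cannot build model")
  structure(list(genes = genes,
                 centroid_low = stats::setNames(unname(centroid_low),
                                                genes),
                 centroid_high = stats::setNames(unname(centroid_high),
                                                 genes),
                 scale = scale, training_meta = training_meta),
            class = "centroid_model")
}

#' @export
print.centroid_model <- function(x, ...) {
  cat(sprintf("centroid_model: %d-gene hypoxia signature (scale: %s)\n",
              length(x$genes), x$scale))
  tm <- x$training_meta
  if (!is.null(tm$n_low))
    cat(sprintf("  trained on %d low / %d high samples\n",
                tm$n_low, tm$n_high))
  if (!is.null(tm$cohort)) cat("  cohort:", tm$cohort, "\n")
  invisible(x)
}

#' @export
coef.centroid_model <- function(object, ...) {
  cbind(low = object$centroid_low, high = object$centroid_high)
}

#' Classify one sample profile against the centroids
#'
#' The sample is median-centred over the panel (its own median is
#' subtracted from every gene; inert under Spearman correlation but kept
#' for fidelity to the deployed rule), then compared to each centroid by
#' the Spearman distance `d = 1 - rho` (average ranks on ties). The call
#' is the nearer centroid; an exact tie is called low, the conservative
#' choice for a poor-prognosis marker.
#'
#' @param sample named numeric vector covering the model's genes
#'   (log2 scale), non-constant.
#' @param model a `centroid_model`.
#' @param sample_id identifier copied into the call.
#' @return one-row data.frame (class call): `sample_id`, `label`,
#'   `dist_low`, `dist_high`, `margin = dist_low - dist_high`.
#' @export
classify <- function(sample, model, sample_id = "sample") {
  stopifnot(inherits(model, "centroid_model"))
  if (is.null(names(sample)))
    stop("sample vector must be named by gene")
  miss <- setdiff(model$genes, names(sample))
  if (length(miss))
    stop("sample is missing model gene(s): ",
         paste(miss, collapse = ", "))
  x <- sample[model$genes]
  if (any(!is.finite(x)))
    stop("sample has missing/non-finite values for gene(s): ",
         paste(model$genes[!is.finite(x)], collapse = ", "),
         " (no imputation is performed)")
  if (stats::sd(x) == 0)
    stop("constant sample profile: Spearman distance undefined")
  x <- x - stats::median(x)
  d_low <- 1 - stats::cor(x, model$centroid_low, method = "spearman")
  d_high <- 1 - stats::cor(x, model$centroid_high, method = "spearman")
  data.frame(sample_id = sample_id,
             label = if (d_high < d_low) "high" else "low",
             dist_low = d_low, dist_high = d_high,
             margin = d_low - d_high, stringsAsFactors = FALSE)
}

#' Classify every sample of a matrix
#'
#' @param matrix a log2 [expr_matrix()] (hypoxia-role genes are used) or
#'   plain log2 matrix covering the model genes.
#' @param model a `centroid_model`.
#' @return list with `calls` (data.frame of per-sample class calls) and
#'   `prevalence_high` (fraction of samples called high; `NA` for an
#'   empty matrix).
#' @export
classify_matrix <- function(matrix, model) {
  if (inherits(matrix, "expr_matrix")) {
    if (matrix$scale != model$scale)
      stop("matrix scale '", matrix$scale,
           "' does not match model scale '", model$scale, "'")
    v <- matrix$values
  } else {
    v <- as.matrix(matrix)
  }
  if (ncol(v) == 0)
    return(list(calls = data.frame(sample_id = character(0),
                                   label = character(0),
                                   dist_low = numeric(0),
                                   dist_high = numeric(0),
                                   margin = numeric(0)),
                prevalence_high = NA_real_))
  calls <- do.call(rbind, lapply(colnames(v), function(s)
    classify(v[, s], model, sample_id = s)))
  list(calls = calls, prevalence_high = mean(calls$label == "high"))
}

#' @export
predict.centroid_model <- function(object, newdata, ...) {
  if (is.numeric(newdata) && is.null(dim(newdata)))
    return(classify(newdata, object))
  classify_matrix(newdata, object)$calls
}

#' Per-tumour concordance of multi-biopsy class calls
#'
#' A tumour is concordant when all of its biopsies receive the same
#' class label.
#'
#' @param calls data.frame of class calls (needs `sample_id`, `label`).
#' @param tumour_id named vector mapping every sample_id to its tumour.
#' @return list with `per_tumour` (named logical) and `fraction`
#'   (concordant tumours / tumours).
#' @export
biopsy_concordance <- function(calls, tumour_id) {
  miss <- setdiff(calls$sample_id, names(tumour_id))
  if (length(miss))
    stop("sample(s) not mapped to a tumour: ",
         paste(miss, collapse = ", "))
  tum <- tumour_id[calls$sample_id]
  per <- tapply(calls$label, tum, function(l) length(unique(l)) == 1)
  per <- stats::setNames(as.logical(per), names(per))
  list(per_tumour = per, fraction = mean(per))
}

#' Write / read a centroid model file
#'
#' CSV with header comment lines recording the scale tag and panel size,
#' then columns `gene`, `centroid_low`, `centroid_high`. Reading refuses
#' nothing about provenance: any panel on the recorded scale can be
#' dropped in, so externally trained centroids can replace the shipped
#' synthetic ones.
#'
#' @param model a `centroid_model`.
#' @param path file path.
#' @export
write_centroid_model <- function(model, path) {
  stopifnot(inherits(model, "centroid_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# scale=%s", model$scale),
               sprintf("# n_genes=%d", length(model$genes))), con)
  utils::write.csv(data.frame(gene = model$genes,
                              centroid_low = unname(model$centroid_low),
                              centroid_high = unname(model$centroid_high)),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_centroid_model
#' @export
read_centroid_model <- function(path) {
  first <- readLines(path, n = 1L)
  scale <- if (grepl("^# scale=", first))
    sub("^# scale=", "", first) else "log2"
  df <- utils::read.csv(path, comment.char = "#")
  new_centroid_model(df$gene, df$centroid_low, df$centroid_high,
                     scale = scale,
                     training_meta = list(source = basename(path)))
}

#' Shipped default model: centroids fit on a seeded synthetic cohort
#'
#' The original training expression matrix behind the deployed assay is
#' not distributed with this package, so the default model is fit on a
#' fully synthetic training cohort (separable classes, balanced mixing)
#' and is labelled as such in its metadata. Replace it with real
#' centroids via [read_centroid_model()] for any substantive use.
#'
#' @param seed generator seed for the synthetic training cohort.
#' @param n_patients training cohort size.
#' @return a `centroid_model`.
#' @export
synthetic_centroid_model <- function(seed = 42L, n_patients = 100L) {
  cfg <- sim_config(seed = seed, n_patients = n_patients,
                    prevalence_high = 0.5)
  cohort <- simulate_cohort(cfg, lanes = FALSE)
  norm <- normalize_counts(cohort$expression)
  fit_centroids(norm, cohort$true_class,
                training_meta = list(cohort = "synthetic training cohort",
                                     synthetic = TRUE, seed = seed))
}
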