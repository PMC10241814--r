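positive_values <- function(x, what = "geNorm") {
  if (inherits(x, "expr_matrix")) {
    if (x$scale == "log2")
      stop(what, " requires a positive linear scale; got log2 ",
           "(back-transform first)")
    v <- x$values
    if (x$scale == "raw") v <- v + 1  # tolerate zero counts
  } else {
    v <- as.matrix(x)
  }
  v
}

#' Screen genes by coefficient of variation
#'
#' Ranks genes by CV = SD/mean on a positive scale and returns the `k`
#' most stable. When a second cohort is supplied the per-cohort CV ranks
#' are combined by mean rank, so a gene must be stable in both cohorts to
#' score well.
#'
#' @param matrix an [expr_matrix()] on a positive scale (raw counts get
#'   +1) or a plain positive matrix.
#' @param k number of genes to return (`k <=` number of genes).
#' @param matrix2 optional second cohort over the same genes.
#' @return character vector of `k` gene names, most stable first.
#' @export
cv_screen <- function(matrix, k, matrix2 = NULL) {
  v <- positive_values(matrix, "cv_screen")
  if (k > nrow(v)) stop("k exceeds the number of genes")
  cv_of <- function(m) {
    mu <- rowMeans(m)
    zero <- mu == 0
    if (any(zero)) {
      warning("excluding gene(s) with mean 0: ",
              paste(rownames(m)[zero], collapse = ", "))
      m <- m[!zero, , drop = FALSE]
      mu <- mu[!zero]
    }
    apply(m, 1, stats::sd) / mu
  }
  cv1 <- cv_of(v)
  if (is.null(matrix2)) {
    score <- rank(cv1, ties.method = "first")
  } else {
    v2 <- positive_values(matrix2, "cv_screen")
    if (!setequal(rownames(v), rownames(v2)))
      stop("the two cohorts must cover the same genes")
    cv2 <- cv_of(v2[rownames(v), , drop = FALSE])
    common <- intersect(names(cv1), names(cv2))
    score <- (rank(cv1[common]) + rank(cv2[common])) / 2
    cv1 <- cv1[common]
  }
  names(sort(score)[seq_len(min(k, length(score)))])
}

#' geNorm expression-stability measure M
#'
#' For each candidate control gene j, `M_j` is the mean over all other
#' candidates k of the SD across samples of `log2(x_j / x_k)`. A low M
#' means the gene keeps a constant ratio to the other candidates, i.e. is
#' stably expressed.
#'
#' @param matrix candidate-gene expression on a positive scale
#'   ([expr_matrix()] or plain matrix, genes x samples, >= 2 genes,
#'   >= 2 samples).
#' @return named numeric vector of M values (all >= 0).
#' @export
genorm_m <- function(matrix) {
  v <- positive_values(matrix)
  if (nrow(v) < 2) stop("geNorm needs at least 2 candidate genes")
  if (ncol(v) < 2) stop("geNorm needs at least 2 samples")
  if (any(v <= 0))
    stop("geNorm log-ratios undefined: non-positive expression value(s)")
  lv <- log2(v)
  k <- nrow(v)
  m <- numeric(k)
  for (j in seq_len(k)) {
    sds <- vapply(seq_len(k)[-j],
                  function(i) stats::sd(lv[j, ] - lv[i, ]), numeric(1))
    m[j] <- mean(sds)
  }
  stats::setNames(m, rownames(v))
}

#' geNorm stability ranking with pairwise-variation stopping
#'
#' Iteratively removes the least stable candidate (highest M; ties drop
#' the lexicographically last gene), recording each gene's M at its
#' exclusion step. The last two genes cannot be separated by geNorm and
#' share the final 2-gene M, ordered lexicographically. Normalization
#' factors `NF_n` are per-sample geometric means over the n most stable
#' genes; the pairwise variation `V(n, n+1)` is the SD across samples of
#' `log2(NF_n / NF_{n+1})`. The selected panel is the smallest n with
#' `V(n, n+1) < v_threshold` (all candidates if the threshold is never
#' met).
#'
#' @param matrix candidate-gene expression on a positive scale (>= 3
#'   genes for a meaningful V series).
#' @param v_threshold pairwise-variation cut-off (default 0.15, the
#'   conventional recommendation).
#' @return object of class `genorm_result`: `ranking` (most to least
#'   stable), `exclusion_m` (M at exclusion, in ranking order),
#'   `m_values` (M on the full candidate panel), `v_series` (named
#'   `V(n,n+1)` values), `n_selected`, `selected`, `v_threshold`.
#' @export
genorm_rank <- function(matrix, v_threshold = 0.15) {
  v <- positive_values(matrix)
  if (any(v <= 0))
    stop("geNorm log-ratios undefined: non-positive expression value(s)")
  k_all <- nrow(v)
  if (k_all < 3) stop("geNorm ranking needs at least 3 candidate genes")
  m_full <- genorm_m(v)

  remaining <- v
  excluded <- character(0)
  excl_m <- numeric(0)
  while (nrow(remaining) > 2) {
    m <- genorm_m(remaining)
    worst <- max(m)
    cand <- sort(names(m)[m == worst])
    drop <- cand[length(cand)]  # tie: lexicographically last goes
    excluded <- c(drop, excluded)
    excl_m <- c(stats::setNames(worst, drop), excl_m)
    remaining <- remaining[setdiff(rownames(remaining), drop), ,
                           drop = FALSE]
  }
  m2 <- genorm_m(remaining)
  last_two <- sort(rownames(remaining))
  ranking <- c(last_two, excluded)
  exclusion_m <- c(stats::setNames(m2[last_two], last_two), excl_m)

  lv <- log2(v[ranking, , drop = FALSE])
  nf_log2 <- function(n) colMeans(lv[seq_len(n), , drop = FALSE])
  v_series <- vapply(2:(k_all - 1), function(n)
    stats::sd(nf_log2(n) - nf_log2(n + 1)), numeric(1))
  names(v_series) <- sprintf("V(%d,%d)", 2:(k_all - 1), 3:k_all)

  hit <- which(v_series < v_threshold)
  n_sel <- if (length(hit)) (2:(k_all - 1))[hit[1]] else k_all
  structure(list(ranking = ranking, exclusion_m = exclusion_m,
                 m_values = m_full, v_series = v_series,
                 n_selected = n_sel,
                 selected = ranking[seq_len(n_sel)],
                 v_threshold = v_threshold),
            class = "genorm_result")
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("geNorm stability ranking (most -> least stable):\n")
  cat("  ", paste(sprintf("%s (M=%.3f)", x$ranking,
                          x$exclusion_m[x$ranking]), collapse = ", "),
      "\n")
  cat("pairwise variation:\n  ",
      paste(sprintf("%s=%.3f", names(x$v_series), x$v_series),
            collapse = ", "), "\n")
  cat(sprintf("selected %d control genes (V < %.2f): %s\n",
              x$n_selected, x$v_threshold,
              paste(x$selected, collapse = ", ")))
  invisible(x)
}
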