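bh_stepup <- function(p, alpha) {
  m <- length(p)
  if (m == 0) return(logical(0))
  o <- order(p)
  ok <- p[o] <= seq_len(m) * alpha / m
  k <- if (any(ok)) max(which(ok)) else 0L
  rej <- logical(m)
  if (k > 0) rej[o[seq_len(k)]] <- TRUE
  rej
}

#' Two-stage linear step-up false discovery rate procedure
#'
#' The adaptive two-stage step-up of Benjamini, Krieger and Yekutieli:
#' stage 1 runs a linear step-up test at `q' = q / (1 + q)` and uses its
#' rejection count r1 to estimate the number of true nulls
#' `m0 = m - r1`; stage 2 re-runs the step-up at `q' * m / m0`
#' (everything is rejected when `m0 = 0`).
#'
#' @param p vector of p-values in `[0, 1]` (no NAs; drop them first).
#' @param q target false discovery rate (default 0.01).
#' @return logical vector of discovery flags, aligned with `p`.
#' @export
two_stage_fdr <- function(p, q = 0.01) {
  if (length(p) == 0) return(logical(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no NAs")
  m <- length(p)
  q1 <- q / (1 + q)
  r1 <- sum(bh_stepup(p, q1))
  m0 <- m - r1
  if (m0 == 0) return(rep(TRUE, m))
  bh_stepup(p, q1 * m / m0)
}

#' Per-gene two-group differential expression with FDR control
#'
#' Tests every gene of a log2 expression matrix between two sample
#' groups with a two-sided Welch t test or Mann-Whitney U test, then
#' flags discoveries with [two_stage_fdr()] at level `q`. Genes whose
#' test is degenerate (zero variance in both groups for the t method)
#' get `p = NA` and are excluded from the multiplicity count m.
#'
#' @param matrix a log2 [expr_matrix()] or plain matrix.
#' @param groups per-sample binary grouping (logical, or factor/character
#'   with 2 levels), aligned with columns; both groups need >= 2 samples.
#' @param method `"t"` (Welch) or `"mann_whitney"`.
#' @param q false discovery rate (default 0.01, the deployed setting).
#' @return object of class `de_result`: data.frame `table` (gene, stat,
#'   p, discovery), plus `method` and `q`.
#' @export
compare_genes <- function(matrix, groups, method = c("t", "mann_whitney"),
                          q = 0.01) {
  method <- match.arg(method)
  v <- if (inherits(matrix, "expr_matrix")) matrix$values
       else as.matrix(matrix)
  if (is.logical(groups)) groups <- ifelse(groups, "g1", "g0")
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) != 2)
    stop("`groups` must have exactly 2 levels")
  if (length(groups) != ncol(v))
    stop("`groups` must align with the matrix columns")
  a <- groups == lev[1]
  if (sum(a) < 2 || sum(!a) < 2)
    stop("both groups need >= 2 samples")
  one <- function(x) {
    if (method == "t") {
      tryCatch({
        tt <- stats::t.test(x[!a], x[a])
        c(tt$statistic, tt$p.value)
      }, error = function(e) c(NA_real_, NA_real_))
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x[!a], x[a],
                                                exact = FALSE,
                                                correct = FALSE))
      c(wt$statistic, wt$p.value)
    }
  }
  res <- t(apply(v, 1, one))
  tab <- data.frame(gene = rownames(v), stat = res[, 1], p = res[, 2],
                    discovery = FALSE, row.names = NULL,
                    stringsAsFactors = FALSE)
  usable <- !is.na(tab$p)
  if (any(usable))
    tab$discovery[usable] <- two_stage_fdr(tab$p[usable], q)
  structure(list(table = tab, method = method, q = q),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("de_result: %d genes, %s test, Q = %g%%; %d discoveries\n",
              nrow(x$table), x$method, 100 * x$q, sum(x$table$discovery)))
  invisible(x)
}

#' Chi-square or Mann-Whitney comparison between groups
#'
#' The two cohort-table tests: proportions across categorical factors
#' by the chi-square test (no continuity correction) and medians of a
#' continuous variable by the Mann-Whitney U test (normal approximation
#' with tie correction). P values are two-sided.
#'
#' @param x for `"chi_square"` a contingency table of counts (matrix);
#'   for `"mann_whitney"` the first sample.
#' @param y second sample (`"mann_whitney"` only).
#' @param kind test to run.
#' @return list with `stat` (chi-square statistic or U) and `p`.
#' @export
compare_groups <- function(x, y = NULL,
                           kind = c("chi_square", "mann_whitney")) {
  kind <- match.arg(kind)
  if (kind == "chi_square") {
    x <- as.matrix(x)
    if (any(rowSums(x) == 0) || any(colSums(x) == 0))
      stop("contingency table has a zero margin")
    ct <- suppressWarnings(stats::chisq.test(x, correct = FALSE))
    list(stat = unname(ct$statistic), p = unname(ct$p.value))
  } else {
    if (is.null(y)) stop("mann_whitney needs two samples")
    if (length(x) < 1 || length(y) < 1)
      stop("both samples must be non-empty")
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = FALSE))
    list(stat = unname(wt$statistic), p = unname(wt$p.value))
  }
}
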