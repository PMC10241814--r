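#' Genes-by-samples expression matrix with gene roles and a scale tag
#'
#' Light container shared by the whole pipeline. Rows are genes (probes),
#' columns are samples. Each gene carries a role describing how the pipeline
#' treats it, and the matrix carries a scale tag so downstream steps can
#' refuse inputs on the wrong scale (e.g. classifying raw counts).
#'
#' @param values numeric matrix with gene rownames and sample colnames.
#' @param roles named character vector, one entry per gene, values in
#'   `c("hypoxia", "control", "candidate_control", "positive", "negative")`.
#'   Genes absent from `roles` default to `"hypoxia"`.
#' @param scale one of `"raw"` (non-negative integer counts),
#'   `"normalized"` (positive linear scale) or `"log2"`.
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, roles = NULL,
                        scale = c("raw", "normalized", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) && nrow(values) > 0)
    stop("`values` must have gene rownames")
  if (is.null(colnames(values)) && ncol(values) > 0)
    stop("`values` must have sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (scale == "raw") {
    if (any(!is.finite(values)) || any(values < 0) ||
        any(values != round(values)))
      stop("raw counts must be finite non-negative integers")
  } else if (any(!is.finite(values))) {
    stop("expression values must be finite")
  }
  all_roles <- stats::setNames(rep("hypoxia", nrow(values)), rownames(values))
  if (!is.null(roles)) {
    bad <- setdiff(names(roles), rownames(values))
    if (length(bad))
      stop("roles given for unknown genes: ", paste(bad, collapse = ", "))
    ok <- c("hypoxia", "control", "candidate_control", "positive", "negative")
    if (!all(roles %in% ok))
      stop("invalid gene role(s): ",
           paste(setdiff(roles, ok), collapse = ", "))
    all_roles[names(roles)] <- roles
  }
  structure(list(values = values, roles = all_roles, scale = scale),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (scale: %s)\n",
              nrow(x$values), ncol(x$values), x$scale))
  tab <- table(x$roles)
  if (length(tab))
    cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by genes and/or samples
#'
#' @param x an `expr_matrix`.
#' @param i gene selector (names, indices or logical).
#' @param j sample selector.
#' @param ... ignored.
#' @export
`[.expr_matrix` <- function(x, i, j, ...) {
  v <- x$values
  if (missing(i)) i <- seq_len(nrow(v))
  if (missing(j)) j <- seq_len(ncol(v))
  v <- v[i, j, drop = FALSE]
  expr_matrix(v, roles = x$roles[rownames(v)], scale = x$scale)
}

#' Genes of an expression matrix, optionally restricted by role
#'
#' @param x an `expr_matrix`.
#' @param role optional role filter (see [expr_matrix()]).
#' @return character vector of gene names.
#' @export
em_genes <- function(x, role = NULL) {
  g <- rownames(x$values)
  if (is.null(role)) g else g[x$roles[g] %in% role]
}

#' Sample identifiers of an expression matrix
#' @param x an `expr_matrix`.
#' @export
em_samples <- function(x) colnames(x$values)

#' Write / read an expression matrix as CSV with a role side-car column
#'
#' The first column holds gene names, the second the gene role, remaining
#' columns one sample each. A header comment line records the scale tag.
#'
#' @param x an `expr_matrix`.
#' @param path file path.
#' @return `write_expression_csv` returns `path` invisibly;
#'   `read_expression_csv` returns an `expr_matrix`.
#' @export
write_expression_csv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scale=%s", x$scale), con)
  df <- data.frame(gene = rownames(x$values), role = x$roles,
                   x$values, check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_csv
#' @export
read_expression_csv <- function(path) {
  first <- readLines(path, n = 1L)
  scale <- "normalized"
  if (grepl("^# scale=", first))
    scale <- sub("^# scale=", "", first)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (!all(c("gene", "role") %in% names(df)))
    stop("expression CSV must have 'gene' and 'role' columns")
  v <- as.matrix(df[, setdiff(names(df), c("gene", "role")), drop = FALSE])
  rownames(v) <- df$gene
  expr_matrix(v, roles = stats::setNames(df$role, df$gene), scale = scale)
}
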