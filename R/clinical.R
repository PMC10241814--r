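ENDPOINTS <- c("lrfs", "mfs", "dfs", "os")

clinical_time_cols <- function() paste0(ENDPOINTS, "_time_years")
clinical_event_cols <- function() paste0(ENDPOINTS, "_event")

#' Validate a per-patient clinical table
#'
#' Checks the schema shared by the simulator and the survival battery:
#' one row per patient with identifiers, baseline covariates, optional
#' nomogram-predicted 10-year overall survival (`pos10`, a fraction),
#' optional immunohistochemistry statuses, and a (time, event) pair per
#' endpoint (LRFS/MFS/DFS/OS). Unknown covariate categories are kept as
#' the literal string `"Unknown"`.
#'
#' @param df data.frame to validate.
#' @return `df`, invisibly, with `grade` coerced to integer.
#' @export
validate_clinical <- function(df) {
  need <- c("sample_id", clinical_time_cols(), clinical_event_cols())
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("clinical table missing required column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in clinical table")
  for (tc in clinical_time_cols()) {
    bad <- which(!is.na(df[[tc]]) & df[[tc]] < 0)
    if (length(bad))
      stop("negative time in '", tc, "' at row ", bad[1])
  }
  for (ec in clinical_event_cols()) {
    bad <- which(!is.na(df[[ec]]) & !(df[[ec]] %in% c(0, 1)))
    if (length(bad))
      stop("event indicator in '", ec, "' not 0/1 at row ", bad[1])
  }
  if ("pos10" %in% names(df)) {
    bad <- which(!is.na(df$pos10) & (df$pos10 < 0 | df$pos10 > 1))
    if (length(bad))
      stop("pos10 outside [0,1] at row ", bad[1])
  }
  if ("grade" %in% names(df)) {
    g <- df$grade
    known <- !is.na(g) & g != "Unknown"
    if (any(known & !(g %in% c("1", "2", "3", 1, 2, 3))))
      stop("grade must be 1, 2, 3 or 'Unknown'")
  }
  invisible(df)
}

#' Read / write the clinical CSV
#'
#' @param path file path.
#' @return `read_clinical` returns a validated data.frame;
#'   `write_clinical` returns `path` invisibly.
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_clinical(df)
  df
}

#' @rdname read_clinical
#' @param df clinical data.frame (validated before writing).
#' @export
write_clinical <- function(df, path) {
  validate_clinical(df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
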