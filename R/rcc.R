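#' Construct an nCounter lane record
#'
#' One lane = one sample on an nCounter cartridge: imaging QC attributes
#' plus raw probe counts. Positive-control probe names must carry their
#' input concentration in femtomolar, e.g. `POS_A(128)`.
#'
#' @param lane_id lane identifier (cartridge position).
#' @param sample_id sample identifier; wins over the filename on read.
#' @param fov_count fields of view attempted.
#' @param fov_counted fields of view successfully imaged; must not exceed
#'   `fov_count`.
#' @param binding_density imaging spot density (spots/um^2), non-negative.
#' @param probes data.frame with columns `code_class`
#'   (Positive/Negative/Housekeeping/Endogenous), `name`, `accession`,
#'   `count` (non-negative integers).
#' @return object of class `rcc_lane`.
#' @export
rcc_lane <- function(lane_id, sample_id, fov_count, fov_counted,
                     binding_density, probes) {
  need <- c("code_class", "name", "accession", "count")
  if (!is.data.frame(probes) || !all(need %in% names(probes)))
    stop("`probes` must be a data.frame with columns ",
         paste(need, collapse = ", "))
  if (any(!is.finite(probes$count)) || any(probes$count < 0) ||
      any(probes$count != round(probes$count)))
    stop("probe counts must be finite non-negative integers")
  if (fov_counted > fov_count)
    stop("fov_counted must not exceed fov_count")
  if (binding_density < 0) stop("binding_density must be non-negative")
  ok <- c("Positive", "Negative", "Housekeeping", "Endogenous")
  if (!all(probes$code_class %in% ok))
    stop("unknown code class(es): ",
         paste(setdiff(probes$code_class, ok), collapse = ", "))
  probes <- probes[, need]
  probes$count <- as.integer(probes$count)
  structure(list(lane_id = as.character(lane_id),
                 sample_id = as.character(sample_id),
                 fov_count = as.integer(fov_count),
                 fov_counted = as.integer(fov_counted),
                 binding_density = as.numeric(binding_density),
                 probes = probes),
            class = "rcc_lane")
}

#' @export
print.rcc_lane <- function(x, ...) {
  cat(sprintf("rcc_lane %s (sample %s): %d probes, FOV %d/%d, BD %.2f\n",
              x$lane_id, x$sample_id, nrow(x$probes),
              x$fov_counted, x$fov_count, x$binding_density))
  invisible(x)
}

rcc_sections <- function(lines) {
  starts <- grep("^<[A-Za-z_]+>$", lines)
  ends <- grep("^</[A-Za-z_]+>$", lines)
  secs <- list()
  for (s in starts) {
    nm <- sub("^<([A-Za-z_]+)>$", "\\1", lines[s])
    e <- ends[ends > s][1]
    if (is.na(e) || sub("^</([A-Za-z_]+)>$", "\\1", lines[e]) != nm)
      stop("malformed RCC: unterminated section <", nm, ">")
    body <- lines[seq(s + 1L, e - 1L)]
    secs[[nm]] <- body[nzchar(body)]
  }
  secs
}

rcc_kv <- function(body) {
  parts <- strsplit(body, ",", fixed = TRUE)
  stats::setNames(vapply(parts, function(p) paste(p[-1], collapse = ","),
                         character(1)),
                  vapply(parts, `[[`, character(1), 1))
}

#' Read an nCounter RCC lane file
#'
#' Parses the tag-bracketed comma-separated RCC dialect
#' (`<Header>`/`<Sample_Attributes>`/`<Lane_Attributes>`/`<Code_Summary>`);
#' section order is irrelevant. The `ID` field of `Sample_Attributes` is
#' the sample identity; the filename is ignored.
#'
#' @param path path to an `.RCC` file.
#' @return an [rcc_lane()].
#' @export
read_rcc <- function(path) {
  secs <- rcc_sections(readLines(path, warn = FALSE))
  for (need in c("Header", "Sample_Attributes", "Lane_Attributes",
                 "Code_Summary"))
    if (is.null(secs[[need]]))
      stop("RCC format error in '", basename(path),
           "': missing section <", need, ">")
  samp <- rcc_kv(secs$Sample_Attributes)
  lane <- rcc_kv(secs$Lane_Attributes)
  cs <- utils::read.csv(text = paste(secs$Code_Summary, collapse = "\n"),
                        stringsAsFactors = FALSE)
  if (!all(c("CodeClass", "Name", "Accession", "Count") %in% names(cs)))
    stop("RCC format error: Code_Summary must have columns ",
         "CodeClass,Name,Accession,Count")
  if (any(cs$Count < 0))
    stop("RCC data error: negative count for probe ",
         cs$Name[which(cs$Count < 0)[1]])
  rcc_lane(lane_id = lane[["ID"]], sample_id = samp[["ID"]],
           fov_count = as.integer(lane[["FovCount"]]),
           fov_counted = as.integer(lane[["FovCounted"]]),
           binding_density = as.numeric(lane[["BindingDensity"]]),
           probes = data.frame(code_class = cs$CodeClass, name = cs$Name,
                               accession = cs$Accession, count = cs$Count,
                               stringsAsFactors = FALSE))
}

#' Write an nCounter RCC lane file
#'
#' @param lane an [rcc_lane()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rcc <- function(lane, path) {
  stopifnot(inherits(lane, "rcc_lane"))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w("<Header>", "FileVersion,1.7", "SoftwareVersion,4.0.0.3", "</Header>", "")
  w("<Sample_Attributes>", paste0("ID,", lane$sample_id),
    "Owner,", "Comments,", "Date,", "GeneRLF,hypoxia_sts_panel",
    "SystemAPF,n6_vDV1", "</Sample_Attributes>", "")
  w("<Lane_Attributes>", paste0("ID,", lane$lane_id),
    paste0("FovCount,", lane$fov_count),
    paste0("FovCounted,", lane$fov_counted),
    "ScannerID,synthetic",
    "StagePosition,1",
    paste0("BindingDensity,", format(lane$binding_density)),
    "CartridgeID,synthetic", "</Lane_Attributes>", "")
  w("<Code_Summary>", "CodeClass,Name,Accession,Count",
    sprintf("%s,%s,%s,%d", lane$probes$code_class, lane$probes$name,
            lane$probes$accession, lane$probes$count),
    "</Code_Summary>", "")
  invisible(path)
}

#' Assemble raw lane records into a genes-by-samples count matrix
#'
#' All lanes must share an identical probe set. Vendor positive/negative
#' controls become `positive`/`negative` roles, Housekeeping probes
#' `candidate_control`, Endogenous probes `hypoxia`.
#'
#' @param lanes list of [rcc_lane()] objects.
#' @return an [expr_matrix()] with `scale = "raw"`.
#' @export
assemble_matrix <- function(lanes) {
  if (length(lanes) == 0) {
    v <- matrix(numeric(0), 0, 0)
    return(expr_matrix(v, scale = "raw"))
  }
  stopifnot(all(vapply(lanes, inherits, logical(1), "rcc_lane")))
  ref <- lanes[[1]]$probes$name
  for (ln in lanes) {
    if (!setequal(ln$probes$name, ref) || anyDuplicated(ln$probes$name)) {
      d <- union(setdiff(ln$probes$name, ref), setdiff(ref, ln$probes$name))
      stop("probe-set mismatch across lanes: ", paste(d, collapse = ", "))
    }
  }
  ids <- vapply(lanes, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids))
    stop("duplicate sample IDs across lanes: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  v <- vapply(lanes, function(ln) {
    stats::setNames(as.numeric(ln$probes$count), ln$probes$name)[ref]
  }, numeric(length(ref)))
  v <- matrix(v, nrow = length(ref), dimnames = list(ref, ids))
  cls <- stats::setNames(lanes[[1]]$probes$code_class, ref)
  roles <- c(Positive = "positive", Negative = "negative",
             Housekeeping = "candidate_control",
             Endogenous = "hypoxia")[cls]
  expr_matrix(v, roles = stats::setNames(unname(roles), ref), scale = "raw")
}

#' Parse positive-control input concentrations from probe names
#'
#' Vendor convention names the positive titration `POS_A(128)` .. in fM.
#'
#' @param names character vector of probe names.
#' @return numeric vector of concentrations (fM), `NA` where unparseable.
#' @export
pos_concentration <- function(names) {
  m <- regmatches(names, regexpr("\\(([0-9.]+)\\)", names))
  out <- rep(NA_real_, length(names))
  hit <- lengths(regmatches(names, gregexpr("\\(([0-9.]+)\\)", names))) > 0
  out[hit] <- as.numeric(gsub("[()]", "", m))
  out
}
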