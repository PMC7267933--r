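# Data model and TSV I/O for longitudinal morphometry cohorts.
#
# The pipeline's universal currency is the long_table: one row per (subject,
# visit), subject-level fields repeated on every row, one numeric column per
# brain region, and an explicit region dictionary declaring whether a column
# is a volume (cm^3), a planar area (mm^2) or a cortical thickness (mm).

.META_COLS <- c("subject_id", "group", "sex", "education", "baseline_age",
                "icv", "converter_label", "visit_index", "time_from_baseline",
                "age_at_visit", "cognitive_status", "mean_thickness")
.REQUIRED_COLS <- c("subject_id", "group", "sex", "education", "baseline_age",
                    "icv", "visit_index", "time_from_baseline")
.GROUPS <- c("CTRL", "PDN", "PDCI")
.SEXES <- c("M", "F")
.STATUSES <- c("NORMAL", "MCI", "DEMENTIA")
.CONVERTER_LABELS <- c("nPDN", "cPDN")
.REGION_KINDS <- c("volume", "area", "thickness")

lm_error <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "longmorph_error", "error", "condition")))
}

#' Declare a region dictionary
#'
#' The region dictionary names the morphometry columns of a cohort table and
#' tags each with its measurement kind, so that volumes (cm^3), planar areas
#' (mm^2) and cortical thickness values (mm) are never mixed within one
#' normalization pass.
#'
#' @param region Character vector of region column names.
#' @param kind Character vector (recycled) among `"volume"`, `"area"`,
#'   `"thickness"`.
#' @param units Character vector of units; defaults to the conventional unit
#'   for each kind (`cm^3`, `mm^2`, `mm`).
#' @return A `data.frame` with columns `region`, `kind`, `units`.
#' @examples
#' region_dictionary(c("brain_volume", "caudal_acc"), c("volume", "thickness"))
#' @export
region_dictionary <- function(region, kind, units = NULL) {
  kind <- rep_len(kind, length(region))
  bad <- setdiff(unique(kind), .REGION_KINDS)
  if (length(bad) > 0L)
    lm_error("longmorph_schema_error", "unknown region kind(s): %s",
             paste(bad, collapse = ", "))
  if (anyDuplicated(region))
    lm_error("longmorph_schema_error", "duplicated region name(s)")
  if (is.null(units))
    units <- c(volume = "cm^3", area = "mm^2", thickness = "mm")[kind]
  data.frame(region = as.character(region), kind = kind,
             units = as.character(units), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Construct a longitudinal cohort table
#'
#' Bundles per-visit morphometry records with their region dictionary and
#' validates all structural invariants: unique (subject, visit) pairs, a
#' baseline visit (`visit_index == 0`, `time_from_baseline == 0`) for every
#' subject, strictly increasing visit times, constant subject-level fields,
#' positive intracranial volume, and consistent ages
#' (`age_at_visit == baseline_age + time_from_baseline`).
#'
#' @param data A `data.frame` with one row per visit. Required columns:
#'   `subject_id`, `group` (CTRL/PDN/PDCI), `sex` (M/F), `education`,
#'   `baseline_age`, `icv`, `visit_index`, `time_from_baseline`. Optional:
#'   `converter_label`, `age_at_visit`, `cognitive_status`, `mean_thickness`,
#'   one numeric column per region, and any extra metadata columns.
#' @param regions A region dictionary from [region_dictionary()].
#' @param provenance Character vector of processing steps already applied
#'   (used to guard against, e.g., double covariate correction).
#' @return An object of class `long_table`.
#' @export
long_table <- function(data, regions, provenance = character()) {
  stopifnot(is.data.frame(data), is.data.frame(regions))
  missing_cols <- setdiff(.REQUIRED_COLS, names(data))
  if (length(missing_cols) > 0L)
    lm_error("longmorph_schema_error", "missing required column(s): %s",
             paste(missing_cols, collapse = ", "))
  if (!all(c("region", "kind", "units") %in% names(regions)))
    lm_error("longmorph_schema_error",
             "region dictionary needs columns region, kind, units")
  for (opt in c("converter_label", "cognitive_status"))
    if (!opt %in% names(data)) data[[opt]] <- NA_character_
  if (!"age_at_visit" %in% names(data))
    data$age_at_visit <- data$baseline_age + data$time_from_baseline
  if (!"mean_thickness" %in% names(data)) data$mean_thickness <- NA_real_
  data$subject_id <- as.character(data$subject_id)
  data$group <- as.character(data$group)
  data$sex <- as.character(data$sex)
  data$cognitive_status <- as.character(data$cognitive_status)
  data$converter_label <- as.character(data$converter_label)
  data$visit_index <- as.integer(data$visit_index)
  data <- data[order(data$subject_id, data$visit_index), , drop = FALSE]
  rownames(data) <- NULL
  x <- structure(list(data = data, regions = regions,
                      provenance = as.character(provenance)),
                 class = "long_table")
  validate_long_table(x)
  x
}

#' Validate a long_table against all structural invariants
#'
#' @param x A `long_table`.
#' @return `x`, invisibly; signals a classed error
#'   (`longmorph_schema_error` or `longmorph_integrity_error`) on the first
#'   violated invariant.
#' @export
validate_long_table <- function(x) {
  stopifnot(inherits(x, "long_table"))
  d <- x$data
  reg <- x$regions
  missing_reg <- setdiff(reg$region, names(d))
  if (length(missing_reg) > 0L)
    lm_error("longmorph_schema_error",
             "region column(s) absent from data: %s",
             paste(missing_reg, collapse = ", "))
  for (r in reg$region)
    if (!is.numeric(d[[r]]))
      lm_error("longmorph_schema_error", "region column '%s' is not numeric", r)
  if (any(!d$group %in% .GROUPS))
    lm_error("longmorph_schema_error", "group must be one of %s",
             paste(.GROUPS, collapse = "/"))
  if (any(!d$sex %in% .SEXES))
    lm_error("longmorph_schema_error", "sex must be M or F")
  st <- d$cognitive_status
  if (any(!is.na(st) & !st %in% .STATUSES))
    lm_error("longmorph_schema_error", "invalid cognitive_status value")
  cl <- d$converter_label
  if (any(!is.na(cl) & !cl %in% .CONVERTER_LABELS))
    lm_error("longmorph_schema_error", "invalid converter_label value")
  key <- paste(d$subject_id, d$visit_index, sep = "\r")
  if (anyDuplicated(key))
    lm_error("longmorph_integrity_error",
             "duplicated (subject_id, visit_index) pair: %s",
             sub("\r", ", visit ", key[duplicated(key)][1L]))
  if (any(!is.finite(d$icv) | d$icv <= 0))
    lm_error("longmorph_integrity_error", "icv must be positive")
  if (any(!is.finite(d$education) | d$education < 0))
    lm_error("longmorph_integrity_error", "education must be non-negative")
  if (any(d$baseline_age < 18 | d$baseline_age > 110))
    lm_error("longmorph_integrity_error", "baseline_age outside [18, 110]")
  if (any(xor(d$visit_index == 0L, d$time_from_baseline == 0)))
    lm_error("longmorph_integrity_error",
             "visit_index 0 must coincide with time_from_baseline 0")
  if (any(abs(d$age_at_visit - (d$baseline_age + d$time_from_baseline)) > 1e-9))
    lm_error("longmorph_integrity_error",
             "age_at_visit != baseline_age + time_from_baseline")
  for (sid in unique(d$subject_id)) {
    rows <- d[d$subject_id == sid, , drop = FALSE]
    if (!0L %in% rows$visit_index)
      lm_error("longmorph_integrity_error", "subject %s has no baseline visit",
               sid)
    tt <- rows$time_from_baseline[order(rows$visit_index)]
    if (any(diff(tt) <= 0))
      lm_error("longmorph_integrity_error",
               "visit times not strictly increasing for subject %s", sid)
    for (col in c("group", "sex", "education", "baseline_age", "icv",
                  "converter_label")) {
      v <- rows[[col]]
      if (length(unique(v[!is.na(v)])) > 1L || (any(is.na(v)) && !all(is.na(v))))
        lm_error("longmorph_integrity_error",
                 "subject-level field '%s' varies within subject %s", col, sid)
    }
    if (!is.na(rows$converter_label[1L]) && rows$group[1L] != "PDN")
      lm_error("longmorph_integrity_error",
               "converter_label set for non-PDN subject %s", sid)
  }
  invisible(x)
}

#' @export
print.long_table <- function(x, ...) {
  d <- x$data
  cat(sprintf("long_table: %d subjects, %d visits, %d regions\n",
              length(unique(d$subject_id)), nrow(d), nrow(x$regions)))
  tab <- table(d$group[d$visit_index == 0L])
  cat("  baseline n:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  if (length(x$provenance) > 0L)
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Subjects of a cohort table
#'
#' @param x A `long_table`.
#' @return One-row-per-subject `data.frame` of the subject-level fields.
#' @export
subject_table <- function(x) {
  stopifnot(inherits(x, "long_table"))
  d <- x$data[x$data$visit_index == 0L, , drop = FALSE]
  d[, c("subject_id", "group", "sex", "education", "baseline_age", "icv",
        "converter_label"), drop = FALSE]
}

#' Baseline slice of a cohort table
#'
#' @param x A `long_table`.
#' @return A `long_table` restricted to `visit_index == 0`.
#' @export
baseline_slice <- function(x) {
  stopifnot(inherits(x, "long_table"))
  x$data <- x$data[x$data$visit_index == 0L, , drop = FALSE]
  rownames(x$data) <- NULL
  x
}

# canonical column order: metadata, extra columns (sorted), regions (sorted)
table_column_order <- function(x) {
  d <- x$data
  meta <- intersect(.META_COLS, names(d))
  regions <- sort(x$regions$region)
  extra <- sort(setdiff(names(d), c(meta, regions)))
  c(meta, extra, regions)
}

#' Read a longitudinal morphometry table from TSV
#'
#' Reads a UTF-8 tab-separated file with a header row, coerces region columns
#' to numeric (empty cells become missing values), re-sorts rows by subject
#' and visit index, and validates every structural invariant.
#'
#' @param path Path to the TSV file.
#' @param schema Region dictionary from [region_dictionary()] declaring the
#'   region columns expected in the file.
#' @return A validated `long_table`.
#' @seealso [write_long_table()]
#' @export
read_long_table <- function(path, schema) {
  if (!file.exists(path))
    lm_error("longmorph_io_error", "input file not found: %s", path)
  d <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                         na.strings = c("", "NA"), check.names = FALSE,
                         stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(.REQUIRED_COLS, names(d))
  if (length(missing_cols) > 0L)
    lm_error("longmorph_schema_error", "missing required column(s): %s",
             paste(missing_cols, collapse = ", "))
  missing_reg <- setdiff(schema$region, names(d))
  if (length(missing_reg) > 0L)
    lm_error("longmorph_schema_error", "region column(s) absent from file: %s",
             paste(missing_reg, collapse = ", "))
  numeric_cols <- c("education", "baseline_age", "icv", "visit_index",
                    "time_from_baseline", "age_at_visit", "mean_thickness",
                    schema$region)
  extra <- setdiff(names(d), c(.META_COLS, schema$region))
  # extra columns: numeric when every non-missing cell parses as a number
  for (col in extra) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    if (!any(is.na(v) & !is.na(d[[col]]))) d[[col]] <- v
  }
  for (col in intersect(numeric_cols, names(d))) {
    raw <- d[[col]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) & !is.na(raw))
    if (length(bad) > 0L)
      lm_error("longmorph_parse_error",
               "non-numeric value '%s' in column '%s' at data row %d",
               raw[bad[1L]], col, bad[1L])
    d[[col]] <- v
  }
  long_table(d, schema)
}

#' Write a longitudinal morphometry table to TSV
#'
#' Columns are written in a deterministic order (metadata columns, then any
#' extra columns sorted lexicographically, then region columns sorted
#' lexicographically), so that tables built with permuted region order produce
#' byte-identical files. Missing values are written as empty cells. Numeric
#' cells are rendered with 17 significant digits so that
#' `read_long_table(write_long_table(x))` reproduces `x` exactly for finite
#' values.
#'
#' @param table A `long_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_long_table <- function(table, path) {
  validate_long_table(table)
  cols <- table_column_order(table)
  d <- table$data[, cols, drop = FALSE]
  out <- d
  for (col in names(out)) {
    v <- out[[col]]
    if (is.numeric(v)) {
      s <- character(length(v))
      ok <- !is.na(v)
      s[ok] <- sprintf("%.17g", v[ok])
      # trim float noise where the short form round-trips exactly
      short <- sprintf("%.15g", v[ok])
      s[ok] <- ifelse(as.numeric(short) == v[ok], short, s[ok])
      # integers print without exponent
      int <- ok & v == round(v) & abs(v) < 1e15
      s[which(int)] <- sprintf("%.0f", v[which(int)])
      out[[col]] <- s
    } else {
      v <- as.character(v)
      v[is.na(v)] <- ""
      out[[col]] <- v
    }
  }
  con <- tryCatch(file(path, open = "wb"), error = function(e)
    lm_error("longmorph_io_error", "cannot open '%s' for writing", path))
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out) > 0L)
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  invisible(path)
}

#' Label PD-N subjects as cognitive-status converters or nonconverters
#'
#' Each cognitively normal PD subject (`group == "PDN"`) with at least one
#' follow-up visit is labelled `cPDN` if any follow-up cognitive status is MCI
#' or DEMENTIA, otherwise `nPDN`. PD-N subjects with a baseline visit only keep
#' a missing label and are excluded from converter analyses. The operation is
#' idempotent.
#'
#' @param table A `long_table` with per-visit `cognitive_status`.
#' @return The table with `converter_label` filled for labelable PD-N subjects.
#' @export
label_converters <- function(table) {
  stopifnot(inherits(table, "long_table"))
  d <- table$data
  pre <- !is.na(d$converter_label) & d$group != "PDN"
  if (any(pre))
    lm_error("longmorph_integrity_error",
             "non-PDN subject %s already carries a converter label",
             d$subject_id[pre][1L])
  for (sid in unique(d$subject_id[d$group == "PDN"])) {
    idx <- which(d$subject_id == sid)
    fu <- d$cognitive_status[idx][d$visit_index[idx] > 0L]
    if (length(fu) == 0L) next
    lab <- if (any(fu %in% c("MCI", "DEMENTIA"), na.rm = TRUE)) "cPDN" else "nPDN"
    d$converter_label[idx] <- lab
  }
  table$data <- d
  validate_long_table(table)
  table
}
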