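#' Read a single-cell classification table
#'
#' Tab- or comma-separated text (dialect auto-detected from the header line)
#' with columns `patient_id`, `section_id`, `site`, `x`, `y`, `cell_class`.
#' Labels are validated against the closed vocabularies; errors name the
#' offending data row.
#'
#' @param path File path.
#' @param allow_extra_sites Accept site labels outside the built-in seven.
#' @return `data.table` of cell records, keyed (grouped) by `section_id`
#'   with input order preserved within sections.
#' @export
read_cell_table <- function(path, allow_extra_sites = FALSE) {
  dt <- fread_delim(path)
  need <- c("patient_id", "section_id", "site", "x", "y", "cell_class")
  check_schema(dt, need, path)
  bad <- which(!dt$cell_class %in% CELL_CLASSES)
  if (length(bad) > 0) {
    stopf("row %d: unknown cell_class '%s' (expected %s)", bad[1],
          dt$cell_class[bad[1]], paste(CELL_CLASSES, collapse = "/"))
  }
  if (!allow_extra_sites) {
    bad <- which(!dt$site %in% SITES)
    if (length(bad) > 0) {
      stopf("row %d: unknown site '%s' (expected %s); use allow_extra_sites to accept",
            bad[1], dt$site[bad[1]], paste(SITES, collapse = "/"))
    }
  }
  if (any(!is.finite(dt$x)) || any(!is.finite(dt$y)) ||
      any(dt$x < 0) || any(dt$y < 0)) {
    stopf("coordinates must be finite and non-negative (image convention)")
  }
  dt[, `:=`(patient_id = as.character(patient_id),
            section_id = as.character(section_id))]
  dt[]
}

#' Read a clinical outcome table
#'
#' Columns: `patient_id`, `age`, `figo_stage`, `debulking`, `chemo_regimen`,
#' `os_months`, `os_event`, `pfs_months`, `pfs_event`. Patients must be
#' unique; times positive; event indicators 0/1. `pfs_months > os_months`
#' raises a warning (not an error).
#'
#' @param path File path.
#' @return `data.table`, one row per patient.
#' @export
read_clinical <- function(path) {
  dt <- fread_delim(path)
  need <- c("patient_id", "age", "figo_stage", "debulking", "chemo_regimen",
            "os_months", "os_event", "pfs_months", "pfs_event")
  check_schema(dt, need, path)
  dt[, patient_id := as.character(patient_id)]
  dup <- dt$patient_id[duplicated(dt$patient_id)]
  if (length(dup) > 0) {
    stopf("duplicate patient_id: %s", paste(unique(dup), collapse = ", "))
  }
  if (any(dt$os_months <= 0) || any(dt$pfs_months <= 0)) {
    stopf("survival times must be positive")
  }
  if (!all(dt$os_event %in% c(0, 1)) || !all(dt$pfs_event %in% c(0, 1))) {
    stopf("event indicators must be 0/1")
  }
  if (any(dt$pfs_months > dt$os_months + 1e-9)) {
    warnf("%d patient(s) with pfs_months > os_months",
          sum(dt$pfs_months > dt$os_months + 1e-9))
  }
  dt[]
}

#' Read an expert-vs-automated annotation table
#'
#' Columns: `cell_id`, `site`, `expert_class`, `predicted_class`; both class
#' columns validated against the 3-class vocabulary.
#'
#' @inheritParams read_cell_table
#' @return `data.table` of annotation pairs.
#' @export
read_annotations <- function(path, allow_extra_sites = FALSE) {
  dt <- fread_delim(path)
  need <- c("cell_id", "site", "expert_class", "predicted_class")
  check_schema(dt, need, path)
  for (col in c("expert_class", "predicted_class")) {
    bad <- which(!dt[[col]] %in% CELL_CLASSES)
    if (length(bad) > 0) {
      stopf("row %d: unknown %s '%s'", bad[1], col, dt[[col]][bad[1]])
    }
  }
  if (!allow_extra_sites) {
    bad <- which(!dt$site %in% SITES)
    if (length(bad) > 0) stopf("row %d: unknown site '%s'", bad[1], dt$site[bad[1]])
  }
  dt[]
}

#' Write a pipeline table as TSV
#'
#' UTF-8, tab-separated, header line, `.` decimal separator regardless of
#' locale; the canonical on-disk dialect of every pipeline artifact.
#'
#' @param x data.frame/data.table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  fwrite(as.data.table(x), path, sep = "\t", quote = FALSE, na = "NA",
         scipen = 0, dec = ".")
  invisible(path)
}

fread_delim <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  fread(path, sep = sep, header = TRUE, encoding = "UTF-8", dec = ".",
        data.table = TRUE)
}

check_schema <- function(dt, need, path) {
  missing <- setdiff(need, names(dt))
  if (length(missing) > 0) {
    stopf("%s: missing column(s): %s", path, paste(missing, collapse = ", "))
  }
}
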