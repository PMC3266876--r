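EGG_TABLE_COLUMNS <- c("individual_id", "strain", "temp_C", "time_h",
                       "eggs_cum", "mode")
EGG_TABLE_MODES <- c("cross_sectional", "longitudinal")

#' Validate an egg-count table
#'
#' Checks the schema (columns `individual_id`, `strain`, `temp_C`,
#' `time_h`, `eggs_cum`, `mode`), value constraints (non-negative
#' integer counts, finite non-negative times, known sampling modes)
#' and within-individual monotonicity of longitudinal counts. Errors
#' name the offending rows.
#'
#' @param table a data frame.
#' @return The table, invisibly; errors on violation.
#' @export
validate_egg_table <- function(table) {
  if (!is.data.frame(table)) stop("egg-count table must be a data frame")
  missing_cols <- setdiff(EGG_TABLE_COLUMNS, names(table))
  if (length(missing_cols) > 0)
    stop("egg-count table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(table) == 0) stop("egg-count table is empty")
  bad_rows <- function(ok, what) {
    if (any(!ok))
      stop(sprintf("%s in row(s): %s", what,
                   paste(utils::head(which(!ok), 10), collapse = ", ")))
  }
  bad_rows(is.finite(table$time_h) & table$time_h >= 0,
           "invalid time_h (must be finite, >= 0)")
  bad_rows(is.finite(table$eggs_cum) & table$eggs_cum >= 0 &
             table$eggs_cum == round(table$eggs_cum),
           "invalid eggs_cum (must be a non-negative integer)")
  bad_rows(table$mode %in% EGG_TABLE_MODES,
           sprintf("invalid mode (must be one of %s)",
                   paste(EGG_TABLE_MODES, collapse = ", ")))
  long <- table[table$mode == "longitudinal", ]
  if (nrow(long) > 0) {
    for (id in unique(long$individual_id)) {
      rec <- long[long$individual_id == id, ]
      if (is.unsorted(rec$eggs_cum[order(rec$time_h)]))
        stop("longitudinal counts of individual ", id,
             " are not non-decreasing in time")
    }
  }
  invisible(table)
}

#' Read and write egg-count tables
#'
#' Tables are stored as plain CSV with a commented (`#`) metadata
#' header, so they stay readable with standard tools. Writing and
#' re-reading is lossless for the data columns; [validate_egg_table()]
#' runs on both paths.
#'
#' @param table an egg-count table.
#' @param path file path.
#' @param meta named list of scalar metadata written as `# key: value`
#'   comment lines (e.g. generator seed and parameters).
#' @return `read_egg_table()`: the validated table;
#'   `write_egg_table()`: the path, invisibly.
#' @export
write_egg_table <- function(table, path, meta = list()) {
  validate_egg_table(table)
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, format(meta[[nm]])), con)
  utils::write.csv(as.data.frame(table)[, EGG_TABLE_COLUMNS],
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_egg_table
#' @export
read_egg_table <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_egg_table(tab)
  tab
}

#' Serialize a temperature law as a plain-text config
#'
#' @param law a [temperature_law()] object.
#' @param path file path (YAML-style key-value text).
#' @return `write_temperature_law()`: the path, invisibly;
#'   `read_temperature_law()`: the law.
#' @export
write_temperature_law <- function(law, path) {
  if (!inherits(law, "temperature_law")) stop("`law` must be a temperature_law")
  yaml::write_yaml(list(
    k_max = as.list(law$k_max), k_d = as.list(law$k_d),
    delta = as.list(law$delta), k_hat = law$k_hat,
    delta_cap = law$delta_cap, range = as.numeric(law$range)), path)
  invisible(path)
}

#' @rdname write_temperature_law
#' @export
read_temperature_law <- function(path) {
  x <- yaml::read_yaml(path)
  temperature_law(k_max = unlist(x$k_max), k_d = unlist(x$k_d),
                  delta = unlist(x$delta), k_hat = x$k_hat,
                  delta_cap = x$delta_cap, range = unlist(x$range))
}
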