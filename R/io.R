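table_schemas <- list(
  timecourse = list(
    required = list(c("time_s"), c("replicate"),
                    c("product_nM", "product_fraction")),
    sorted_within = "replicate", time_col = "time_s"
  ),
  titration = list(
    required = list(c("enzyme_nM", "x_ratio")),
    sorted_within = NULL, time_col = NULL
  ),
  trace = list(
    required = list(c("t_s"), c("I563"), c("I665")),
    sorted_within = NA, time_col = "t_s"
  ),
  spectrum = list(
    required = list(c("wavelength_nm"), c("intensity")),
    sorted_within = NULL, time_col = NULL
  ),
  events = list(
    required = list(c("mass_kDa", "contrast")),
    sorted_within = NULL, time_col = NULL
  )
)

#' Read a typed experiment table
#'
#' Reads a CSV experiment file under one of the interchange schemas,
#' validating required columns, numeric content and time ordering, and
#' surfacing any `# truth:` metadata header written by the generators
#' (see [write_experiment_table()]) as the `truth` attribute.
#'
#' Schemas (alternatives separated by `|`):
#' * `timecourse`: `time_s, replicate, product_nM | product_fraction`
#' * `titration`: `enzyme_nM, free_intensity, total_intensity` or
#'   `x_ratio, efret`
#' * `trace`: `t_s, I563, I665`
#' * `spectrum`: `wavelength_nm, intensity`
#' * `events`: `mass_kDa` or `contrast`
#'
#' @param path CSV file path. Lines starting with `#` are metadata.
#' @param schema One of `"timecourse"`, `"titration"`, `"trace"`,
#'   `"spectrum"`, `"events"`.
#' @return A validated tibble; generator truth (if present) in
#'   `attr(, "truth")`.
#' @export
read_experiment_table <- function(path,
                                  schema = c("timecourse", "titration",
                                             "trace", "spectrum", "events")) {
  schema <- match.arg(schema)
  spec <- table_schemas[[schema]]
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  truth <- NULL
  tline <- grep("^#\\s*truth:", meta, value = TRUE)
  if (length(tline) > 0) {
    truth <- jsonlite::fromJSON(sub("^#\\s*truth:\\s*", "", tline[1]))
  }
  tbl <- readr::read_csv(I(lines[!grepl("^#", lines)]),
                         show_col_types = FALSE, progress = FALSE)
  for (alt in spec$required) {
    if (!any(alt %in% names(tbl))) {
      stop(sprintf("schema '%s': missing column %s in %s",
                   schema, paste(alt, collapse = " or "), path),
           call. = FALSE)
    }
  }
  numeric_cols <- setdiff(
    intersect(names(tbl), unlist(spec$required)), "replicate"
  )
  for (cl in numeric_cols) {
    bad <- which(!is.na(tbl[[cl]]) & is.na(suppressWarnings(
      as.numeric(tbl[[cl]])
    )))
    if (!is.numeric(tbl[[cl]])) {
      v <- suppressWarnings(as.numeric(tbl[[cl]]))
      bad <- which(is.na(v) & !is.na(tbl[[cl]]))
      if (length(bad) > 0) {
        stop(sprintf("schema '%s': non-numeric value in column %s at row %d",
                     schema, cl, bad[1]), call. = FALSE)
      }
      tbl[[cl]] <- v
    }
  }
  if (!is.null(spec$time_col)) {
    check_sorted <- function(x, rows) {
      if (is.unsorted(x)) {
        i <- which(diff(x) < 0)[1]
        stop(sprintf("schema '%s': %s not sorted at row %d",
                     schema, spec$time_col, rows[i + 1]), call. = FALSE)
      }
    }
    if (identical(spec$sorted_within, "replicate") &&
        "replicate" %in% names(tbl)) {
      for (r in unique(tbl$replicate)) {
        idx <- which(tbl$replicate == r)
        check_sorted(tbl[[spec$time_col]][idx], idx)
      }
    } else {
      check_sorted(tbl[[spec$time_col]], seq_len(nrow(tbl)))
    }
  }
  attr(tbl, "truth") <- truth
  tbl
}

#' Write an experiment table with truth metadata
#'
#' Writes a tibble as CSV, prefixed with a `# truth:` JSON header when the
#' table (or the `truth` argument) carries generator truth, so a
#' generated file read back with [read_experiment_table()] surfaces the
#' parameters it was simulated from.
#'
#' @param tbl The table to write.
#' @param path Output CSV path.
#' @param truth Optional truth list; defaults to `attr(tbl, "truth")`.
#' @return `path`, invisibly.
#' @export
write_experiment_table <- function(tbl, path, truth = attr(tbl, "truth")) {
  header <- character()
  if (!is.null(truth)) {
    header <- paste0(
      "# truth: ",
      jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA)
    )
  }
  body <- readr::format_csv(tbl)
  writeLines(c(header, sub("\n$", "", body)), path)
  invisible(path)
}

#' Kinetics report with fold changes
#'
#' Builds a rates-and-fold-changes table in the layout of pre-steady-state
#' kinetics summaries: one row per substrate with `kobs` and `kss` (each
#' with standard error) and their fold changes relative to a reference.
#'
#' Two modes:
#' * `mode = "reference"`: folds computed against the row whose
#'   `substrate` equals `reference` (e.g. every substrate vs dsDNA).
#' * `mode = "paired"`: `rates` carries an `enzyme` column; each
#'   substrate's non-reference enzyme rows are compared against the same
#'   substrate's `reference` enzyme row (e.g. mutant vs matched wild type).
#'
#' Fold standard errors use first-order ratio propagation
#' ([fold_change_with_error()]). Reference rows have `NA` folds (rendered
#' as a dash when printed). Full precision is kept; round for display.
#'
#' @param rates A data frame with columns `substrate`, `kobs`, `kobs_se`,
#'   `kss`, `kss_se`, plus `enzyme` in paired mode.
#' @param reference The reference `substrate` (reference mode) or `enzyme`
#'   (paired mode).
#' @param mode `"reference"` or `"paired"`.
#' @return A tibble with `kobs_fold`, `kobs_fold_se`, `kss_fold`,
#'   `kss_fold_se` columns appended.
#' @examples
#' rates <- tibble::tibble(
#'   substrate = c("dsDNA", "PTJ"),
#'   kobs = c(129, 10), kobs_se = c(24, 1),
#'   kss = c(1.7, 2.7), kss_se = c(0.26, 0.21)
#' )
#' report_kinetics(rates, reference = "dsDNA")
#' @export
report_kinetics <- function(rates, reference, mode = c("reference", "paired")) {
  mode <- match.arg(mode)
  rates <- tibble::as_tibble(rates)
  need <- c("substrate", "kobs", "kobs_se", "kss", "kss_se")
  if (mode == "paired") need <- c("enzyme", need)
  missing_cols <- setdiff(need, names(rates))
  if (length(missing_cols) > 0) {
    stop("rates table missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  fold_cols <- function(ref_row, rows) {
    kobs_fc <- fold_change_with_error(ref_row$kobs, ref_row$kobs_se,
                                      rows$kobs, rows$kobs_se)
    kss_fc <- fold_change_with_error(ref_row$kss, ref_row$kss_se,
                                     rows$kss, rows$kss_se)
    rows$kobs_fold <- kobs_fc$fold
    rows$kobs_fold_se <- kobs_fc$fold_se
    rows$kobs_direction <- kobs_fc$direction
    rows$kss_fold <- kss_fc$fold
    rows$kss_fold_se <- kss_fc$fold_se
    rows$kss_direction <- kss_fc$direction
    rows
  }
  blank_folds <- function(rows) {
    rows$kobs_fold <- NA_real_
    rows$kobs_fold_se <- NA_real_
    rows$kobs_direction <- NA_character_
    rows$kss_fold <- NA_real_
    rows$kss_fold_se <- NA_real_
    rows$kss_direction <- NA_character_
    rows
  }

  if (mode == "reference") {
    ref_row <- dplyr::filter(rates, .data$substrate == reference)
    if (nrow(ref_row) != 1) {
      stop(sprintf("reference substrate '%s' must appear exactly once",
                   reference), call. = FALSE)
    }
    out <- fold_cols(ref_row, rates)
    out[out$substrate == reference,
        c("kobs_fold", "kobs_fold_se", "kss_fold", "kss_fold_se")] <- NA_real_
    out[out$substrate == reference,
        c("kobs_direction", "kss_direction")] <- NA_character_
    out
  } else {
    purrr::map_dfr(unique(rates$substrate), function(s) {
      sub <- dplyr::filter(rates, .data$substrate == s)
      ref_row <- dplyr::filter(sub, .data$enzyme == reference)
      if (nrow(ref_row) != 1) {
        stop(sprintf(
          "substrate '%s' needs exactly one row for reference enzyme '%s'",
          s, reference
        ), call. = FALSE)
      }
      others <- dplyr::filter(sub, .data$enzyme != reference)
      dplyr::bind_rows(blank_folds(ref_row), fold_cols(ref_row, others))
    })
  }
}

#' Format a kinetics report for display
#'
#' Renders [report_kinetics()] output with folds rounded to one decimal and
#' reference-row folds as an en dash, matching the conventional printed
#' layout.
#'
#' @param report Output of [report_kinetics()].
#' @return A character-matrix-like tibble for printing.
#' @export
format_kinetics_report <- function(report) {
  fmt_fold <- function(f, se) {
    ifelse(is.na(f), "–",
           sprintf("%.1f ± %.1f", round(f, 1), round(se, 1)))
  }
  keep <- intersect(c("enzyme", "substrate"), names(report))
  dplyr::bind_cols(
    report[, keep],
    tibble::tibble(
      kobs = sprintf("%.3g ± %.2g", report$kobs, report$kobs_se),
      kobs_fold = fmt_fold(report$kobs_fold, report$kobs_fold_se),
      kss = sprintf("%.3g ± %.2g", report$kss, report$kss_se),
      kss_fold = fmt_fold(report$kss_fold, report$kss_fold_se)
    )
  )
}
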