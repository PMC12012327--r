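detect_sep <- function(path) {
  line1 <- readLines(path, n = 1L)
  if (length(line1) == 0L) stop(sprintf("empty file: %s", path), call. = FALSE)
  if (grepl("\t", line1)) "\t" else ","
}

read_schema_table <- function(path, required) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          strip.white = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in required) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
      stop(sprintf("%s: non-numeric value in column `%s` at row %d",
                   path, col, if (is.na(bad)) 1L else bad), call. = FALSE)
    }
  }
  df
}

collect_row_errors <- function(df, checks, path) {
  msgs <- character()
  for (nm in names(checks)) {
    bad <- which(!checks[[nm]])
    if (length(bad)) {
      msgs <- c(msgs, sprintf("row %s: %s", paste(bad, collapse = ","), nm))
    }
  }
  if (length(msgs)) {
    stop(sprintf("%s: %s", path, paste(msgs, collapse = "; ")), call. = FALSE)
  }
  invisible(df)
}

#' Read a cumulative-labeling table
#'
#' Tab- or comma-separated text with a header row naming (case-insensitive)
#' `time_h`, `n_total`, `n_labeled`. All row-level validation failures are
#' reported together with their row numbers.
#'
#' @param path File path.
#' @return A validated data frame ready for [fit_labeling_curve()].
#' @export
read_labeling_table <- function(path) {
  df <- read_schema_table(path, c("time_h", "n_total", "n_labeled"))
  collect_row_errors(df, list(
    "time_h must be >= 0" = df$time_h >= 0,
    "n_total must be > 0" = df$n_total > 0,
    "n_labeled must lie in [0, n_total]" =
      df$n_labeled >= 0 & df$n_labeled <= df$n_total), path)
  df
}

#' Read a pulse-chase count table
#'
#' Columns `t_chase_h`, `n_edu`, `n_edu_ph3` (case-insensitive header).
#'
#' @param path File path.
#' @return A validated data frame with an added `f_ph3` column.
#' @export
read_pulse_chase_table <- function(path) {
  df <- read_schema_table(path, c("t_chase_h", "n_edu", "n_edu_ph3"))
  collect_row_errors(df, list(
    "t_chase_h must be > 0" = df$t_chase_h > 0,
    "n_edu must be >= 0" = df$n_edu >= 0,
    "n_edu_ph3 must lie in [0, n_edu]" =
      df$n_edu_ph3 >= 0 & df$n_edu_ph3 <= df$n_edu), path)
  df$f_ph3 <- ifelse(df$n_edu > 0, df$n_edu_ph3 / df$n_edu, NA_real_)
  df
}

#' Read a photobleaching trace CSV
#'
#' Columns `t_s`, `roi`, `reference`, `background`, one header row.
#'
#' @param path File path.
#' @param bleach_index Index of the first post-bleach frame; auto-detected
#'   from the largest single-frame drop in `roi` when `NULL`.
#' @return A [frap_trace()].
#' @export
read_frap_trace <- function(path, bleach_index = NULL) {
  df <- read_schema_table(path, c("t_s", "roi", "reference", "background"))
  frap_trace(df$t_s, df$roi, df$reference, df$background, bleach_index)
}

#' Write / read motif-annotated peak tables
#'
#' BED-style 0-based half-open intervals (`chrom`, `start`, `end`, `name`,
#' `score`, `strand`) followed by logical motif columns, tab-separated with
#' a header line (prefixed `#` on write, tolerated on read).
#'
#' @param path File path.
#' @return `read_peaks()`: a data frame with integer coordinates and
#'   logical motif columns.
#' @export
read_peaks <- function(path) {
  header <- sub("^#", "", readLines(path, n = 1L))
  cols <- strsplit(header, "\t")[[1]]
  df <- utils::read.table(path, header = FALSE, sep = "\t", skip = 1L,
                          col.names = cols, stringsAsFactors = FALSE)
  required <- c("chrom", "start", "end")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in c("start", "end")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | v != floor(v))
    if (length(bad)) {
      stop(sprintf("%s: non-integer coordinate in `%s` at row %d",
                   path, col, bad[1]), call. = FALSE)
    }
    df[[col]] <- as.integer(v)
  }
  collect_row_errors(df, list(
    "start must be >= 0" = df$start >= 0,
    "end must be > start" = df$end > df$start), path)
  extra <- setdiff(names(df), c(required, "name", "score", "strand"))
  for (m in extra) {
    if (all(df[[m]] %in% c(0, 1, TRUE, FALSE, "TRUE", "FALSE"))) {
      df[[m]] <- as.logical(df[[m]])
    }
  }
  df
}

#' @rdname read_peaks
#' @param peaks A peak data frame.
#' @param force Overwrite an existing file.
#' @export
write_peaks <- function(peaks, path, force = FALSE) {
  check_overwrite(path, force)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(peaks), collapse = "\t")), con)
  utils::write.table(peaks, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene list (one identifier per line)
#'
#' @param path File path.
#' @return Character vector of identifiers (blank lines dropped).
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

check_overwrite <- function(path, force) {
  if (file.exists(path) && !force) {
    stop(sprintf("refusing to overwrite %s (use force = TRUE / --force)", path),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a flat key-value report
#'
#' Emits a named list of scalars as a JSON object (full precision) and,
#' optionally, as aligned-column text for reading at the terminal.
#'
#' @param x Named list of scalar values.
#' @param json_path Path of the JSON output.
#' @param text_path Optional path of an aligned text rendering.
#' @param force Overwrite existing files.
#' @return `json_path`, invisibly.
#' @export
write_report <- function(x, json_path, text_path = NULL, force = FALSE) {
  check_overwrite(json_path, force)
  jsonlite::write_json(x, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(text_path)) {
    check_overwrite(text_path, force)
    keys <- format(names(x))
    vals <- vapply(x, function(v) paste(format(v), collapse = " "),
                   character(1))
    writeLines(paste(keys, ":", vals), text_path)
  }
  invisible(json_path)
}

#' Write a simulated table with a seed/parameter sidecar
#'
#' Writes a data frame as TSV and a sidecar JSON (`<path>.json`) recording
#' the seed and generator parameters, so every synthetic data set is
#' traceable to the run that produced it.
#'
#' @param df Data frame to write.
#' @param path Output TSV path.
#' @param seed Integer seed used by the generator.
#' @param params Named list of generator parameters.
#' @param force Overwrite existing files.
#' @return `path`, invisibly.
#' @export
write_sim_table <- function(df, path, seed, params = list(), force = FALSE) {
  check_overwrite(path, force)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- paste0(path, ".json")
  check_overwrite(sidecar, force)
  jsonlite::write_json(
    list(seed = seed, params = params,
         package_version = as.character(utils::packageVersion("opcycle"))),
    sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Format a duration for reporting
#'
#' One decimal below 10 h, nearest integer (half-up) at or above 10 h —
#' the precision used for cell-cycle durations in reports.
#'
#' @param h Duration in hours.
#' @return Character scalar.
#' @examples
#' format_duration(1.7725)  # "1.8"
#' format_duration(204.5)   # "205"
#' @export
format_duration <- function(h) {
  if (!is.finite(h)) return(as.character(h))
  # half-up rounding with an epsilon so values computed as x.4999... by
  # floating-point arithmetic still report as the intended half-integer
  if (abs(h) < 10) sprintf("%.1f", h)
  else sprintf("%d", as.integer(floor(h + 0.5 + 1e-9)))
}
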