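# Delimited-text I/O for the pipeline's tabular interchange formats.

#' Read / write a landmark (marker) table
#'
#' Tab-delimited text with header columns `ommatidium_id`, `marker_role`,
#' `x`, `y`, `z` (micrometres); ocelli rows carry an empty
#' `ommatidium_id`.
#'
#' @param path File path.
#' @return `read_marker_table`: data.frame in the long marker schema.
#' @export
read_marker_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_marker_table
#' @param markers Long-format marker data.frame.
#' @export
write_marker_table <- function(markers, path) {
  utils::write.table(markers, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read / write a walking trajectory
#'
#' Tab-delimited text with header `t_s`, `x_mm`, `y_mm` (one animal per
#' file); read back as columns `t`, `x`, `y`.
#'
#' @param path File path.
#' @return `read_trajectory`: data.frame with columns `t`, `x`, `y`.
#' @export
read_trajectory <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stop_field(all(c("t_s", "x_mm", "y_mm") %in% names(d)), "path",
             "trajectory file must have columns t_s, x_mm, y_mm")
  data.frame(t = d$t_s, x = d$x_mm, y = d$y_mm)
}

#' @rdname read_trajectory
#' @param traj data.frame with columns `t`, `x`, `y`.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.table(data.frame(t_s = traj$t, x_mm = traj$x, y_mm = traj$y),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a key-value sidecar file
#'
#' Structured text, one `key = value` pair per line; numeric values are
#' converted. Used for stimulus descriptors (`lambda_deg`,
#' `velocity_deg_s`) and generator ground-truth sidecars.
#'
#' @param path File path.
#' @return `read_sidecar`: named list.
#' @export
read_sidecar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- lapply(kv, function(p) {
    v <- trimws(paste(p[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(out) <- vapply(kv, function(p) trimws(p[1]), character(1))
  out
}

#' @rdname read_sidecar
#' @param values Named list (or vector) of scalar values.
#' @export
write_sidecar <- function(values, path) {
  writeLines(sprintf("%s = %s", names(values),
                     vapply(values, format, character(1))), path)
  invisible(path)
}

#' Read a stimulus descriptor sidecar
#'
#' @param path Sidecar file with keys `lambda_deg` and `velocity_deg_s`.
#' @return A [stimulus_condition()].
#' @export
read_stimulus <- function(path) {
  kv <- read_sidecar(path)
  stop_field(all(c("lambda_deg", "velocity_deg_s") %in% names(kv)), "path",
             "stimulus sidecar needs lambda_deg and velocity_deg_s")
  stimulus_condition(kv$lambda_deg, kv$velocity_deg_s)
}
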