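# CSV interchange for the long-format tables. The SNR table is the sole
# input of the statistics stages, so real (non-synthetic) data can be
# substituted at that boundary.

SNR_SCHEMA <- c("subject_id", "phase", "condition", "snr", "spai")
RATINGS_SCHEMA <- c("subject_id", "phase", "condition", "scale", "value")

#' Write / read the long-format SNR table
#'
#' Columns: `subject_id`, `phase`, `condition`, `snr`, `spai`.
#'
#' @param table The table (`snr_table` data frame).
#' @param path CSV path.
#' @return `read_snr_table()` returns the validated table; writers return the
#'   path invisibly.
#' @export
write_snr_table <- function(table, path) {
  utils::write.csv(as.data.frame(table)[, SNR_SCHEMA], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_snr_table
#' @export
read_snr_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab <- validate_schema(tab, SNR_SCHEMA, "SNR table")
  bad <- which(!is.finite(tab$snr) | tab$snr <= 0)
  if (length(bad))
    stop("SNR table: non-positive or missing snr at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  class(tab) <- c("snr_table", "data.frame")
  tab
}

#' Write / read the ratings table
#'
#' Columns: `subject_id`, `phase`, `condition`, `scale`, `value`.
#'
#' @param table Ratings data frame.
#' @param path CSV path.
#' @export
write_ratings_table <- function(table, path) {
  utils::write.csv(as.data.frame(table)[, RATINGS_SCHEMA], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_ratings_table
#' @export
read_ratings_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_schema(tab, RATINGS_SCHEMA, "ratings table")
}

validate_schema <- function(tab, schema, what) {
  miss <- setdiff(schema, names(tab))
  if (length(miss))
    stop(what, ": missing required column(s) ", paste(miss, collapse = ", "))
  extra <- setdiff(names(tab), schema)
  if (length(extra)) {
    warning(what, ": ignoring extra column(s) ", paste(extra, collapse = ", "))
    tab <- tab[, schema]
  }
  tab
}

#' Load externally supplied tables for the statistics stages
#'
#' Validates schemas and returns tables the frequentist and Bayesian stages
#' consume unchanged, so deposited study data can replace the synthetic
#' generator at this boundary.
#'
#' @param snr_csv Path to the SNR table CSV.
#' @param ratings_csv Optional path to the ratings CSV.
#' @return List with `snr` and (optionally) `ratings`.
#' @export
load_real_data <- function(snr_csv, ratings_csv = NULL) {
  out <- list(snr = read_snr_table(snr_csv))
  if (!is.null(ratings_csv)) out$ratings <- read_ratings_table(ratings_csv)
  out
}

#' Write per-trial metadata alongside an EDF file
#'
#' @param epochs An `epoch_set`.
#' @param path CSV path.
#' @export
write_trial_meta <- function(epochs, path) {
  utils::write.csv(epochs$trial_meta, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_meta
#' @export
read_trial_meta <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
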