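#' Parcellated region-by-time BOLD-like series
#'
#' The basic data container of the package: one subject-session's signal
#' matrix (rows = time points sampled every `tr_seconds`, columns = brain
#' regions), together with identifying metadata.
#'
#' @param values numeric matrix, time x region; no missing values.
#' @param tr_seconds sampling interval (repetition time) in seconds.
#' @param region_labels character vector, one label per column. Defaults to
#'   `R1..Rn`.
#' @param subject_id,session_label,group_label identifying metadata strings.
#' @return an object of class `parcellated_ts`.
#' @export
parcellated_ts <- function(values, tr_seconds, region_labels = NULL,
                           subject_id = NA_character_,
                           session_label = NA_character_,
                           group_label = NA_character_) {
  values <- as.matrix(values)
  if (!is.numeric(values) || anyNA(values)) {
    stop_invalid("time series must be a numeric matrix without missing values")
  }
  if (ncol(values) < 2L) stop_invalid("need at least 2 regions")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0) {
    stop_invalid("tr_seconds must be a positive scalar")
  }
  if (is.null(region_labels)) region_labels <- paste0("R", seq_len(ncol(values)))
  if (length(region_labels) != ncol(values)) {
    stop_invalid("region_labels length (", length(region_labels),
                 ") does not match region count (", ncol(values), ")")
  }
  colnames(values) <- region_labels
  structure(
    list(values = values, tr_seconds = tr_seconds,
         region_labels = as.character(region_labels),
         subject_id = subject_id, session_label = session_label,
         group_label = group_label),
    class = "parcellated_ts"
  )
}

#' @export
print.parcellated_ts <- function(x, ...) {
  cat(sprintf(
    "<parcellated_ts> %d time points x %d regions, TR = %g s (%s / %s / %s)\n",
    nrow(x$values), ncol(x$values), x$tr_seconds,
    x$group_label, x$subject_id, x$session_label))
  invisible(x)
}

#' @export
dim.parcellated_ts <- function(x) dim(x$values)

n_regions <- function(ts) ncol(ts$values)
n_timepoints <- function(ts) nrow(ts$values)
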