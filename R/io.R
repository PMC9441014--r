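#' Read and write parcellated time-series CSVs
#'
#' The on-disk format is a plain CSV with one row per time point and a header
#' of region names. On reading, the header is checked against the
#' parcellation table: a mismatch in the set of names is a schema error; a
#' mere difference in order is tolerated, with the columns reordered to the
#' parcellation order (a message notes it). Values round-trip exactly.
#'
#' @param path CSV file path.
#' @param parcellation parcellation data frame (see [read_parcellation()]).
#' @param tr_seconds sampling interval of the stored series.
#' @param subject_id,session_label,group_label metadata attached to the
#'   returned object.
#' @return a [parcellated_ts].
#' @export
read_timeseries <- function(path, parcellation, tr_seconds,
                            subject_id = NA_character_,
                            session_label = NA_character_,
                            group_label = NA_character_) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  bad <- !vapply(df, is.numeric, logical(1))
  if (any(bad)) {
    stop_invalid("non-numeric values in column(s): ",
                 paste(names(df)[bad], collapse = ", "), " of ", path)
  }
  have <- names(df)
  want <- parcellation$name
  if (!setequal(have, want) || length(have) != length(want)) {
    missing <- setdiff(want, have)
    extra <- setdiff(have, want)
    stop_invalid(
      "columns of ", path, " do not match the parcellation",
      if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
      if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")))
  }
  if (!identical(have, want)) {
    message("reordering columns of ", basename(path), " to parcellation order")
    df <- df[, want]
  }
  parcellated_ts(as.matrix(df), tr_seconds, region_labels = want,
                 subject_id = subject_id, session_label = session_label,
                 group_label = group_label)
}

#' @rdname read_timeseries
#' @param ts a [parcellated_ts] to write.
#' @export
write_timeseries <- function(ts, path, parcellation = NULL) {
  stopifnot(inherits(ts, "parcellated_ts"))
  df <- as.data.frame(ts$values)
  if (!is.null(parcellation)) names(df) <- parcellation$name
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a square structural-connectivity matrix (header-free CSV)
#'
#' @param path CSV file path.
#' @return a symmetric nonnegative numeric matrix.
#' @export
read_sc_matrix <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m)) stop_invalid(path, " is not square")
  if (any(m < 0)) stop_invalid(path, " has negative entries")
  (m + t(m)) / 2
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return a list with `dataset`, `sc_matrices`, `parcellation`, `manifest`.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  parcellation <- read_parcellation(file.path(dir, "parcellation.tsv"))
  tr <- manifest$tr_seconds
  dataset <- list()
  for (grp in list.dirs(file.path(dir, "cohort"), recursive = FALSE)) {
    for (sub in list.dirs(grp, recursive = FALSE)) {
      for (f in list.files(sub, pattern = "\\.csv$", full.names = TRUE)) {
        ses <- sub("\\.csv$", "", basename(f))
        sid <- basename(sub)
        dataset[[paste(sid, ses, sep = "_")]] <-
          read_timeseries(f, parcellation, tr, subject_id = sid,
                          session_label = ses, group_label = basename(grp))
      }
    }
  }
  sc_files <- list.files(file.path(dir, "sc"), pattern = "\\.csv$",
                         full.names = TRUE)
  sc <- lapply(sc_files, read_sc_matrix)
  names(sc) <- sub("\\.csv$", "", basename(sc_files))
  list(dataset = dataset, sc_matrices = sc, parcellation = parcellation,
       manifest = manifest)
}

#' Serialise a fitted MOU model to a directory of plain-text files
#'
#' Writes `<stem>_ec.csv`, `<stem>_sigma.csv` and `<stem>_meta.json` (tau and
#' the fit report, if given).
#'
#' @param model a [mou_model].
#' @param dir output directory.
#' @param stem file-name stem, typically `<subject>_<session>`.
#' @param report optional fit report to store alongside.
#' @return the stem path, invisibly.
#' @export
write_mou_model <- function(model, dir, stem, report = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(model$ec, file.path(dir, paste0(stem, "_ec.csv")),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(matrix(model$sigma, ncol = 1),
                     file.path(dir, paste0(stem, "_sigma.csv")),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  meta <- list(tau_seconds = model$tau_seconds)
  if (!is.null(report)) {
    meta$fit <- list(iterations = report$iterations,
                     best_error = report$best_error,
                     best_pearson_r = report$best_pearson_r,
                     converged = report$converged)
  }
  jsonlite::write_json(meta, file.path(dir, paste0(stem, "_meta.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, stem))
}
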