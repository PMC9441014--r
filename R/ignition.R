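#' Instantaneous phases of band-limited signals
#'
#' Band-passes the series (default 0.04-0.07 Hz, second-order zero-phase
#' Butterworth), demeans it, and takes the angle of the analytic signal
#' (frequency-domain Hilbert transform).
#'
#' @param ts a [parcellated_ts].
#' @param band pass band in Hz.
#' @return an object of class `phase_series`: `phases` (time x region, in
#'   (-pi, pi]), `band_hz`, `tr_seconds`.
#' @export
instantaneous_phases <- function(ts, band = c(0.04, 0.07)) {
  filtered <- bandpass(ts, band[1], band[2])
  ph <- apply(filtered$values, 2L, function(x) Arg(analytic_signal(x - mean(x))))
  structure(list(phases = matrix(ph, nrow = nrow(ts$values),
                                 dimnames = dimnames(ts$values)),
                 band_hz = band, tr_seconds = ts$tr_seconds),
            class = "phase_series")
}

#' Pairwise phase-locking value
#'
#' `exp(-3 d)` where `d` is the circular distance between the two phases,
#' wrapped to `[0, pi]`. Equal phases give 1; opposite phases give
#' `exp(-3 pi)`.
#'
#' @param phi_j,phi_k phases in radians (vectorised).
#' @return values in (0, 1].
#' @export
phase_lock_value <- function(phi_j, phi_k) {
  exp(-3 * wrap_phase_distance(phi_j - phi_k))
}

# Full time-resolved phase-lock matrix for one time point.
phase_lock_matrix <- function(phases_t) {
  exp(-3 * wrap_phase_distance(outer(phases_t, phases_t, `-`)))
}

#' Detect intrinsic driving events
#'
#' Each region's series is z-scored; an event is marked at every sample where
#' the z-score crosses above `threshold_sd` from at or below it (rising-edge
#' convention: one event per supra-threshold excursion). A region with zero
#' signal variance has no events and is flagged.
#'
#' @param ts a [parcellated_ts] (typically already band-passed).
#' @param threshold_sd event threshold in SD units (default 1: mean + SD of
#'   the raw signal, i.e. z = 1 after standardisation).
#' @return an object of class `event_raster`: binary `events` (time x
#'   region), `threshold_sd`, logical `flagged` per region.
#' @export
detect_events <- function(ts, threshold_sd = 1) {
  stopifnot(inherits(ts, "parcellated_ts"))
  X <- ts$values
  sds <- apply(X, 2L, sd)
  flagged <- sds == 0
  if (any(flagged)) {
    warning("region(s) with zero variance carry no events: ",
            paste(colnames(X)[flagged], collapse = ", "))
  }
  ev <- matrix(0L, nrow(X), ncol(X), dimnames = dimnames(X))
  for (j in which(!flagged)) {
    z <- (X[, j] - mean(X[, j])) / sds[j]
    up <- z > threshold_sd
    ev[which(up & !c(TRUE, up[-length(up)])), j] <- 1L
  }
  structure(list(events = ev, threshold_sd = threshold_sd, flagged = flagged),
            class = "event_raster")
}

# Size of the largest connected component of a binary adjacency matrix.
largest_component_size <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  max(igraph::components(g)$csize)
}

#' Event-triggered integration
#'
#' For each time point of the window `[event_time, event_time + window_trs)`,
#' builds the phase-lock matrix over `node_subset`, binarises it at
#' `binarize_threshold`, and takes the size of the largest connected
#' component of the resulting undirected graph. The integration value is the
#' window mean of those sizes divided by `|node_subset|`, so it lies in
#' (0, 1].
#'
#' @param phases a [instantaneous_phases()] result.
#' @param event_time index of the driving event (1-based).
#' @param node_subset region indices analysed (default: all regions).
#' @param window_trs window length in TR units (default 4).
#' @param binarize_threshold phase-lock cutoff in (0, 1) (default 0.5).
#' @return normalised integration in (0, 1], or `NA` when the window does not
#'   fit inside the series.
#' @export
integration_for_event <- function(phases, event_time, node_subset = NULL,
                                  window_trs = 4L, binarize_threshold = 0.5) {
  stopifnot(inherits(phases, "phase_series"))
  n <- ncol(phases$phases)
  if (is.null(node_subset)) node_subset <- seq_len(n)
  if (length(node_subset) == 0L) stop_invalid("node_subset must not be empty")
  if (any(node_subset < 1L | node_subset > n)) stop_invalid("node_subset out of range")
  if (event_time < 1L || event_time + window_trs - 1L > nrow(phases$phases)) {
    return(NA_real_)  # window does not fit; caller discards the event
  }
  sizes <- vapply(seq.int(event_time, event_time + window_trs - 1L),
                  function(t) {
    P <- phase_lock_matrix(phases$phases[t, node_subset])
    largest_component_size(P >= binarize_threshold)
  }, numeric(1))
  mean(sizes) / length(node_subset)
}

#' Per-region intrinsic-ignition profile
#'
#' Band-passes the series, detects driving events per region, and for every
#' event of region `r` computes the event-triggered integration
#' ([integration_for_event()]). IDMI (intrinsic-driven mean integration) is
#' the mean integration over the region's events, and metastability its
#' standard deviation; regions with fewer than 2 usable events carry `NA`
#' metastability (and `NA` IDMI when they have none) and are flagged.
#'
#' @param ts a [parcellated_ts] (raw; filtering is applied internally).
#' @param node_subset region indices analysed (default: all).
#' @param window_trs integration window in TRs (default 4).
#' @param band pass band in Hz (default 0.04-0.07).
#' @param threshold_sd event threshold in SD units.
#' @param binarize_threshold phase-lock binarisation cutoff.
#' @return an object of class `ignition_profile`: per analysed region `idmi`,
#'   `metastability`, `n_events`, plus `node_subset`, `window_trs` and the
#'   subject metadata of `ts`.
#' @export
ignition_profile <- function(ts, node_subset = NULL, window_trs = 4L,
                             band = c(0.04, 0.07), threshold_sd = 1,
                             binarize_threshold = 0.5) {
  stopifnot(inherits(ts, "parcellated_ts"))
  n <- n_regions(ts)
  if (is.null(node_subset)) node_subset <- seq_len(n)
  if (any(node_subset < 1L | node_subset > n)) stop_invalid("node_subset out of range")
  if (nrow(ts$values) < window_trs) stop_invalid("series shorter than one window")
  filtered <- bandpass(ts, band[1], band[2])
  phases <- structure(
    list(phases = apply(filtered$values, 2L,
                        function(x) Arg(analytic_signal(x - mean(x)))),
         band_hz = band, tr_seconds = ts$tr_seconds),
    class = "phase_series")
  raster <- detect_events(filtered, threshold_sd)
  k <- length(node_subset)
  idmi <- metas <- rep(NA_real_, k)
  n_events <- integer(k)
  for (i in seq_len(k)) {
    r <- node_subset[i]
    ev <- which(raster$events[, r] == 1L)
    ints <- vapply(ev, function(t) {
      integration_for_event(phases, t, node_subset, window_trs,
                            binarize_threshold)
    }, numeric(1))
    ints <- ints[!is.na(ints)]
    n_events[i] <- length(ints)
    if (length(ints) >= 1L) idmi[i] <- mean(ints)
    if (length(ints) >= 2L) metas[i] <- sd(ints)
  }
  structure(list(idmi = stats::setNames(idmi, ts$region_labels[node_subset]),
                 metastability = stats::setNames(metas, ts$region_labels[node_subset]),
                 n_events = stats::setNames(n_events, ts$region_labels[node_subset]),
                 node_subset = node_subset, window_trs = as.integer(window_trs),
                 subject_id = ts$subject_id, session_label = ts$session_label,
                 group_label = ts$group_label),
            class = "ignition_profile")
}

#' @rdname ignition_profile
#' @param idmi,metastability,n_events per-region vectors for constructing a
#'   profile directly (e.g. in simulation studies).
#' @export
new_ignition_profile <- function(idmi, metastability, n_events,
                                 node_subset = seq_along(idmi),
                                 window_trs = 4L,
                                 subject_id = NA_character_,
                                 session_label = NA_character_,
                                 group_label = NA_character_) {
  stopifnot(length(idmi) == length(metastability),
            length(idmi) == length(n_events))
  structure(list(idmi = idmi, metastability = metastability,
                 n_events = n_events, node_subset = node_subset,
                 window_trs = as.integer(window_trs),
                 subject_id = subject_id, session_label = session_label,
                 group_label = group_label),
            class = "ignition_profile")
}

#' @export
print.ignition_profile <- function(x, ...) {
  cat(sprintf(
    "<ignition_profile> %d regions, median IDMI %.3f, median metastability %.3f (%s/%s)\n",
    length(x$node_subset), stats::median(x$idmi, na.rm = TRUE),
    stats::median(x$metastability, na.rm = TRUE),
    x$subject_id, x$session_label))
  invisible(x)
}

#' Compare ignition measures between two sets of profiles
#'
#' Each profile is aggregated to its mean IDMI and mean metastability over
#' the analysed regions (undefined regions excluded); the two sets are then
#' compared per measure with a Wilcoxon signed-rank test (paired) or rank-sum
#' test (unpaired). When the paired differences are all zero the comparison
#' is reported as non-significant (p = 1).
#'
#' @param profiles_a,profiles_b lists of [ignition_profile] objects; in
#'   paired mode they must have equal length and matching subject order.
#' @param paired logical.
#' @return named list (`idmi`, `metastability`) of `comparison_result`s.
#' @export
compare_ignition <- function(profiles_a, profiles_b, paired = FALSE) {
  agg <- function(ps, field) {
    vapply(ps, function(p) mean(p[[field]], na.rm = TRUE), numeric(1))
  }
  if (paired) {
    if (length(profiles_a) != length(profiles_b)) {
      stop_invalid("paired comparison requires equally many profiles")
    }
    sa <- unname(vapply(profiles_a, `[[`, character(1), "subject_id"))
    sb <- unname(vapply(profiles_b, `[[`, character(1), "subject_id"))
    if (!any(is.na(sa)) && !any(is.na(sb)) && !identical(sa, sb)) {
      stop_invalid("paired comparison requires matching subject order")
    }
  }
  out <- lapply(c(idmi = "idmi", metastability = "metastability"),
                function(field) {
    xa <- agg(profiles_a, field)
    xb <- agg(profiles_b, field)
    ok <- is.finite(xa) & is.finite(xb)
    if (paired) {
      d <- xa[ok] - xb[ok]
      if (all(d == 0)) {
        return(structure(list(statistic = NA_real_, p_value = 1,
                              direction = "tie"),
                         class = "comparison_result"))
      }
      wt <- suppressWarnings(wilcox.test(xa[ok], xb[ok], paired = TRUE,
                                         exact = FALSE))
    } else {
      wt <- suppressWarnings(wilcox.test(xa[ok], xb[ok], exact = FALSE))
    }
    structure(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                   direction = if (mean(xa[ok]) > mean(xb[ok])) "a"
                               else if (mean(xa[ok]) < mean(xb[ok])) "b"
                               else "tie"),
              class = "comparison_result")
  })
  out
}
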