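#' Binary structural-connectivity mask
#'
#' Wraps a binary region x region matrix marking which directed connections
#' the effective-connectivity model is allowed to use, together with the
#' realised density (nonzero off-diagonal entries / n(n-1)).
#'
#' @param mask binary (0/1) square matrix with zero diagonal.
#' @return an object of class `sc_mask`.
#' @export
sc_mask <- function(mask) {
  mask <- as.matrix(mask)
  if (nrow(mask) != ncol(mask)) stop_invalid("mask must be square")
  if (any(mask != 0 & mask != 1)) stop_invalid("mask entries must be 0 or 1")
  if (any(diag(mask) != 0)) stop_invalid("mask diagonal must be zero")
  n <- nrow(mask)
  structure(list(mask = mask, density = sum(mask) / (n * (n - 1))),
            class = "sc_mask")
}

#' @export
print.sc_mask <- function(x, ...) {
  cat(sprintf("<sc_mask> %d regions, %d directed entries (density %.3f)%s\n",
              nrow(x$mask), sum(x$mask), x$density,
              if (isSymmetric(x$mask)) ", symmetric" else ""))
  invisible(x)
}

#' Zero-phase band-pass filtering of a parcellated time series
#'
#' Applies a second-order Butterworth band-pass filter forward and backward
#' (`signal::filtfilt`), so the output has no phase shift. Each region is
#' demeaned before filtering.
#'
#' @param ts a [parcellated_ts].
#' @param low_hz,high_hz pass-band edges in Hz; must satisfy
#'   `0 < low < high < 1/(2 tr)` (Nyquist).
#' @param order Butterworth section order (default 2).
#' @return a filtered [parcellated_ts] of the same shape.
#' @export
bandpass <- function(ts, low_hz, high_hz, order = 2L) {
  stopifnot(inherits(ts, "parcellated_ts"))
  nyq <- 1 / (2 * ts$tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop_invalid(sprintf(
      "band (%g, %g) Hz must satisfy 0 < low < high < Nyquist (%g Hz)",
      low_hz, high_hz, nyq))
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  vals <- apply(ts$values, 2L, function(x) {
    signal::filtfilt(bf, x - mean(x))
  })
  out <- ts
  out$values <- matrix(vals, nrow = nrow(ts$values),
                       dimnames = dimnames(ts$values))
  out
}

#' Empirical zero-lag and lagged covariance matrices (FC0, FC1)
#'
#' Computes the pair of spatial covariance matrices the MOU model is fitted
#' to: `q0[j,k] = cov(x_j(t), x_k(t))` and
#' `q1[j,k] = cov(x_j(t), x_k(t + lag))`. Series are demeaned per region and
#' covariances normalised by `T - 1`.
#'
#' @param ts a [parcellated_ts].
#' @param lag_trs positive integer lag, in TR units (default 1).
#' @return an object of class `cov_pair` with fields `q0`, `q1`, `lag_trs`,
#'   `tr_seconds`.
#' @export
covariance_pair <- function(ts, lag_trs = 1L) {
  stopifnot(inherits(ts, "parcellated_ts"))
  lag_trs <- as.integer(lag_trs)
  if (lag_trs < 1L) stop_invalid("lag_trs must be >= 1")
  T <- n_timepoints(ts)
  if (T <= lag_trs + 2L) {
    stop_invalid("insufficient data: need more than lag_trs + 2 time points")
  }
  X <- scale(ts$values, center = TRUE, scale = FALSE)
  q0 <- crossprod(X) / (T - 1)
  q0 <- (q0 + t(q0)) / 2          # exact symmetry despite roundoff
  q1 <- crossprod(X[seq_len(T - lag_trs), , drop = FALSE],
                  X[(1 + lag_trs):T, , drop = FALSE]) / (T - 1)
  cov_pair(q0, q1, lag_trs, ts$tr_seconds)
}

#' @rdname covariance_pair
#' @param q0,q1 covariance matrices (q0 symmetric).
#' @param tr_seconds sampling interval in seconds.
#' @export
cov_pair <- function(q0, q1, lag_trs = 1L, tr_seconds = 1) {
  q0 <- as.matrix(q0); q1 <- as.matrix(q1)
  stopifnot(nrow(q0) == ncol(q0), all(dim(q0) == dim(q1)))
  if (!isSymmetric(unname(q0), tol = 1e-8)) stop_invalid("q0 must be symmetric")
  structure(list(q0 = q0, q1 = q1, lag_trs = as.integer(lag_trs),
                 tr_seconds = tr_seconds),
            class = "cov_pair")
}

#' Estimate the MOU decay time constant from the autocovariance
#'
#' Per region, the autocovariance of an Ornstein-Uhlenbeck process decays as
#' `exp(-lag * tr / tau)`. The estimate is the average, over regions whose
#' autocovariances at all used lags are positive, of the ordinary
#' least-squares slope of `log a(lag)` against the lag (in TR units):
#' `tau = -tr / slope`.
#'
#' @param ts a [parcellated_ts].
#' @param max_lag_trs largest lag used (lags `1..max_lag_trs`); must be >= 2
#'   so the slope is identified.
#' @return estimated time constant in seconds.
#' @export
estimate_tau <- function(ts, max_lag_trs = 2L) {
  stopifnot(inherits(ts, "parcellated_ts"))
  max_lag_trs <- as.integer(max_lag_trs)
  if (max_lag_trs < 2L) stop_invalid("max_lag_trs must be >= 2 (slope needs at least 2 lags)")
  T <- n_timepoints(ts)
  if (T <= max_lag_trs + 2L) stop_invalid("series too short for requested lags")
  X <- scale(ts$values, center = TRUE, scale = FALSE)
  lags <- seq_len(max_lag_trs)
  ac <- vapply(lags, function(k) {
    colSums(X[seq_len(T - k), , drop = FALSE] *
              X[(1 + k):T, , drop = FALSE]) / (T - 1)
  }, numeric(ncol(X)))          # regions x lags
  ac <- matrix(ac, ncol = max_lag_trs)
  usable <- apply(ac > 0, 1L, all)
  if (!any(usable)) {
    stop_invalid("autocovariance non-positive at a used lag for every region; cannot estimate tau")
  }
  lbar <- mean(lags)
  slopes <- apply(log(ac[usable, , drop = FALSE]), 1L, function(y) {
    sum((lags - lbar) * (y - mean(y))) / sum((lags - lbar)^2)
  })
  slope <- mean(slopes)
  if (slope >= 0) stop_invalid("autocovariance does not decay; cannot estimate tau")
  -ts$tr_seconds / slope
}

#' Build a binary SC mask by density thresholding
#'
#' Average mode: element-wise mean of the supplied structural matrices, then
#' keep the top fraction `density` of undirected pairs by weight (ties broken
#' deterministically towards the lexicographically smallest (row, column)
#' pair), returned as a symmetric binary mask. Pairs with non-positive mean
#' weight are never retained. Intersection mode: `sc_list` is a list of
#' groups (each a list of matrices); one average-mode mask is built per group
#' and their element-wise AND returned.
#'
#' @param sc_list list of symmetric nonnegative matrices (average mode), or a
#'   list of such lists, one per group (intersection mode).
#' @param density fraction of undirected pairs to retain, in (0, 1].
#' @param mode `"average"` or `"intersection"`.
#' @return an [sc_mask].
#' @export
build_sc_mask <- function(sc_list, density, mode = c("average", "intersection")) {
  mode <- match.arg(mode)
  if (length(sc_list) == 0L) stop_invalid("sc_list must not be empty")
  if (!(density > 0 && density <= 1)) stop_invalid("density must be in (0, 1]")
  if (mode == "intersection") {
    masks <- lapply(sc_list, build_sc_mask, density = density, mode = "average")
    m <- Reduce(`*`, lapply(masks, `[[`, "mask"))
    return(sc_mask(m))
  }
  sc_list <- lapply(sc_list, as.matrix)
  n <- nrow(sc_list[[1L]])
  if (!all(vapply(sc_list, function(m) all(dim(m) == n), logical(1)))) {
    stop_invalid("all SC matrices must be square and of equal size")
  }
  avg <- Reduce(`+`, sc_list) / length(sc_list)
  avg <- (avg + t(avg)) / 2
  ut <- which(upper.tri(avg), arr.ind = TRUE)
  w <- avg[ut]
  keep_n <- round(density * n * (n - 1) / 2)
  # order: weight descending, then (row, col) ascending for deterministic ties
  ord <- order(-w, ut[, 1L], ut[, 2L])
  ord <- ord[w[ord] > 0]
  keep <- head(ord, keep_n)
  m <- matrix(0, n, n)
  m[ut[keep, , drop = FALSE]] <- 1
  m <- m + t(m)
  dimnames(m) <- dimnames(avg)
  sc_mask(m)
}
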