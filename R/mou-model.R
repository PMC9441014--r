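#' Multivariate Ornstein-Uhlenbeck (MOU) network model
#'
#' The generative model for parcellated resting-state activity:
#' `dx = (-x/tau + t(C) x) dt + dB`, where `C = ec` is the directed
#' effective-connectivity matrix (`ec[j, k]` = influence of region `j` on
#' region `k`, nonnegative, zero on the diagonal and wherever the SC mask is
#' zero) and `dB` is white noise with diagonal covariance `diag(sigma)`.
#'
#' The Jacobian of the deterministic drift is `J = -I/tau + t(ec)` (it maps
#' `ec[j, k]` to `J[k, j]`, so that region `k`'s rate of change receives
#' `ec[j, k] * x_j`). The model is stable iff every eigenvalue of `J` has a
#' negative real part.
#'
#' @param ec nonnegative matrix of directed weights, zero diagonal, zero
#'   off-mask.
#' @param sigma vector of per-region noise variances (diagonal of Sigma), all
#'   positive.
#' @param tau_seconds decay time constant in seconds.
#' @param mask an [sc_mask] constraining the support of `ec`.
#' @param check_stability if `TRUE` (default) fail on an unstable model.
#' @return an object of class `mou_model`.
#' @export
mou_model <- function(ec, sigma, tau_seconds, mask = NULL,
                      check_stability = TRUE) {
  ec <- as.matrix(ec)
  n <- nrow(ec)
  stopifnot(ncol(ec) == n)
  if (any(ec < 0)) stop_invalid("ec weights must be nonnegative")
  if (any(diag(ec) != 0)) stop_invalid("ec diagonal must be zero")
  if (is.null(mask)) {
    mask <- sc_mask((ec > 0) * 1)
  }
  stopifnot(inherits(mask, "sc_mask"), nrow(mask$mask) == n)
  if (any(ec[mask$mask == 0] != 0)) stop_invalid("ec has weight outside the SC mask")
  sigma <- as.numeric(sigma)
  if (length(sigma) == 1L) sigma <- rep(sigma, n)
  if (length(sigma) != n || any(sigma <= 0)) {
    stop_invalid("sigma must be ", n, " positive noise variances")
  }
  if (!is.numeric(tau_seconds) || tau_seconds <= 0) {
    stop_invalid("tau_seconds must be positive")
  }
  m <- structure(list(ec = unname(ec), sigma = sigma,
                      tau_seconds = tau_seconds, mask = mask),
                 class = "mou_model")
  if (check_stability && !is_stable(m)) {
    stop_invalid("unstable MOU model: spectral abscissa of the Jacobian is ",
                 signif(spectral_abscissa(m), 4), " (must be < 0)")
  }
  m
}

#' @rdname mou_model
#' @param model a `mou_model`.
#' @export
mou_jacobian <- function(model) {
  J <- t(model$ec)
  diag(J) <- -1 / model$tau_seconds
  J
}

#' @rdname mou_model
#' @export
spectral_abscissa <- function(model) {
  J <- if (inherits(model, "mou_model")) mou_jacobian(model) else as.matrix(model)
  max(Re(eigen(J, only.values = TRUE)$values))
}

#' @rdname mou_model
#' @export
is_stable <- function(model) spectral_abscissa(model) < 0

#' @export
print.mou_model <- function(x, ...) {
  cat(sprintf(
    "<mou_model> %d regions, %d directed connections, tau = %.3g s, spectral abscissa %.4g\n",
    nrow(x$ec), sum(x$ec > 0), x$tau_seconds, spectral_abscissa(x)))
  invisible(x)
}

#' Solve the continuous Lyapunov equation J Q + Q J' + S = 0
#'
#' Uses the eigendecomposition of `J` (valid for any stable, diagonalisable
#' `J`); falls back to the Kronecker-product linear system when `J` is close
#' to defective.
#'
#' @param J stable square matrix (all eigenvalue real parts negative).
#' @param S symmetric source matrix.
#' @return the unique symmetric solution `Q`.
#' @export
solve_lyapunov <- function(J, S) {
  J <- as.matrix(J); S <- as.matrix(S)
  n <- nrow(J)
  e <- eigen(J)
  lam <- e$values
  if (max(Re(lam)) >= 0) stop_invalid("J is not stable; Lyapunov solution undefined")
  V <- e$vectors
  Vi <- tryCatch(solve(V), error = function(err) NULL)
  if (!is.null(Vi)) {
    Sp <- Vi %*% S %*% t(Vi)
    M <- -Sp / outer(lam, lam, `+`)
    Q <- Re(V %*% M %*% t(V))
  } else {
    # defective J: dense Kronecker solve (small systems only)
    if (n > 60) stop_invalid("J is defective; Lyapunov solve not supported at this size")
    A <- kronecker(diag(n), J) + kronecker(J, diag(n))
    Q <- matrix(solve(A, -as.vector(S)), n, n)
  }
  (Q + t(Q)) / 2
}

#' Model covariance matrices of a MOU process
#'
#' The stationary zero-lag covariance `q0` solves the continuous Lyapunov
#' equation `J q0 + q0 J' + Sigma = 0`; the lagged covariance is
#' `q1 = q0 expm(J' * lag)` with the lag expressed in seconds
#' (`lag_trs * tr_seconds`).
#'
#' @param model a stable [mou_model].
#' @param lag_trs lag in TR units (default 1).
#' @param tr_seconds sampling interval in seconds.
#' @return a [cov_pair].
#' @export
model_covariances <- function(model, lag_trs = 1L, tr_seconds = 1) {
  stopifnot(inherits(model, "mou_model"))
  J <- mou_jacobian(model)
  if (max(Re(eigen(J, only.values = TRUE)$values)) >= 0) {
    stop_invalid("unstable model: covariances are not defined")
  }
  q0 <- solve_lyapunov(J, diag(model$sigma))
  Et <- as.matrix(Matrix::expm(t(J) * lag_trs * tr_seconds))
  q1 <- q0 %*% Et
  cov_pair(q0, q1, lag_trs, tr_seconds)
}

#' One Lyapunov gradient-descent step of the MOU fit
#'
#' Given the model's current covariances and the empirical ones, computes the
#' covariance deviations `DQ0 = q0_emp - q0_model`, `DQt = q1_emp - q1_model`
#' and the Jacobian update `DJ' = q0^{-1} (DQ0 + t(DQt) expm(-J' lag))`; the EC
#' weights move by `rate_ec` along `DJ` (the transpose of the computed
#' matrix, restricted to the SC mask and clipped at zero) and the noise
#' variances by `rate_sigma` along `diag(-J' DQ0 - DQ0 J)` (clipped at
#' `sigma_floor`).
#'
#' @param model current [mou_model].
#' @param emp empirical [cov_pair] (carries the lag and TR).
#' @param rate_ec,rate_sigma learning rates.
#' @param sigma_floor lower clip for noise variances.
#' @return a list with elements `model` (the updated model, stability
#'   unchecked) and `model_error`, the normalised error of the *input* model
#'   (sum of squared deviations of q0 and q1 over the summed squared
#'   empirical entries).
#' @export
lyapunov_step <- function(model, emp, rate_ec = 5e-4, rate_sigma = 0.05,
                          sigma_floor = 1e-6) {
  stopifnot(inherits(model, "mou_model"), inherits(emp, "cov_pair"))
  J <- mou_jacobian(model)
  lag_s <- emp$lag_trs * emp$tr_seconds
  mc <- model_covariances(model, emp$lag_trs, emp$tr_seconds)
  dq0 <- emp$q0 - mc$q0
  dq1 <- emp$q1 - mc$q1
  err <- (sum(dq0^2) + sum(dq1^2)) / (sum(emp$q0^2) + sum(emp$q1^2))

  Em <- as.matrix(Matrix::expm(-t(J) * lag_s))
  # the lagged deviation enters in the (t+lag, t) orientation, matching the
  # lag convention under which the update's fixed point is the true model
  rhs <- dq0 + t(dq1) %*% Em
  dJt <- tryCatch(solve(mc$q0, rhs), error = function(e) NULL)
  if (is.null(dJt)) dJt <- MASS::ginv(mc$q0) %*% rhs  # pseudo-inverse fallback

  ec <- model$ec + rate_ec * t(dJt) * model$mask$mask
  ec[ec < 0] <- 0
  dsig <- diag(-t(J) %*% dq0 - dq0 %*% J)
  sigma <- pmax(model$sigma + rate_sigma * dsig, sigma_floor)
  new_model <- mou_model(ec, sigma, model$tau_seconds, model$mask,
                         check_stability = FALSE)
  list(model = new_model, model_error = err)
}

#' Goodness of fit of a MOU model against empirical covariances
#'
#' Pearson correlation between model and empirical covariances, computed over
#' the concatenation of the lower triangle (including the diagonal) of q0 and
#' the full q1, plus the normalised model error used by the optimiser.
#'
#' @param model a stable [mou_model].
#' @param emp empirical [cov_pair].
#' @return list with `pearson_r` and `model_error`.
#' @export
fit_quality <- function(model, emp) {
  mc <- model_covariances(model, emp$lag_trs, emp$tr_seconds)
  lt <- lower.tri(emp$q0, diag = TRUE)
  v_emp <- c(emp$q0[lt], as.vector(emp$q1))
  v_mod <- c(mc$q0[lt], as.vector(mc$q1))
  if (sd(v_emp) == 0) stop_invalid("empirical covariances have zero variance; correlation undefined")
  err <- (sum((emp$q0 - mc$q0)^2) + sum((emp$q1 - mc$q1)^2)) /
    (sum(emp$q0^2) + sum(emp$q1^2))
  list(pearson_r = cor(v_mod, v_emp), model_error = err)
}
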