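#' Optimiser settings for [fit_mou()]
#'
#' @param rate_ec learning rate for the EC weights.
#' @param rate_sigma learning rate for the noise variances.
#' @param max_iter maximum number of gradient iterations.
#' @param patience stop when the best error has not improved for this many
#'   consecutive iterations.
#' @param sigma_floor lower clip for noise variances.
#' @return a list of class `fit_opts`.
#' @export
fit_opts <- function(rate_ec = 5e-4, rate_sigma = 0.05, max_iter = 10000L,
                     patience = 2000L, sigma_floor = 1e-6) {
  stopifnot(rate_ec > 0, rate_sigma > 0, max_iter >= 1, patience >= 1,
            sigma_floor > 0)
  structure(list(rate_ec = rate_ec, rate_sigma = rate_sigma,
                 max_iter = as.integer(max_iter),
                 patience = as.integer(patience), sigma_floor = sigma_floor),
            class = "fit_opts")
}

#' Fit a MOU model to empirical covariances by Lyapunov gradient descent
#'
#' Starting from `C = 0` and noise variances matching the empirical signal
#' variances (`sigma_i = 2 q0[i,i] / tau`, the stationary variance of an
#' uncoupled Ornstein-Uhlenbeck node), repeats [lyapunov_step()] until the
#' model error stops improving for `opts$patience` iterations or `max_iter`
#' is reached, and returns the best-error iterate. The EC support is
#' restricted to `mask` and weights are kept nonnegative throughout.
#'
#' @param emp empirical [cov_pair] (e.g. from [covariance_pair()] on a
#'   band-passed series).
#' @param mask an [sc_mask]; only masked entries of `ec` are optimised.
#' @param tau_init time constant in seconds, typically from [estimate_tau()];
#'   held fixed during the optimisation.
#' @param opts a [fit_opts()] list.
#' @param engine `"cpp"` (compiled loop, default) or `"r"` (reference loop
#'   built on [lyapunov_step()]; identical arithmetic, much slower).
#' @return list with `model` (the fitted [mou_model]) and `report`
#'   (iterations, model_error_history, best_pearson_r, converged flag).
#' @export
fit_mou <- function(emp, mask, tau_init, opts = fit_opts(),
                    engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(emp, "cov_pair"), inherits(mask, "sc_mask"),
            inherits(opts, "fit_opts"))
  n <- nrow(emp$q0)
  if (nrow(mask$mask) != n) stop_invalid("mask size does not match covariance size")
  if (any(diag(emp$q0) <= 0)) {
    stop_invalid("empirical q0 must have positive diagonal entries")
  }
  if (!is.numeric(tau_init) || tau_init <= 0) stop_invalid("tau_init must be positive")
  sigma0 <- pmax(2 * diag(emp$q0) / tau_init, opts$sigma_floor)
  lag_s <- emp$lag_trs * emp$tr_seconds

  if (engine == "cpp") {
    res <- .mou_fit_core(emp$q0, emp$q1, mask$mask, tau_init, lag_s, sigma0,
                         opts$rate_ec, opts$rate_sigma, opts$sigma_floor,
                         opts$max_iter, opts$patience)
  } else {
    res <- fit_mou_r(emp, mask, tau_init, sigma0, opts)
  }
  if (isTRUE(res$diverged)) {
    stop_invalid("MOU fit diverged; last stable iterate at iteration ",
                 res$best_iter)
  }
  model <- mou_model(res$ec, as.numeric(res$sigma), tau_init, mask,
                     check_stability = FALSE)
  report <- structure(
    list(iterations = res$iterations,
         model_error_history = as.numeric(res$error_history),
         best_error = res$best_error,
         best_iter = res$best_iter,
         best_pearson_r = res$best_pearson_r,
         converged = isTRUE(res$converged),
         pinv_used = isTRUE(res$pinv_used)),
    class = "mou_fit_report")
  list(model = model, report = report)
}

#' @export
print.mou_fit_report <- function(x, ...) {
  cat(sprintf(
    "<mou_fit_report> %d iterations, best error %.4g (iter %d), best r %.4f%s\n",
    x$iterations, x$best_error, x$best_iter, x$best_pearson_r,
    if (x$converged) ", converged" else ""))
  invisible(x)
}

# Pure-R reference implementation of the optimisation loop; shares its step
# arithmetic with lyapunov_step() so the compiled engine can be validated
# against it.
fit_mou_r <- function(emp, mask, tau, sigma0, opts) {
  model <- mou_model(matrix(0, nrow(emp$q0), ncol(emp$q0)), sigma0, tau, mask)
  lt <- lower.tri(emp$q0, diag = TRUE)
  v_emp <- c(emp$q0[lt], as.vector(emp$q1))
  best <- list(model = model, err = Inf, iter = 0L)
  best_r <- -2
  since_best <- 0L
  err_hist <- numeric(0)
  err0 <- NA_real_
  diverge_run <- 0L
  converged <- FALSE
  diverged <- FALSE
  it <- 0L
  while (it < opts$max_iter) {
    if (!is_stable(model)) {
      model <- best$model
      opts$rate_ec <- opts$rate_ec / 2
      if (opts$rate_ec < 1e-12) break
      next
    }
    mc <- model_covariances(model, emp$lag_trs, emp$tr_seconds)
    v_mod <- c(mc$q0[lt], as.vector(mc$q1))
    if (sd(v_mod) > 0) best_r <- max(best_r, cor(v_mod, v_emp))
    stepped <- lyapunov_step(model, emp, opts$rate_ec, opts$rate_sigma,
                             opts$sigma_floor)
    err <- stepped$model_error
    err_hist <- c(err_hist, err)
    if (is.na(err0)) err0 <- err
    if (err > max(10 * err0, 2 * best$err)) {
      model <- best$model
      opts$rate_ec <- opts$rate_ec / 2
      opts$rate_sigma <- opts$rate_sigma / 2
      diverge_run <- diverge_run + 1L
      if (diverge_run >= 100L) { diverged <- TRUE; break }
      if (opts$rate_ec < 1e-12) break
      next
    }
    if (err < best$err) {
      best <- list(model = model, err = err, iter = it)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best > opts$patience) { converged <- TRUE; break }
    }
    model <- stepped$model
    it <- it + 1L
  }
  list(ec = best$model$ec, sigma = best$model$sigma,
       error_history = err_hist, best_error = best$err,
       best_iter = best$iter, best_pearson_r = best_r,
       iterations = length(err_hist), converged = converged,
       diverged = diverged, pinv_used = FALSE)
}
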