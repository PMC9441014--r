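#' Specification of a synthetic two-group, two-session cohort
#'
#' Describes the study design the generator emulates: two groups (a trained
#' group whose post-session effective connectivity differs at a known set of
#' edges, and a control group whose two sessions are statistically
#' identical), a common sparse structural skeleton, and MOU dynamics sampled
#' at the scanner repetition time. Defaults mirror a neurofeedback-style
#' resting-state study: 17 + 16 subjects, 116 regions, TR = 2 s, 235 volumes
#' per session, 30%-density structural skeleton, 5 perturbed edges.
#'
#' @param n_group_a,n_group_b subjects per group (group A is the perturbed
#'   one).
#' @param n_regions number of parcellated regions.
#' @param sessions_per_subject currently fixed at 2 (pre/post).
#' @param tr_seconds repetition time in seconds.
#' @param n_volumes time points per session.
#' @param sc_density density of the undirected structural skeleton, in (0,1].
#' @param n_perturbed_edges number of directed edges (drawn from the skeleton)
#'   whose weight changes between sessions in group A; ignored when
#'   `perturbed_edges` is given.
#' @param perturbed_edges optional integer matrix/2-column data frame of
#'   (source, target) region indices; must lie inside the generated mask.
#' @param perturbation_scale effect size: multiplicative mode multiplies each
#'   perturbed weight by `1 + perturbation_scale`; additive mode adds
#'   `perturbation_scale` to it.
#' @param perturbation_mode `"multiplicative"` (default; keeps the mask
#'   support unchanged) or `"additive"`.
#' @param tau_seconds MOU decay time constant of the generating models.
#' @param dt_seconds Euler-Maruyama integration step (default `tr/20`).
#' @param subject_jitter relative spread of subject-specific edge weights
#'   around the shared group template (0.2 = +/-20%), mirroring the high
#'   between-subject similarity of real connectomes.
#' @param seed integer seed; every subject-session derives its own stream.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_group_a = 17L, n_group_b = 16L, n_regions = 116L,
                        sessions_per_subject = 2L, tr_seconds = 2,
                        n_volumes = 235L, sc_density = 0.30,
                        n_perturbed_edges = 5L, perturbed_edges = NULL,
                        perturbation_scale = 20,
                        perturbation_mode = c("multiplicative", "additive"),
                        tau_seconds = 2, dt_seconds = tr_seconds / 20,
                        subject_jitter = 0.2, seed = 1L) {
  perturbation_mode <- match.arg(perturbation_mode)
  if (n_regions < 2L) stop_invalid("n_regions must be >= 2")
  if (n_volumes <= 10L) stop_invalid("n_volumes must be > 10")
  if (!(sc_density > 0 && sc_density <= 1)) stop_invalid("sc_density must be in (0, 1]")
  if (sc_density * n_regions * (n_regions - 1) < 1) {
    stop_invalid("sc_density too low: the skeleton would hold no edge")
  }
  if (sessions_per_subject != 2L) stop_invalid("only the pre/post (2-session) design is supported")
  if (!is.null(perturbed_edges)) {
    perturbed_edges <- as.matrix(perturbed_edges)
    if (ncol(perturbed_edges) != 2L) stop_invalid("perturbed_edges needs 2 columns (source, target)")
  }
  structure(list(
    n_group_a = as.integer(n_group_a), n_group_b = as.integer(n_group_b),
    n_regions = as.integer(n_regions),
    sessions_per_subject = as.integer(sessions_per_subject),
    tr_seconds = tr_seconds, n_volumes = as.integer(n_volumes),
    sc_density = sc_density,
    n_perturbed_edges = as.integer(n_perturbed_edges),
    perturbed_edges = perturbed_edges,
    perturbation_scale = perturbation_scale,
    perturbation_mode = perturbation_mode,
    tau_seconds = tau_seconds, dt_seconds = dt_seconds,
    subject_jitter = subject_jitter,
    seed = as.integer(seed)), class = "cohort_spec")
}

#' Random binary structural-connectivity skeleton
#'
#' Draws a zero-diagonal binary mask at the requested density. In symmetric
#' mode, `round(density * n(n-1)/2)` undirected pairs are retained (each
#' contributing two directed entries); otherwise `round(density * n(n-1))`
#' directed entries.
#'
#' @param n_regions number of regions (>= 2).
#' @param density fraction of (un)directed connections retained, in (0, 1].
#' @param symmetric draw undirected pairs (default) or directed entries.
#' @param seed integer seed.
#' @return an [sc_mask].
#' @export
random_sc_mask <- function(n_regions, density, symmetric = TRUE, seed = 1L) {
  if (n_regions < 2L) stop_invalid("n_regions must be >= 2")
  if (!(density > 0 && density <= 1)) stop_invalid("density must be in (0, 1]")
  n <- as.integer(n_regions)
  m <- matrix(0, n, n)
  with_seed(seed, {
    if (symmetric) {
      pairs <- which(upper.tri(m))
      k <- round(density * n * (n - 1) / 2)
      sel <- if (k >= length(pairs)) pairs else sample(pairs, k)
      m[sel] <- 1
      m <- m + t(m)
    } else {
      cells <- which(row(m) != col(m))
      k <- round(density * n * (n - 1))
      sel <- if (k >= length(cells)) cells else sample(cells, k)
      m[sel] <- 1
    }
  })
  sc_mask(m)
}

#' Forward simulation of a MOU model
#'
#' Integrates `dx = J x dt + sqrt(Sigma) dB` by Euler-Maruyama at step
#' `dt_seconds`, discards a stationarity burn-in, and subsamples to the
#' repetition time. The step is snapped to an integer divisor of
#' `tr_seconds`.
#'
#' @param model a stable [mou_model].
#' @param duration_seconds sampled duration (after burn-in).
#' @param dt_seconds integration step; must be `<= tr_seconds`.
#' @param tr_seconds sampling interval of the returned series.
#' @param seed integer seed; identical seeds give bit-identical series.
#' @param burn_in_seconds discarded initial transient (default `20 * tau`).
#' @param ... metadata passed to [parcellated_ts()] (subject_id, ...).
#' @return a [parcellated_ts] with `floor(duration / tr)` rows.
#' @export
simulate_mou <- function(model, duration_seconds, dt_seconds = tr_seconds / 20,
                         tr_seconds, seed = 1L,
                         burn_in_seconds = 20 * model$tau_seconds, ...) {
  stopifnot(inherits(model, "mou_model"))
  if (dt_seconds > tr_seconds) stop_invalid("dt_seconds must be <= tr_seconds")
  if (!is_stable(model)) {
    stop_invalid("unstable MOU model (spectral abscissa ",
                 signif(spectral_abscissa(model), 4), "); refusing to simulate")
  }
  n <- nrow(model$ec)
  stride <- max(1L, round(tr_seconds / dt_seconds))
  dt <- tr_seconds / stride
  n_keep <- floor(duration_seconds / tr_seconds)
  if (n_keep < 1L) stop_invalid("duration shorter than one TR")
  n_burn <- ceiling(burn_in_seconds / dt)
  n_steps <- n_burn + n_keep * stride
  J <- mou_jacobian(model)
  noise_sd <- sqrt(model$sigma * dt)
  out <- matrix(NA_real_, n_keep, n)
  with_seed(seed, {
    eps <- matrix(rnorm(n_steps * n), nrow = n) * noise_sd
    x <- numeric(n)
    k <- 0L
    for (s in seq_len(n_steps)) {
      x <- x + dt * (J %*% x) + eps[, s]
      if (s > n_burn && (s - n_burn) %% stride == 0L) {
        k <- k + 1L
        out[k, ] <- x
      }
    }
  })
  parcellated_ts(out, tr_seconds, ...)
}

# Scale nonnegative weight matrices so the worst-case Jacobian keeps a
# stability margin: spectral abscissa <= -margin/tau.
scale_for_stability <- function(w_list, tau, margin = 0.1) {
  rho <- max(vapply(w_list, function(w) {
    max(Re(eigen(w, only.values = TRUE)$values))
  }, numeric(1)))
  if (rho <= 0) return(1)
  (1 - margin) / (tau * rho)
}

#' Random stable MOU model on a random skeleton
#'
#' Draws a sparse skeleton ([random_sc_mask()]), uniform edge weights on it,
#' and per-region noise variances, then rescales the weights so the Jacobian
#' keeps a stability margin (spectral abscissa `-margin / tau`). Used by the
#' parameter-recovery studies.
#'
#' @param n_regions,density skeleton size and density.
#' @param tau_seconds decay time constant.
#' @param seed integer seed.
#' @param margin stability margin as a fraction of `1/tau`.
#' @param symmetric skeleton symmetry (the weights on it are directed either
#'   way).
#' @param weight_range,sigma_range uniform ranges for edge weights (before
#'   rescaling) and noise variances.
#' @return a stable [mou_model].
#' @export
random_mou_model <- function(n_regions, density = 0.2, tau_seconds = 2,
                             seed = 1L, margin = 0.1, symmetric = TRUE,
                             weight_range = c(0.5, 1.5),
                             sigma_range = c(0.9, 1.1)) {
  mask <- random_sc_mask(n_regions, density, symmetric = symmetric,
                         seed = derive_seed(seed, "mask"))
  cells <- which(mask$mask == 1)
  w <- matrix(0, n_regions, n_regions)
  with_seed(derive_seed(seed, "model"), {
    w[cells] <- runif(length(cells), weight_range[1], weight_range[2])
    sigma <- runif(n_regions, sigma_range[1], sigma_range[2])
  })
  w <- w * scale_for_stability(list(t(w)), tau_seconds, margin)
  mou_model(w, sigma, tau_seconds, mask)
}

#' Generate a ground-truth-known synthetic cohort
#'
#' Builds a common random structural skeleton, draws a group template of
#' uniform edge weights on it, gives each subject weights jittered around the
#' template, perturbs a fixed set of directed edges in the post-session
#' models of group A only, and simulates every subject-session. Weights are
#' rescaled per subject so that even the perturbed Jacobian keeps a stability
#' margin (spectral abscissa at `-0.1 / tau`). Per-subject structural
#' matrices (symmetrised weights) are returned so the mask-building stage can
#' be exercised end to end.
#'
#' @param spec a [cohort_spec()].
#' @return a list of class `cohort` with elements `dataset` (list of
#'   [parcellated_ts], one per subject-session), `truth` (true models,
#'   perturbed edges, group/session labels), `mask` (the generating
#'   [sc_mask]), `sc_matrices` (per-subject symmetric weight matrices) and
#'   `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_regions
  tau <- spec$tau_seconds
  mask <- random_sc_mask(n, spec$sc_density, symmetric = TRUE,
                         seed = derive_seed(spec$seed, "sc_mask"))
  edge_cells <- which(mask$mask == 1)

  edges <- spec$perturbed_edges
  if (is.null(edges)) {
    sel <- with_seed(derive_seed(spec$seed, "perturbed_edges"),
                     sample(edge_cells, min(spec$n_perturbed_edges,
                                            length(edge_cells))))
    edges <- cbind(source = (sel - 1L) %% n + 1L,
                   target = (sel - 1L) %/% n + 1L)
  } else {
    idx <- (edges[, 2L] - 1L) * n + edges[, 1L]
    if (any(mask$mask[idx] == 0)) {
      stop_invalid("perturbed edge(s) outside the SC mask: rows ",
                   paste(which(mask$mask[idx] == 0), collapse = ", "))
    }
    colnames(edges) <- c("source", "target")
  }
  edge_idx <- (edges[, 2L] - 1L) * n + edges[, 1L]

  perturb <- function(w) {
    if (spec$perturbation_mode == "multiplicative") {
      w[edge_idx] <- w[edge_idx] * (1 + spec$perturbation_scale)
    } else {
      w[edge_idx] <- w[edge_idx] + spec$perturbation_scale
    }
    w
  }

  subjects <- c(sprintf("A%02d", seq_len(spec$n_group_a)),
                sprintf("B%02d", seq_len(spec$n_group_b)))
  groups <- rep(c("A", "B"), c(spec$n_group_a, spec$n_group_b))
  sessions <- c("pre", "post")

  dataset <- list()
  true_models <- list()
  sc_matrices <- list()
  session_labels <- data.frame(subject_id = character(0),
                               group_label = character(0),
                               session_label = character(0))
  template <- matrix(0, n, n)
  template[edge_cells] <- with_seed(derive_seed(spec$seed, "template"),
                                    runif(length(edge_cells), 0.5, 1.5))
  for (i in seq_along(subjects)) {
    sid <- subjects[i]
    w <- template
    w[edge_cells] <- w[edge_cells] *
      (1 + spec$subject_jitter *
         with_seed(derive_seed(spec$seed, paste0("weights/", sid)),
                   runif(length(edge_cells), -1, 1)))
    gamma <- scale_for_stability(list(t(w), t(perturb(w))), tau)
    w <- gamma * w
    sigma <- with_seed(derive_seed(spec$seed, paste0("sigma/", sid)),
                       runif(n, 0.9, 1.1))
    for (ses in sessions) {
      w_ses <- if (groups[i] == "A" && ses == "post") perturb(w) else w
      model <- mou_model(w_ses, sigma, tau, mask)
      key <- paste(sid, ses, sep = "_")
      true_models[[key]] <- model
      ts <- simulate_mou(
        model, duration_seconds = spec$n_volumes * spec$tr_seconds,
        dt_seconds = spec$dt_seconds, tr_seconds = spec$tr_seconds,
        seed = derive_seed(spec$seed, paste0("sim/", key)),
        subject_id = sid, session_label = ses, group_label = groups[i])
      dataset[[key]] <- ts
      session_labels <- rbind(session_labels,
                              data.frame(subject_id = sid,
                                         group_label = groups[i],
                                         session_label = ses))
    }
    sc_matrices[[sid]] <- (w + t(w)) / 2
  }
  truth <- list(true_models = true_models,
                perturbed_edges = edges,
                group_labels = stats::setNames(groups, subjects),
                session_labels = session_labels)
  structure(list(dataset = dataset, truth = truth, mask = mask,
                 sc_matrices = sc_matrices, spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d + %d subjects x 2 sessions, %d regions, %d volumes at TR %g s, %d perturbed edges (scale %g)\n",
    x$spec$n_group_a, x$spec$n_group_b, x$spec$n_regions, x$spec$n_volumes,
    x$spec$tr_seconds, nrow(x$truth$perturbed_edges),
    x$spec$perturbation_scale))
  invisible(x)
}

#' Band-limited signals with controllable phase coupling
#'
#' Generates region signals as mixtures `s_i = coupling * s0 + (1 - coupling)
#' * e_i` of one shared and one independent band-limited Gaussian signal,
#' each variance-normalised afterwards. Pairwise phase coherence grows
#' monotonically with `coupling`; at `coupling = 1` every region follows the
#' same phase trajectory. Used as a fixture generator for the ignition stage.
#'
#' @param n_regions number of regions.
#' @param coupling shared-signal weight in `[0, 1]`.
#' @param n_volumes number of time points.
#' @param tr_seconds sampling interval in seconds.
#' @param band pass band in Hz, inside (0, Nyquist).
#' @param seed integer seed.
#' @param ... metadata passed to [parcellated_ts()].
#' @return a [parcellated_ts].
#' @export
simulate_phase_signals <- function(n_regions, coupling, n_volumes,
                                   tr_seconds, band = c(0.04, 0.07),
                                   seed = 1L, ...) {
  if (coupling < 0 || coupling > 1) stop_invalid("coupling must be in [0, 1]")
  nyq <- 1 / (2 * tr_seconds)
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < nyq)) {
    stop_invalid("band must lie inside (0, ", nyq, ") Hz")
  }
  bf <- signal::butter(2, band / nyq, type = "pass")
  raw <- with_seed(seed, matrix(rnorm(n_volumes * (n_regions + 1)),
                                n_volumes, n_regions + 1))
  filt <- apply(raw, 2L, function(x) signal::filtfilt(bf, x))
  shared <- filt[, 1L]
  vals <- coupling * shared + (1 - coupling) * filt[, -1L, drop = FALSE]
  vals <- apply(vals, 2L, function(x) x / max(sd(x), .Machine$double.eps))
  parcellated_ts(vals, tr_seconds, ...)
}

#' Write a synthetic cohort to disk
#'
#' Layout: `dir/cohort/<group>/<subject>/<session>.csv` (rows = time,
#' header = region labels), `dir/sc/<subject>.csv` (square, header-free),
#' `dir/parcellation.tsv`, and `dir/manifest.json` recording the spec, the
#' labels and the planted edges.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param parcellation optional parcellation table; defaults to
#'   [make_parcellation()] of the cohort's region count.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, parcellation = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(parcellation)) parcellation <- make_parcellation(cohort$spec$n_regions)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (key in names(cohort$dataset)) {
    ts <- cohort$dataset[[key]]
    sub_dir <- file.path(dir, "cohort", ts$group_label, ts$subject_id)
    dir.create(sub_dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(sub_dir, paste0(ts$session_label, ".csv"))
    write_timeseries(ts, path, parcellation)
    files <- c(files, path)
  }
  dir.create(file.path(dir, "sc"), showWarnings = FALSE)
  for (sid in names(cohort$sc_matrices)) {
    utils::write.table(cohort$sc_matrices[[sid]],
                       file.path(dir, "sc", paste0(sid, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  write_parcellation(parcellation, file.path(dir, "parcellation.tsv"))
  manifest <- list(
    spec = unclass(cohort$spec)[setdiff(names(cohort$spec), "perturbed_edges")],
    perturbed_edges = apply(cohort$truth$perturbed_edges, 1L, function(e) {
      list(source = unname(e[1]), target = unname(e[2]))
    }),
    group_labels = as.list(cohort$truth$group_labels),
    tr_seconds = cohort$spec$tr_seconds,
    files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
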