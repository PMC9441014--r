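#' Pipeline configuration
#'
#' Collects every setting of the end-to-end analysis: input location (a
#' cohort directory written by [write_cohort()], or a [cohort_spec()] to
#' generate a synthetic cohort in memory), frequency bands, SC mask density,
#' optimiser and classification settings, RFE and ignition settings, and one
#' global seed from which every stage derives its own deterministic stream.
#'
#' @param cohort_dir directory holding a cohort (ignored when `synthetic` is
#'   given).
#' @param synthetic optional [cohort_spec()]; when given the cohort is
#'   generated rather than read.
#' @param output_dir where reports and artifacts are written.
#' @param model_band band-pass (Hz) applied before covariance estimation for
#'   the MOU fit.
#' @param ignition_band band-pass (Hz) for the ignition analysis.
#' @param sc_density density of the thresholded SC mask.
#' @param lag_trs covariance lag in TR units.
#' @param tau_max_lag largest lag used by [estimate_tau()].
#' @param fit a [fit_opts()] list.
#' @param n_splits,test_fraction,classifiers,metrics classification settings.
#' @param rfe_repetitions repetitions of the SVM-RFE procedure.
#' @param ignition_window integration window in TRs.
#' @param threshold_sd,binarize_threshold ignition event and phase-lock
#'   thresholds.
#' @param write_models write per-session fitted models as CSV + JSON.
#' @param seed global integer seed.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_dir = NULL, synthetic = NULL,
                            output_dir = tempfile("mouec_out"),
                            model_band = c(0.01, 0.07),
                            ignition_band = c(0.04, 0.07),
                            sc_density = 0.30, lag_trs = 1L,
                            tau_max_lag = 2L, fit = fit_opts(),
                            n_splits = 50L, test_fraction = 0.2,
                            classifiers = c("svm", "1nn"),
                            metrics = c("ec", "fc"),
                            rfe_repetitions = 10L,
                            ignition_window = 4L, threshold_sd = 1,
                            binarize_threshold = 0.5,
                            write_models = FALSE, seed = 1L) {
  if (is.null(cohort_dir) && is.null(synthetic)) {
    stop_invalid("either cohort_dir or a synthetic cohort_spec is required")
  }
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "cohort_spec"))
  if (is.null(sc_density) || !(sc_density > 0 && sc_density <= 1)) {
    stop_invalid("sc_density must be given, in (0, 1]")
  }
  stopifnot(length(model_band) == 2L, length(ignition_band) == 2L,
            inherits(fit, "fit_opts"), n_splits >= 1L,
            test_fraction > 0, test_fraction < 1,
            all(classifiers %in% c("svm", "1nn")),
            all(metrics %in% c("ec", "fc", "sc")))
  structure(as.list(environment()), class = "pipeline_config")
}

# Tiny rolling hash of the deparsed config, for the run log. The output
# location is not part of the scientific configuration, so two runs that
# differ only in where they write share a hash (and hence a report).
config_hash <- function(config) {
  config$output_dir <- NULL
  h <- 5381
  for (code in utf8ToInt(paste(deparse(config), collapse = ""))) {
    h <- (h * 33 + code) %% 2147483647
  }
  sprintf("%08x", h)
}

run_stage <- function(name, verbose, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  if (verbose) {
    message(sprintf("[mouec] stage %-12s %.1f s", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  out
}

#' Run the full analysis pipeline
#'
#' Sequences every stage on one cohort: SC mask construction (group-average
#' masks and their intersection), per-session band-passing, covariance and
#' time-constant estimation, MOU-EC fitting, within-group (pre vs post) and
#' between-group (post vs post) classification with label-shuffled surrogates
#' and rank-sum comparisons, SVM-RFE support-network extraction on the
#' group-A EC features, and intrinsic-ignition profiles (whole-brain and
#' support-node subset) with session/group comparisons. Fully reproducible
#' from (config, seed): the JSON report is byte-identical across runs.
#'
#' @param config a [pipeline_config()].
#' @param verbose log stage timings (timings go to the console only, never
#'   into the report).
#' @return the report list, invisibly; also written to
#'   `output_dir/report.json` together with the support-network TSV and
#'   accuracy tables.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  if (verbose) {
    message("[mouec] seed ", seed, ", config hash ", config_hash(config))
  }

  ## ---- input ----
  data <- run_stage("input", verbose, {
    if (!is.null(config$synthetic)) {
      cohort <- generate_cohort(config$synthetic)
      list(dataset = cohort$dataset,
           sc_matrices = cohort$sc_matrices,
           parcellation = make_parcellation(config$synthetic$n_regions),
           truth = cohort$truth)
    } else {
      read_cohort(config$cohort_dir)
    }
  })
  dataset <- data$dataset
  meta <- data.frame(
    key = names(dataset),
    subject_id = vapply(dataset, `[[`, character(1), "subject_id"),
    session_label = vapply(dataset, `[[`, character(1), "session_label"),
    group_label = vapply(dataset, `[[`, character(1), "group_label"),
    stringsAsFactors = FALSE)
  groups <- sort(unique(meta$group_label))
  if (length(groups) != 2L) stop_invalid("pipeline expects exactly 2 groups")

  ## ---- SC masks ----
  masks <- run_stage("sc_mask", verbose, {
    subj_group <- meta$group_label[match(names(data$sc_matrices),
                                         meta$subject_id)]
    by_group <- lapply(groups, function(g) {
      data$sc_matrices[which(subj_group == g)]
    })
    names(by_group) <- groups
    group_masks <- lapply(by_group, build_sc_mask, density = config$sc_density)
    inter <- build_sc_mask(by_group, density = config$sc_density,
                           mode = "intersection")
    list(group = group_masks, intersection = inter)
  })

  ## ---- per-session covariances and MOU fits ----
  fits <- run_stage("fit_mou", verbose, {
    lapply(names(dataset), function(key) {
      ts <- dataset[[key]]
      filt <- bandpass(ts, config$model_band[1], config$model_band[2])
      emp <- covariance_pair(filt, config$lag_trs)
      tau <- estimate_tau(filt, config$tau_max_lag)
      mask <- masks$group[[ts$group_label]]
      fit <- fit_mou(emp, mask, tau, config$fit)
      list(key = key, model = fit$model, report = fit$report, emp = emp,
           fc = emp$q0, tau = tau)
    })
  })
  names(fits) <- names(dataset)
  if (config$write_models) {
    mdir <- file.path(config$output_dir, "models")
    for (f in fits) write_mou_model(f$model, mdir, f$key, f$report)
  }

  ## ---- classification tasks ----
  class_res <- run_stage("classify", verbose, {
    tasks <- list()
    for (g in groups) {
      keys <- meta$key[meta$group_label == g]
      tasks[[paste0("within_", g)]] <-
        list(keys = keys, labels = meta$session_label[match(keys, meta$key)],
             mask = masks$group[[g]])
    }
    post_keys <- meta$key[meta$session_label == "post"]
    tasks[["between_post"]] <-
      list(keys = post_keys,
           labels = meta$group_label[match(post_keys, meta$key)],
           mask = masks$intersection)
    lapply(names(tasks), function(tn) {
      tk <- tasks[[tn]]
      metrics <- config$metrics
      if (tn == "between_post" && !is.null(data$sc_matrices) &&
          !("sc" %in% metrics)) {
        metrics <- c(metrics, "sc")
      }
      res <- lapply(metrics, function(mt) {
        fs <- task_features(tk, fits, data$sc_matrices, meta, mt)
        per_clf <- lapply(config$classifiers, function(clf) {
          real <- evaluate_classifier(
            fs, clf, config$n_splits, config$test_fraction,
            seed = derive_seed(seed, paste("clf", tn, mt, clf, sep = "/")))
          surr <- surrogate_distribution(
            fs, clf, config$n_splits, config$test_fraction,
            seed = derive_seed(seed, paste("surr", tn, mt, clf, sep = "/")))
          cmp <- compare_distributions(real, surr)
          list(mean_accuracy = mean(real$accuracies),
               surrogate_mean_accuracy = mean(surr$accuracies),
               accuracies = real$accuracies,
               surrogate_accuracies = surr$accuracies,
               vs_surrogate_p = cmp$p_value)
        })
        names(per_clf) <- config$classifiers
        per_clf
      })
      names(res) <- metrics
      res
    }) -> out
    names(out) <- names(tasks)
    out
  })

  ## ---- SVM-RFE support network on group-A (first group) EC features ----
  g1 <- groups[1L]
  support <- run_stage("rfe", verbose, {
    keys <- meta$key[meta$group_label == g1]
    tk <- list(keys = keys,
               labels = meta$session_label[match(keys, meta$key)],
               mask = masks$group[[g1]])
    fs <- task_features(tk, fits, data$sc_matrices, meta, "ec")
    net <- select_support_network(fs, config$rfe_repetitions,
                                  config$test_fraction,
                                  seed = derive_seed(seed, "rfe"))
    write_support_network(net, data$parcellation,
                          file.path(config$output_dir, "support_network.tsv"))
    net
  })

  ## ---- intrinsic ignition ----
  ignition <- run_stage("ignition", verbose, {
    subsets <- list(whole_brain = NULL, support = support$node_set)
    lapply(subsets, function(ns) {
      profiles <- lapply(dataset, function(ts) {
        ignition_profile(ts, node_subset = ns,
                         window_trs = config$ignition_window,
                         band = config$ignition_band,
                         threshold_sd = config$threshold_sd,
                         binarize_threshold = config$binarize_threshold)
      })
      comparisons <- list()
      for (g in groups) {
        subj <- meta$subject_id[meta$group_label == g & meta$session_label == "pre"]
        pre <- profiles[paste0(subj, "_pre")]
        post <- profiles[paste0(subj, "_post")]
        cmp <- compare_ignition(pre, post, paired = TRUE)
        comparisons[[paste0("pre_vs_post_", g)]] <-
          lapply(cmp, function(x) list(p_value = x$p_value,
                                       direction = x$direction))
      }
      cmp <- compare_ignition(
        profiles[meta$key[meta$session_label == "post" & meta$group_label == groups[1]]],
        profiles[meta$key[meta$session_label == "post" & meta$group_label == groups[2]]],
        paired = FALSE)
      comparisons[["post_between_groups"]] <-
        lapply(cmp, function(x) list(p_value = x$p_value,
                                     direction = x$direction))
      summary <- data.frame(
        key = names(profiles),
        mean_idmi = vapply(profiles, function(p) mean(p$idmi, na.rm = TRUE),
                           numeric(1)),
        mean_metastability = vapply(profiles, function(p) {
          mean(p$metastability, na.rm = TRUE)
        }, numeric(1)))
      list(summary = summary, comparisons = comparisons)
    })
  })

  ## ---- report ----
  report <- run_stage("report", verbose, {
    rep <- list(
      seed = seed,
      config_hash = config_hash(config),
      n_sessions = length(dataset),
      mask_densities = lapply(masks$group, `[[`, "density"),
      intersection_density = masks$intersection$density,
      fit = list(
        mean_best_error = mean(vapply(fits, function(f) f$report$best_error,
                                      numeric(1))),
        mean_best_pearson_r = mean(vapply(fits, function(f) {
          f$report$best_pearson_r
        }, numeric(1))),
        mean_tau_seconds = mean(vapply(fits, `[[`, numeric(1), "tau"))),
      classification = class_res,
      support_network = list(
        size = support$size,
        n_nodes = length(support$node_set),
        edges = support$edges),
      ignition = lapply(ignition, function(x) {
        list(comparisons = x$comparisons,
             mean_idmi = mean(x$summary$mean_idmi, na.rm = TRUE),
             mean_metastability = mean(x$summary$mean_metastability,
                                       na.rm = TRUE))
      }))
    jsonlite::write_json(rep, file.path(config$output_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    rep
  })
  invisible(report)
}

# Assemble the feature set of one classification task.
task_features <- function(task, fits, sc_matrices, meta, metric_tag) {
  keys <- task$keys
  labels <- task$labels
  if (metric_tag == "ec") {
    models <- lapply(keys, function(k) {
      m <- fits[[k]]$model
      if (!identical(m$mask$mask, task$mask$mask)) {
        # restrict to the task mask (e.g. group intersection)
        ec <- m$ec * task$mask$mask
        m <- mou_model(ec, m$sigma, m$tau_seconds, task$mask,
                       check_stability = FALSE)
      }
      m
    })
    names(models) <- keys
    build_features(models, task$mask, "ec", labels,
                   subject_ids = meta$subject_id[match(keys, meta$key)])
  } else if (metric_tag == "fc") {
    mats <- lapply(keys, function(k) fits[[k]]$fc)
    names(mats) <- keys
    build_features(mats, metric_tag = "fc", labels = labels,
                   subject_ids = meta$subject_id[match(keys, meta$key)])
  } else {
    subj <- meta$subject_id[match(keys, meta$key)]
    mats <- lapply(subj, function(s) sc_matrices[[s]])
    names(mats) <- keys
    build_features(mats, metric_tag = "sc", labels = labels,
                   subject_ids = subj)
  }
}
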