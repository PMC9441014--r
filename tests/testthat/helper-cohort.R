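# Full-scale synthetic cohorts (17 + 16 subjects, 116 regions, 235 volumes)
# with their per-session MOU fits. Built once and cached: both the
# classification and the RFE checks consume the same fixture. Fits use
# 300 iterations — enough for stable session contrasts at this size (the
# error plateau is reached much earlier; see the methods vignette).

cohort_fixture <- function(which = c("strong", "null")) {
  which <- match.arg(which)
  fixture(paste0("cohort_", which), function() {
    scale <- if (which == "strong") 20 else 0
    spec <- cohort_spec(perturbation_scale = scale, seed = 301)
    coh <- generate_cohort(spec)
    models <- lapply(coh$dataset, function(ts) {
      filt <- bandpass(ts, 0.01, 0.07)
      fit_mou(covariance_pair(filt, 1), coh$mask, estimate_tau(filt, 2),
              fit_opts(max_iter = 300, patience = 300))$model
    })
    keys <- names(models)[grepl("^A", names(models))]
    fs_ec <- build_features(models[keys], coh$mask, "ec",
                            labels = sub(".*_", "", keys))
    list(coh = coh, models = models, fs_ec = fs_ec)
  })
}
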