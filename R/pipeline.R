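# Umbrella pipeline: synthgen -> preprocess -> features -> train -> evaluate,
# driven by one structured configuration with a single global seed from which
# every stage seed is derived.

#' Default pipeline configuration
#'
#' Nested per-module parameter blocks. Any subset can be overridden in a
#' YAML config file; unknown keys are rejected.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "fatiguefuse_run",
    synthgen = list(n_per_state = 30L, window_s = 30, fs = 2000),
    preprocess = list(ecg_cutoff = 100, semg_cutoff = 500, notch_f0 = 50,
                      harmonics = 3L, emd_denoise = FALSE,
                      n_initial_imfs = 3L),
    features = list(min_intervals = 16L),
    ipso_svm = list(q = 50L, c1 = 0.5, c2 = 0.5, omega = 0.8, h_e = 0.95,
                    max_iter = 50L, v_max = 2, C = 10, sigma = sqrt(11)),
    evaluate = list(n_rep = 20L, test_fraction = 0.3,
                    models = c("ipso_svm", "bpnn", "knn", "lda"))
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file, overlays it on [default_config()] and rejects unknown
#' keys at any nesting level.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  check_keys <- function(u, d, prefix = "") {
    bad <- setdiff(names(u), names(d))
    if (length(bad))
      ff_stop_invalid(sprintf("unknown config key(s): %s",
                              paste0(prefix, bad, collapse = ", ")))
    for (k in names(u))
      if (is.list(d[[k]]) && is.list(u[[k]]))
        check_keys(u[[k]], d[[k]], paste0(prefix, k, "."))
  }
  check_keys(user, cfg)
  modifyList(cfg, user)
}

# Polynomial hash of the resolved configuration, embedded in artifacts so
# outputs are traceable to the exact settings that produced them. The output
# directory is excluded: it locates the artifacts but does not affect them.
config_hash <- function(cfg) {
  cfg$out_dir <- NULL
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full fatigue-estimation pipeline
#'
#' Executes synthgen -> preprocess -> features -> train -> evaluate in
#' order, writing each stage's artifacts under `config$out_dir`. Stages
#' whose primary output already exists are skipped unless `force = TRUE`.
#' A resolved-config snapshot (`config.json`, including its hash) is written
#' alongside the outputs, and all JSON artifacts embed the hash.
#'
#' @param config configuration list from [load_config()] /
#'   [default_config()].
#' @param force rerun stages whose outputs already exist (default `FALSE`).
#' @param quiet suppress stage progress messages (default `FALSE`).
#' @return Invisibly, a list with paths of the produced artifacts and the
#'   final comparison table.
#' @export
run_pipeline <- function(config = default_config(), force = FALSE,
                         quiet = FALSE) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  jsonlite::write_json(c(config, list(config_hash = hash)),
                       file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  seeds <- derive_seeds(config$seed, 4, salt = 99L)

  windows_dir <- file.path(out, "windows")
  t0 <- Sys.time()
  if (force || !file.exists(file.path(windows_dir, "manifest.csv"))) {
    say("[synthgen] generating %d windows/state (seed %d)",
        config$synthgen$n_per_state, as.integer(seeds[1]))
    records <- generate_dataset(config$synthgen$n_per_state,
                                window_s = config$synthgen$window_s,
                                fs = config$synthgen$fs, seed = seeds[1])
    write_dataset(records, windows_dir, meta = list(config_hash = hash,
                                                    seed = seeds[1]))
  } else say("[synthgen] outputs exist, skipping")

  features_csv <- file.path(out, "features.csv")
  if (force || !file.exists(features_csv)) {
    records <- read_dataset(windows_dir)
    say("[preprocess+features] %d windows", length(records))
    pp <- config$preprocess
    feats <- extract_feature_table(
      lapply(records, function(r)
        preprocess_record(r, ecg_cutoff = pp$ecg_cutoff,
                          semg_cutoff = pp$semg_cutoff,
                          notch_f0 = pp$notch_f0, harmonics = pp$harmonics,
                          emd_denoise = pp$emd_denoise,
                          n_initial_imfs = pp$n_initial_imfs)),
      min_intervals = config$features$min_intervals)
    write_feature_table(feats, features_csv)
  } else say("[features] outputs exist, skipping")
  feats <- read_feature_table(features_csv)

  ip <- config$ipso_svm
  cfg_sw <- swarm_config(q = ip$q, c1 = ip$c1, c2 = ip$c2, omega = ip$omega,
                         h_e = ip$h_e, max_iter = ip$max_iter,
                         v_max = ip$v_max, seed = seeds[2])
  model_json <- file.path(out, "model.json")
  if (force || !file.exists(model_json)) {
    say("[train] IPSO-SVM (q=%d, max_iter=%d)", ip$q, ip$max_iter)
    fit <- fit_ipso_svm(as.matrix(feats[, feature_names()]), feats$label,
                        cfg = cfg_sw, C = ip$C, sigma = ip$sigma)
    write_model(fit, model_json, meta = list(config_hash = hash,
                                             seed = seeds[2]))
  } else say("[train] outputs exist, skipping")

  ev <- config$evaluate
  report_json <- file.path(out, "report.json")
  comparison_csv <- file.path(out, "comparison.csv")
  if (force || !file.exists(report_json)) {
    factories <- list(
      ipso_svm = clf_ipso_svm(cfg_sw, C = ip$C, sigma = ip$sigma),
      svm = clf_svm(C = ip$C, sigma = ip$sigma),
      bpnn = clf_bpnn(), knn = clf_knn(), lda = clf_lda())
    reports <- list()
    for (nm in ev$models) {
      say("[evaluate] %s over %d MCCV splits", nm, ev$n_rep)
      reports[[nm]] <- mccv(feats, classifier = factories[[nm]],
                            n_rep = ev$n_rep,
                            test_fraction = ev$test_fraction, seed = seeds[3])
    }
    write_report(reports[[ev$models[1]]], report_json,
                 meta = list(config_hash = hash))
    say("[evaluate] modality comparison")
    cmp <- compare_modalities(feats,
                              fused_classifier = clf_ipso_svm(cfg_sw, C = ip$C,
                                                              sigma = ip$sigma),
                              n_rep = ev$n_rep,
                              test_fraction = ev$test_fraction, seed = seeds[4])
    write.csv(cmp$table, comparison_csv, row.names = FALSE)
    summary_rates <- data.frame(
      classifier = names(reports),
      mean_rate = vapply(reports, function(r) r$mean_rate, numeric(1)))
    write.csv(summary_rates, file.path(out, "classifier_rates.csv"),
              row.names = FALSE)
  } else say("[evaluate] outputs exist, skipping")
  say("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(out_dir = out, features = features_csv, model = model_json,
                 report = report_json, comparison = comparison_csv,
                 config_hash = hash))
}
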