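#' Default pipeline configuration
#'
#' Nested configuration of the end-to-end analysis: cohort simulation,
#' preprocessing, feature extraction, selection, classification and
#' topographic mapping. Every entry can be overridden by the
#' corresponding argument of [run_pipeline()] via a partial list;
#' unknown keys are rejected by name.
#'
#' @param seed run seed; every random stage derives from it.
#' @param out_dir output directory of the run.
#' @return Nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, out_dir = "eegresp_run") {
  structure(list(
    seed = seed,
    out_dir = out_dir,
    task = "response",
    cohort = list(n_patients = 34, n_controls = 30,
                  responder_fraction = 16 / 34, fs = 256,
                  duration_per_condition = 300, effect_size = 1.5,
                  patient_shift = 0,
                  effect_channels = c("F7", "F8", "T4"),
                  band_amplitudes = list(delta = 20, theta = 10,
                                         alpha = c(EC = 15, EO = 7.5),
                                         beta = 5, gamma = 2)),
    preprocess = list(bandpass = c(0.1, 70), notch = 50,
                      reference = "average", resample_to = 140,
                      epoch_length = 120, epoch_offset = 0,
                      apply_filters = TRUE),
    features = list(methods = "wavelet", bands = c("delta", "theta")),
    selection = list(selector = "roc", k = 15, r_max = 0.9,
                     scope = "train-fold"),
    classify = list(folds = 10, repeats = 100, group_by_subject = TRUE,
                    subset_sizes = NULL),
    maps = list(enabled = TRUE, stratify_sex = TRUE, top_n = 15,
                fallback_top_n = 100)
  ), class = "pipeline_config")
}

# deep-merge a partial override into the default config, rejecting keys
# the schema does not know
.merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, "$", key) else key
    if (!key %in% names(base))
      stop("unknown configuration key: `", full, "`")
    if (is.list(base[[key]]) && is.list(override[[key]]) &&
        !is.null(names(base[[key]])))
      base[[key]] <- .merge_config(base[[key]], override[[key]], full)
    else
      base[[key]] <- override[[key]]
  }
  base
}

#' Run the end-to-end analysis pipeline
#'
#' Simulate (or load) a cohort, preprocess, extract features,
#' standardize against the healthy-control reference, rank features,
#' cross-validate the classifier and draw the rank-sum topographies.
#' All stage outputs are written as plain-text files into the run
#' directory; a fixed seed makes the whole run reproducible.
#'
#' @param config partial configuration list merged over
#'   [pipeline_config()]; unknown keys raise an error naming the key.
#' @param cohort optionally, an existing cohort (as from
#'   [generate_cohort()] or [read_cohort_csv()]) to analyse instead of
#'   simulating one.
#' @return Invisibly, a list with the run artifacts: `config`,
#'   `metadata`, `ranked_table`, `cv` (per method), `maps`, `pca`,
#'   and the run directory.
#' @export
run_pipeline <- function(config = list(), cohort = NULL) {
  cfg <- .merge_config(pipeline_config(), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  log_msg <- function(...) message("[eegresp] ", sprintf(...))

  if (is.null(cohort)) {
    spec <- do.call(cohort_spec, c(cfg$cohort, list(seed = cfg$seed)))
    log_msg("simulating cohort: %d patients / %d controls, d = %.2g at %s",
            spec$n_patients, spec$n_controls, spec$effect_size,
            paste(spec$effect_channels, collapse = ","))
    cohort <- generate_cohort(spec)
  }
  write.csv(cohort$metadata, file.path(cfg$out_dir, "metadata.csv"),
            row.names = FALSE)

  pcfg <- preprocess_config(
    bandpass = cfg$preprocess$bandpass, notch = cfg$preprocess$notch,
    reference = cfg$preprocess$reference,
    resample_to = cfg$preprocess$resample_to,
    epoch_length = cfg$preprocess$epoch_length)

  is_patient <- sapply(cohort$recordings, function(r)
    r$group %in% c("R", "NR"))
  out <- list(config = cfg, metadata = cohort$metadata, cv = list(),
              out_dir = cfg$out_dir)

  fms <- list()
  for (m in cfg$features$methods) {
    log_msg("extracting %s features", m)
    fm_pat <- extract_features(cohort$recordings[is_patient], method = m,
                               bands = cfg$features$bands, cfg = pcfg,
                               epoch_offset = cfg$preprocess$epoch_offset,
                               preprocess = cfg$preprocess$apply_filters)
    fm_ctl <- extract_features(cohort$recordings[!is_patient], method = m,
                               bands = cfg$features$bands, cfg = pcfg,
                               epoch_offset = cfg$preprocess$epoch_offset,
                               preprocess = cfg$preprocess$apply_filters)
    fms[[m]] <- list(patients = fm_pat, controls = fm_ctl)
  }

  primary <- cfg$features$methods[1]
  ref <- fit_reference(fms[[primary]]$controls)
  task_fm <- if (cfg$task == "diagnosis") {
    all_fm <- combine_instances(fms[[primary]]$patients,
                                fms[[primary]]$controls)
    as_diagnosis_task(all_fm)
  } else {
    fms[[primary]]$patients
  }
  std <- standardize(if (cfg$task == "diagnosis") task_fm else
    fms[[primary]]$patients, ref)
  if (cfg$task == "diagnosis") std$instance_meta <- task_fm$instance_meta

  log_msg("ranking %d features on the full data set", ncol(std$values))
  ranked <- auc_rank(std)
  ranked <- prune_correlated(ranked, std, r_max = cfg$selection$r_max,
                             n_keep = max(cfg$maps$fallback_top_n,
                                          cfg$selection$k))
  top <- take_top(ranked, cfg$selection$k)
  pos <- fm_labels(std)
  ranked_table <- data.frame(
    channel = std$feature_meta$channel[top],
    band = std$feature_meta$band[top],
    abs_z = abs(ranked$auc[top]),
    p = vapply(top, function(j) suppressWarnings(
      wilcox.test(std$values[pos, j], std$values[!pos, j])$p.value),
      numeric(1)))
  write.csv(ranked_table, file.path(cfg$out_dir, "top_features.csv"),
            row.names = FALSE)
  out$ranked_table <- ranked_table
  out$ranked <- ranked

  for (m in cfg$features$methods) {
    fm_task <- if (cfg$task == "diagnosis")
      as_diagnosis_task(combine_instances(fms[[m]]$patients,
                                          fms[[m]]$controls))
    else fms[[m]]$patients
    log_msg("cross-validating %s features (%dx%d-fold)", m,
            cfg$classify$repeats, cfg$classify$folds)
    out$cv[[m]] <- cross_validate(
      fm_task, k_features = cfg$selection$k,
      selector = cfg$selection$selector, folds = cfg$classify$folds,
      repeats = cfg$classify$repeats, seed = cfg$seed + 1,
      r_max = cfg$selection$r_max,
      group_by_subject = cfg$classify$group_by_subject,
      scope = cfg$selection$scope)
    if (!is.null(cfg$classify$subset_sizes)) {
      out$sweep[[m]] <- subset_sweep(
        fm_task, sizes = cfg$classify$subset_sizes,
        selector = cfg$selection$selector, folds = cfg$classify$folds,
        repeats = cfg$classify$repeats, seed = cfg$seed + 1,
        group_by_subject = cfg$classify$group_by_subject,
        scope = cfg$selection$scope)
      write.csv(out$sweep[[m]]$summary,
                file.path(cfg$out_dir, paste0("sweep_", m, ".csv")),
                row.names = FALSE)
    }
  }

  if (isTRUE(cfg$maps$enabled)) {
    log_msg("building rank-sum topographies")
    strata <- expand.grid(
      sex = if (isTRUE(cfg$maps$stratify_sex)) c(NA, "F", "M") else NA,
      condition = c("EC", "EO"), stringsAsFactors = FALSE)
    out$maps <- list()
    for (i in seq_len(nrow(strata))) {
      sx <- strata$sex[i]; cd <- strata$condition[i]
      mp <- wilcoxon_channel_map(
        std, ranked, top_n = cfg$maps$top_n,
        fallback_top_n = cfg$maps$fallback_top_n,
        stratum_sex = if (is.na(sx)) NULL else sx,
        stratum_condition = cd)
      if (is.null(mp)) next
      nm <- paste0("map_", ifelse(is.na(sx), "all", sx), "_", cd)
      write.csv(mp, file.path(cfg$out_dir, paste0(nm, ".csv")),
                row.names = FALSE)
      out$maps[[nm]] <- mp
    }
  }

  out$pca <- pca_scatter(fm_subset(std, cols = top))
  write.csv(data.frame(out$pca$scores,
                       group = std$instance_meta$group,
                       condition = std$instance_meta$condition),
            file.path(cfg$out_dir, "pca_scores.csv"), row.names = FALSE)

  report <- list(
    seed = cfg$seed, task = cfg$task,
    n_patients = cfg$cohort$n_patients,
    n_controls = cfg$cohort$n_controls,
    cv = lapply(out$cv, function(cv) {
      s <- cv$summary
      setNames(lapply(seq_len(nrow(s)), function(i)
        list(mean = s$mean[i], sd = s$sd[i])), s$metric)
    }),
    top_features = ranked_table,
    pca_variance_explained_2 = sum(out$pca$variance_explained[1:2])
  )
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  log_msg("run complete: %s", cfg$out_dir)
  invisible(out)
}

#' Row-bind two feature matrices over identical features
#'
#' @param a,b [feature_matrix()] objects with identical feature columns.
#' @return The combined [feature_matrix()].
#' @export
combine_instances <- function(a, b) {
  stopifnot(identical(a$feature_meta$feature, b$feature_meta$feature))
  feature_matrix(rbind(a$values, b$values), a$feature_meta,
                 rbind(a$instance_meta, b$instance_meta))
}
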