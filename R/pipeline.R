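#' Derive a per-stage seed from the master seed
#'
#' Deterministic, stable across platforms: mixes the stage name into the
#' master seed so each stage can be rerun independently with the same
#' stream. Always below 2^31.
#'
#' @param seed master integer seed.
#' @param stage stage name.
#' @return integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) + h * 10007) %% 2147483647)
}

#' Default configuration for a full analysis run
#'
#' A plain nested list (readable from YAML via `yaml::read_yaml()`)
#' collecting the seed, the experiment size, generative-parameter and task
#' overrides, per-stage toggles and per-stage settings. Stage toggles:
#' simulate, psychometrics, similarity, choice_probability, glm (tracking
#' is exercised separately on frame stacks).
#'
#' @param seed master integer seed.
#' @return nested list.
#' @export
default_run_config <- function(seed = 1) {
  list(
    seed = seed,
    experiment = list(n_subjects = 3, sessions_per_subject = 2,
                      trials_per_session = 300),
    task = list(),
    params = list(),
    stages = list(simulate = TRUE, psychometrics = TRUE, similarity = TRUE,
                  choice_probability = TRUE, glm = TRUE),
    similarity = list(window = c(0, 2.4)),
    cp = list(n_shuffles = 100, n_bins = 6, n_components = 2,
              window = c(-0.5, 0.5)),
    glm = list(stepwise = FALSE)
  )
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline into an output directory
#'
#' Orchestrates simulate -> psychometrics -> trajectory similarity ->
#' choice probability (instantaneous, per subject at the highest
#' choice-variance stimulus; trajectory-level with CP binning and per-bin
#' psychometrics) -> GLM ladder, writing tabular outputs as CSV and
#' summaries as JSON. Every artifact records the config hash and seed;
#' rerunning with the same config reproduces identical outputs (the run log
#' carries wall times and is the only file excluded from that guarantee).
#'
#' @param config nested list as from [default_run_config()]; partial
#'   configs are merged over the defaults.
#' @param out_dir output directory (created if needed).
#' @return (invisibly) the summary list written to `summary.json`.
#' @export
run_full_analysis <- function(config = default_run_config(), out_dir) {
  config <- .merge_config(default_run_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config)
  log_path <- file.path(out_dir, "run_log.txt")
  cat(sprintf("run start seed=%s config=%s\n", config$seed, hash),
      file = log_path)
  log_stage <- function(stage, t0) {
    cat(sprintf("%s done in %.2f s\n", stage,
                as.numeric(Sys.time()) - t0),
        file = log_path, append = TRUE)
  }
  jsonlite::write_json(c(config, list(config_hash = hash)),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  summary_out <- list(config_hash = hash, seed = config$seed)

  stopifnot(isTRUE(config$stages$simulate))
  t0 <- as.numeric(Sys.time())
  task <- do.call(task_config, config$task)
  params <- do.call(generative_params, config$params)
  exp <- simulate_experiment(
    config = task, params = params,
    n_subjects = config$experiment$n_subjects,
    sessions_per_subject = config$experiment$sessions_per_subject,
    trials_per_session = config$experiment$trials_per_session,
    seed = stage_seed(config$seed, "simulate")
  )
  trials <- exp$trials
  trajs <- exp$trajectories
  write_session_csv(trials, file.path(out_dir, "session.csv"))
  write_trajectory_matrix(trajs, file.path(out_dir, "trajectories.csv"))
  log_stage("simulate", t0)

  if (isTRUE(config$stages$psychometrics)) {
    t0 <- as.numeric(Sys.time())
    key <- interaction(trials$subject, trials$session, drop = TRUE)
    fits <- lapply(split(trials, key), fit_psychometric)
    psy <- data.frame(
      subject = vapply(split(trials$subject, key), `[`, character(1), 1),
      session = vapply(split(trials$session, key), `[`, character(1), 1),
      intercept = vapply(fits, `[[`, numeric(1), "intercept"),
      slope = vapply(fits, `[[`, numeric(1), "slope"),
      bias_point = vapply(fits, `[[`, numeric(1), "bias_point"),
      n_trials = vapply(fits, `[[`, numeric(1), "n_trials"),
      converged = vapply(fits, `[[`, logical(1), "converged"),
      row.names = NULL
    )
    write.csv(psy, file.path(out_dir, "psychometrics.csv"), row.names = FALSE)
    summary_out$psychometrics <- list(
      mean_bias_point = mean(psy$bias_point[psy$converged]),
      mean_slope = mean(psy$slope[psy$converged]))
    log_stage("psychometrics", t0)
  }

  if (isTRUE(config$stages$similarity)) {
    t0 <- as.numeric(Sys.time())
    longest <- max(trials$stimulus)
    sel <- which(trials$stimulus == longest)
    w <- traj_window(trajs, window = config$similarity$window)
    cm <- pairwise_trajectory_correlations(w[sel, , drop = FALSE])
    part <- partition_correlations(cm, trials$subject[sel], trials$session[sel])
    coef_df <- do.call(rbind, lapply(
      c("same_session", "same_subject_diff_session", "diff_subject"),
      function(g) if (length(part[[g]]))
        data.frame(group = g, r = part[[g]]) else NULL))
    write.csv(coef_df, file.path(out_dir, "similarity_coefficients.csv"),
              row.names = FALSE)
    within <- c(part$same_session, part$same_subject_diff_session)
    ks_cross <- if (length(within) && length(part$diff_subject))
      compare_distributions_ks(within, part$diff_subject) else c(D = NA, p = NA)
    ks_within <- if (length(part$same_session) &&
                       length(part$same_subject_diff_session))
      compare_distributions_ks(part$same_session,
                               part$same_subject_diff_session) else c(D = NA, p = NA)
    summary_out$similarity <- list(
      medians = as.list(setNames(part$summary$median, part$summary$group)),
      ks_within_vs_cross_p = unname(ks_cross["p"]),
      ks_same_vs_diff_session_p = unname(ks_within["p"]))
    log_stage("similarity", t0)
  }

  if (isTRUE(config$stages$choice_probability)) {
    t0 <- as.numeric(Sys.time())
    cp_rows <- list()
    bin_rows <- list()
    sig_fracs <- numeric(0)
    for (subj in unique(trials$subject)) {
      si <- trials$subject == subj
      stim <- select_max_variance_stimulus(trials[si, ])
      sel <- which(si & trials$stimulus == stim)
      series <- cp_timecourse(
        trajectory_matrix(unclass(trajs)[sel, , drop = FALSE],
                          frame_rate = attr(trajs, "frame_rate"),
                          time0 = traj_time_axis(trajs)[1]),
        trials$choice[sel],
        n_shuffles = config$cp$n_shuffles,
        seed = stage_seed(config$seed, paste("cp", subj)))
      if (isTRUE(attr(series, "usable"))) {
        cp_rows[[subj]] <- data.frame(subject = subj, stimulus = stim,
                                      as.data.frame(series))
        sig_fracs <- c(sig_fracs, mean(series$significant))
      }
      # trajectory-level CP on the pre-decision window, all stimuli pooled
      feats <- traj_window(trajs, window = config$cp$window,
                           target_fps = 120)[si, , drop = FALSE]
      wts <- choice_variance_weights(trials[si, ])
      model <- withCallingHandlers(
        fit_trajectory_choice_model(
          feats, trials$choice[si], weights = wts,
          n_components = config$cp$n_components,
          seed = stage_seed(config$seed, paste("gmm", subj))),
        message = function(m) invokeRestart("muffleMessage"))
      cps <- posterior_choice_probability(model, feats)
      binning <- bin_trials_by_cp(cps, n_bins = config$cp$n_bins)
      pb <- per_bin_psychometrics(trials[si, ], binning)
      bin_rows[[subj]] <- data.frame(
        subject = subj, bin = seq_len(binning$n_bins),
        n = binning$counts,
        bias_point = vapply(pb, `[[`, numeric(1), "bias_point"),
        converged = vapply(pb, `[[`, logical(1), "converged"))
    }
    write.csv(do.call(rbind, c(cp_rows, list(make.row.names = FALSE))),
              file.path(out_dir, "cp_series.csv"), row.names = FALSE)
    write.csv(do.call(rbind, c(bin_rows, list(make.row.names = FALSE))),
              file.path(out_dir, "cp_bins.csv"), row.names = FALSE)
    summary_out$choice_probability <- list(
      mean_significant_fraction = mean(sig_fracs))
    log_stage("choice_probability", t0)
  }

  if (isTRUE(config$stages$glm)) {
    t0 <- as.numeric(Sys.time())
    feats <- trajectory_pca(traj_window(trajs, window = config$cp$window,
                                        target_fps = 120))
    design <- build_design_matrix(trials, feats, boundary = task$boundary)
    specs <- model_specs()
    if (config$experiment$n_subjects < 2) {
      specs <- lapply(specs, setdiff, "subject")
    }
    fits <- lapply(names(specs), function(m) {
      fit_choice_glm(design, specs[[m]], model_id = m)
    })
    names(fits) <- names(specs)
    cmp <- compare_models(fits)
    write.csv(cmp$table, file.path(out_dir, "glm_table.csv"), row.names = FALSE)
    jsonlite::write_json(cmp$lr_tests, file.path(out_dir, "lr_tests.json"),
                         auto_unbox = TRUE, digits = NA)
    if (isTRUE(config$glm$stepwise)) {
      final <- lapply(names(specs), function(m) {
        stepwise_select(specs[[m]], design)$terms
      })
      jsonlite::write_json(setNames(final, names(specs)),
                           file.path(out_dir, "final_specs.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    summary_out$glm <- list(
      best_bic_model = cmp$table$model[which.min(cmp$table$bic)],
      explained_variance_pc12 =
        sum(feats$explained_variance_fraction[1:2]))
    log_stage("glm", t0)
  }

  jsonlite::write_json(summary_out, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary_out)
}
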