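#' Sample a stimulus sequence with premature-trial repetition
#'
#' Stimuli are drawn uniformly from the configured set, except that a
#' stimulus interrupted by a premature response is repeated on the following
#' trial (the animal cannot skip long intervals by responding early).
#'
#' @param config a [task_config()].
#' @param n_trials number of trials (>= 1).
#' @param premature_flags logical vector of length `n_trials`; `TRUE` at t
#'   forces trial t+1 to repeat trial t's stimulus.
#' @param seed optional integer seed.
#' @return numeric vector of stimulus durations, seconds.
#' @export
#' @examples
#' cfg <- task_config()
#' s <- sample_stimulus_sequence(cfg, 5, c(FALSE, TRUE, FALSE, FALSE, FALSE), seed = 1)
#' s[3] == s[2]
sample_stimulus_sequence <- function(config, n_trials, premature_flags = NULL,
                                     seed = NULL) {
  stopifnot(inherits(config, "task_config"), n_trials >= 1)
  if (is.null(premature_flags)) premature_flags <- rep(FALSE, n_trials)
  if (length(premature_flags) != n_trials) {
    stop("input error: premature_flags must have length n_trials")
  }
  if (!is.null(seed)) set.seed(seed)
  set <- config$stimulus_set
  out <- numeric(n_trials)
  # draws are consumed in trial order so forced repeats do not shift the
  # stream for later trials
  for (t in seq_len(n_trials)) {
    if (t > 1 && premature_flags[t - 1]) {
      out[t] <- out[t - 1]
    } else {
      out[t] <- set[sample.int(length(set), 1)]
    }
  }
  out
}

#' Default idiosyncratic trajectory template for a synthetic subject
#'
#' Each subject gets a smooth periodic head-position profile whose frequency
#' and phase depend on the subject index, so templates of different subjects
#' are close to orthogonal over the analysis window while trials of the same
#' subject share the same shape (the within/between-subject structure seen
#' in real trajectory data).
#'
#' @param subject_index positive integer identifying the subject.
#' @param amplitude template amplitude in pixels.
#' @return a function of time (seconds) returning pixels.
#' @export
default_trajectory_template <- function(subject_index, amplitude = 25) {
  force(subject_index); force(amplitude)
  freq <- 0.5 * subject_index
  phase <- 0.6 * subject_index
  function(t) amplitude * sin(2 * pi * freq * t + phase)
}

#' Half-cosine ramp carrying the latent-bias coupling into trajectories
#'
#' Zero before -0.5 s, rises as a half cosine to 1 at +0.5 s, then stays
#' at 1. The coupling is therefore time-extended and already present before
#' interval onset, the regime in which trajectory-based choice prediction
#' is informative early in the trial.
#'
#' @param t time in seconds relative to interval onset.
#' @return numeric vector in `[0, 1]`.
#' @export
coupling_mode_profile <- function(t) {
  ifelse(t <= -0.5, 0, ifelse(t >= 0.5, 1, (1 - cos(pi * (t + 0.5))) / 2))
}

# Temporally smooth AR(1) noise, one row per trial. Stationary SD = sd,
# per-frame coefficient exp(-1/(fps*tau)).
.traj_noise <- function(n_trials, n_time, sd, tau, fps) {
  if (sd <= 0) return(matrix(0, n_trials, n_time))
  phi <- exp(-1 / (fps * tau))
  innov_sd <- sd * sqrt(1 - phi^2)
  out <- matrix(rnorm(n_trials * n_time, 0, innov_sd), n_trials, n_time)
  prev <- rnorm(n_trials, 0, sd)
  for (k in seq_len(n_time)) {
    prev <- phi * prev + out[, k]
    out[, k] <- prev
  }
  out
}

#' Simulate one behavioral session with coupled head trajectories
#'
#' Generates `n_trials` trials of the duration-categorization task under the
#' generative model documented in [generative_params()]: a latent AR(1) bias
#' z_t enters both the choice log-odds and (scaled by
#' `traj_coupling_gain` and the [coupling_mode_profile()]) the head
#' trajectory, so trajectory fluctuations predict choices exactly to the
#' extent that the coupling gain is nonzero. Premature responses are never
#' rewarded and force the stimulus to repeat; rewards follow the correct-side
#' rule (long choices after intervals above the boundary, short below).
#'
#' @param config a [task_config()].
#' @param params a [generative_params()].
#' @param n_trials number of trials (>= 1).
#' @param subject,session labels stored in the trial table.
#' @param subject_index integer used to pick the default trajectory template
#'   when `params$traj_template` is `NULL`.
#' @param t_range time support of the trajectory grid, seconds relative to
#'   interval onset (half-open).
#' @return list of class `cp_session` with elements
#'   `trials` (data.frame: subject, session, trial, stimulus, choice,
#'   rewarded, premature, prev_stimulus, prev_reward_code, prev_difficulty,
#'   latent_bias) and `trajectories` (a [trajectory_matrix()] with one row
#'   per trial). `latent_bias` is the generative ground truth z_t.
#' @export
simulate_session <- function(config = task_config(),
                             params = generative_params(),
                             n_trials = 456,
                             subject = "subject1", session = "session1",
                             subject_index = 1,
                             t_range = c(-0.5, 2.5)) {
  stopifnot(inherits(config, "task_config"), inherits(params, "generative_params"),
            n_trials >= 1)
  if (!is.null(params$seed)) set.seed(params$seed)

  ar <- params$latent_ar_coeff
  innov_sd <- params$latent_noise_sd * sqrt(1 - ar^2)
  boundary <- config$boundary
  set <- config$stimulus_set

  z <- numeric(n_trials)
  stimulus <- numeric(n_trials)
  choice_long <- logical(n_trials)
  premature <- logical(n_trials)
  rewarded <- logical(n_trials)
  prev_reward_code <- integer(n_trials)
  prev_stimulus <- rep(NA_real_, n_trials)

  z_prev <- rnorm(1, 0, params$latent_noise_sd)
  r_prev <- 0L
  for (t in seq_len(n_trials)) {
    z_t <- ar * z_prev + rnorm(1, 0, innov_sd)
    if (t > 1 && premature[t - 1]) {
      stim <- stimulus[t - 1]
    } else {
      stim <- set[sample.int(length(set), 1)]
    }
    p_long <- plogis(params$psycho_slope * (log(stim) - log(boundary)) +
                       params$psycho_bias + z_t +
                       params$history_reward_weight * r_prev)
    ch <- runif(1) < p_long
    prem <- runif(1) < min(1, params$premature_rate_base * stim / boundary)
    correct <- (ch && stim > boundary) || (!ch && stim < boundary)
    rew <- correct && !prem

    z[t] <- z_t
    stimulus[t] <- stim
    choice_long[t] <- ch
    premature[t] <- prem
    rewarded[t] <- rew
    prev_reward_code[t] <- r_prev
    if (t > 1) prev_stimulus[t] <- stimulus[t - 1]

    r_prev <- if (rew && ch) 1L else if (rew && !ch) -1L else 0L
    z_prev <- z_t
  }

  trials <- data.frame(
    subject = subject,
    session = session,
    trial = seq_len(n_trials),
    stimulus = stimulus,
    choice = ifelse(choice_long, "long", "short"),
    rewarded = rewarded,
    premature = premature,
    prev_stimulus = prev_stimulus,
    prev_reward_code = prev_reward_code,
    prev_difficulty = abs(prev_stimulus - boundary),
    latent_bias = z,
    stringsAsFactors = FALSE
  )

  fps <- config$frame_rate
  n_time <- round((t_range[2] - t_range[1]) * fps)
  tgrid <- t_range[1] + (seq_len(n_time) - 1) / fps
  template <- params$traj_template
  if (is.null(template)) template <- default_trajectory_template(subject_index)
  pos <- matrix(template(tgrid), n_trials, n_time, byrow = TRUE) +
    outer(params$traj_coupling_gain * z, coupling_mode_profile(tgrid)) +
    .traj_noise(n_trials, n_time, params$traj_noise_sd, params$traj_noise_tau, fps)

  structure(
    list(trials = trials,
         trajectories = trajectory_matrix(pos, frame_rate = fps,
                                          time0 = t_range[1]),
         config = config, params = params),
    class = "cp_session"
  )
}

#' Simulate a multi-subject, multi-session experiment
#'
#' Runs [simulate_session()] for every (subject, session) combination with
#' per-session seeds derived deterministically from `seed` and distinct
#' default trajectory templates per subject, then row-binds trial tables and
#' trajectory matrices.
#'
#' @param config a [task_config()].
#' @param params a [generative_params()]; its `seed` field is ignored in
#'   favor of per-session derived seeds.
#' @param n_subjects,sessions_per_subject,trials_per_session experiment size.
#' @param seed master integer seed.
#' @return list of class `cp_experiment` with `trials` and `trajectories`
#'   covering all sessions (rows aligned).
#' @export
simulate_experiment <- function(config = task_config(),
                                params = generative_params(),
                                n_subjects = 3,
                                sessions_per_subject = 2,
                                trials_per_session = 456,
                                seed = 1) {
  all_trials <- list()
  all_traj <- list()
  for (i in seq_len(n_subjects)) {
    subj <- sprintf("subject%d", i)
    for (j in seq_len(sessions_per_subject)) {
      sess <- sprintf("session%d", j)
      p <- params
      p$seed <- stage_seed(seed, paste(subj, sess))
      if (is.null(p$traj_template)) p$traj_template <- default_trajectory_template(i)
      s <- simulate_session(config, p, trials_per_session,
                            subject = subj, session = sess, subject_index = i)
      all_trials[[length(all_trials) + 1]] <- s$trials
      all_traj[[length(all_traj) + 1]] <- unclass(s$trajectories)
    }
  }
  trials <- do.call(rbind, all_trials)
  rownames(trials) <- NULL
  pos <- do.call(rbind, all_traj)
  structure(
    list(trials = trials,
         trajectories = trajectory_matrix(pos, frame_rate = config$frame_rate,
                                          time0 = traj_time_axis(all_traj[[1]])[1]),
         config = config, params = params, seed = seed),
    class = "cp_experiment"
  )
}

#' @export
print.cp_session <- function(x, ...) {
  cat("Synthetic session:", nrow(x$trials), "trials,",
      ncol(x$trajectories), "trajectory samples/trial\n")
  invisible(x)
}

#' @export
print.cp_experiment <- function(x, ...) {
  cat("Synthetic experiment:", length(unique(x$trials$subject)), "subjects,",
      nrow(x$trials), "trials\n")
  invisible(x)
}

#' Write / read a session trial table as CSV
#'
#' The canonical column set (subject, session, trial, stimulus, choice,
#' rewarded, premature) is always present; extra columns (history context,
#' generative ground truth) round-trip unchanged.
#'
#' @param trials trial data.frame as produced by [simulate_session()].
#' @param path CSV path.
#' @export
write_session_csv <- function(trials, path) {
  core <- c("subject", "session", "trial", "stimulus", "choice",
            "rewarded", "premature")
  missing <- setdiff(core, names(trials))
  if (length(missing) > 0) {
    stop("input error: trial table lacks columns: ", paste(missing, collapse = ", "))
  }
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_csv
#' @export
read_session_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
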