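#' Task configuration for a duration-categorization session
#'
#' Describes the behavioral task: the set of stimulus intervals, the
#' categorical boundary separating "short" from "long", reinforcement
#' timing, the cueing tones and the video frame rate. Defaults reproduce
#' the rat task: eight intervals symmetric about a 1.5 s boundary in four
#' difficulty levels, 11 s error timeout, 150 ms / 7 kHz tones, 120
#' frames/s video (use 90 for the mouse task).
#'
#' @param stimulus_set numeric vector of interval durations in seconds.
#'   Every stimulus must have its mirror `2 * boundary - s` in the set.
#' @param boundary categorical boundary in seconds; must lie strictly
#'   inside the stimulus range.
#' @param long_reward_side which choice port is rewarded after long
#'   intervals ("left" or "right").
#' @param timeout_error timeout after an incorrect or premature response,
#'   seconds.
#' @param timeout_trial_spacing minimum spacing between trial initiations,
#'   seconds.
#' @param tone_duration duration of the interval-delimiting tones, seconds.
#' @param tone_freq tone frequency, Hz.
#' @param frame_rate video frame rate in frames/s; any positive value is
#'   accepted (120 and 90 are the values used in practice).
#'
#' @return An object of class `task_config`.
#' @export
#' @examples
#' cfg <- task_config()
#' cfg$stimulus_set
task_config <- function(stimulus_set = c(0.6, 1.05, 1.26, 1.38, 1.62, 1.74, 1.95, 2.4),
                        boundary = 1.5,
                        long_reward_side = c("left", "right"),
                        timeout_error = 11,
                        timeout_trial_spacing = 9,
                        tone_duration = 0.15,
                        tone_freq = 7000,
                        frame_rate = 120) {
  if (length(stimulus_set) == 0) {
    stop("configuration error: 'stimulus_set' must not be empty")
  }
  if (!is.numeric(stimulus_set) || any(!is.finite(stimulus_set)) || any(stimulus_set <= 0)) {
    stop("configuration error: stimuli must be positive finite durations")
  }
  long_reward_side <- match.arg(long_reward_side)
  if (!(boundary > min(stimulus_set) && boundary < max(stimulus_set))) {
    stop("configuration error: boundary must lie strictly inside the stimulus range")
  }
  mirrors <- 2 * boundary - stimulus_set
  has_mirror <- vapply(mirrors, function(m) any(abs(stimulus_set - m) < 1e-9), logical(1))
  if (!all(has_mirror)) {
    stop("configuration error: every stimulus must have its mirror 2*boundary - s in the set")
  }
  if (!is.numeric(frame_rate) || frame_rate <= 0) {
    stop("configuration error: frame_rate must be positive")
  }
  structure(
    list(
      stimulus_set = sort(stimulus_set),
      boundary = boundary,
      long_reward_side = long_reward_side,
      timeout_error = timeout_error,
      timeout_trial_spacing = timeout_trial_spacing,
      tone_duration = tone_duration,
      tone_freq = tone_freq,
      frame_rate = frame_rate
    ),
    class = "task_config"
  )
}

#' Generative parameters for synthetic sessions
#'
#' Parameters of the generative model behind [simulate_session()]. The model
#' is: per trial t, a latent bias z_t follows an AR(1) process across trials
#' (stationary SD `latent_noise_sd`, coefficient `latent_ar_coeff`); the
#' probability of a "long" report is
#' `plogis(psycho_slope * (log I - log boundary) + psycho_bias + z_t +
#' history_reward_weight * R_{t-1})` with R the signed previous-reward code;
#' and the head trajectory is an idiosyncratic subject template plus
#' `traj_coupling_gain * z_t` times a fixed half-cosine ramp profile, plus
#' temporally smooth AR(1) noise. With `traj_coupling_gain = 0` trajectories
#' carry no choice information by construction.
#'
#' Defaults are calibrated to the published task statistics: slope 10 per
#' log-second and latent SD 1 jointly give roughly 96% / 67% / 84% correct
#' on easiest / hardest / all stimuli; `premature_rate_base = 0.067` is the
#' rats' mean premature-response rate; `history_reward_weight = 0.4`
#' reproduces a previous-reward effect of the magnitude implied by the
#' published model comparison.
#'
#' @param psycho_slope psychometric slope, 1/log-seconds.
#' @param psycho_bias constant bias on the log-odds of choosing long.
#' @param latent_ar_coeff AR(1) coefficient of the latent bias across trials,
#'   in `[0, 1)`.
#' @param latent_noise_sd stationary standard deviation of the latent bias
#'   (log-odds units).
#' @param traj_coupling_gain pixels of trajectory displacement per latent
#'   unit; 0 decouples trajectories from choices.
#' @param history_reward_weight weight of the signed previous-reward code on
#'   the choice log-odds.
#' @param premature_rate_base baseline premature-response probability; the
#'   per-trial rate scales with stimulus duration as `base * I / boundary`.
#' @param traj_template function of time (seconds) returning the subject's
#'   template head position in pixels, or `NULL` to use
#'   [default_trajectory_template()] keyed by subject index.
#' @param traj_noise_sd stationary SD of the smooth trajectory noise, pixels.
#' @param traj_noise_tau time constant of the trajectory noise, seconds.
#' @param seed integer seed; identical seeds give bit-identical sessions.
#'
#' @return An object of class `generative_params`.
#' @export
generative_params <- function(psycho_slope = 10,
                              psycho_bias = 0,
                              latent_ar_coeff = 0.9,
                              latent_noise_sd = 1,
                              traj_coupling_gain = 4,
                              history_reward_weight = 0.4,
                              premature_rate_base = 0.067,
                              traj_template = NULL,
                              traj_noise_sd = 4,
                              traj_noise_tau = 0.1,
                              seed = NULL) {
  num <- c(psycho_slope = psycho_slope, psycho_bias = psycho_bias,
           latent_ar_coeff = latent_ar_coeff, latent_noise_sd = latent_noise_sd,
           traj_coupling_gain = traj_coupling_gain,
           history_reward_weight = history_reward_weight,
           premature_rate_base = premature_rate_base,
           traj_noise_sd = traj_noise_sd, traj_noise_tau = traj_noise_tau)
  if (any(!is.finite(num))) {
    stop("parameter error: non-finite generative parameter: ",
         paste(names(num)[!is.finite(num)], collapse = ", "))
  }
  if (latent_ar_coeff < 0 || latent_ar_coeff >= 1) {
    stop("parameter error: latent_ar_coeff must lie in [0, 1)")
  }
  if (premature_rate_base < 0 || premature_rate_base > 1) {
    stop("parameter error: premature_rate_base must be a probability")
  }
  if (!is.null(traj_template) && !is.function(traj_template)) {
    stop("parameter error: traj_template must be a function of time or NULL")
  }
  structure(
    list(psycho_slope = psycho_slope, psycho_bias = psycho_bias,
         latent_ar_coeff = latent_ar_coeff, latent_noise_sd = latent_noise_sd,
         traj_coupling_gain = traj_coupling_gain,
         history_reward_weight = history_reward_weight,
         premature_rate_base = premature_rate_base,
         traj_template = traj_template,
         traj_noise_sd = traj_noise_sd, traj_noise_tau = traj_noise_tau,
         seed = seed),
    class = "generative_params"
  )
}

#' @export
print.task_config <- function(x, ...) {
  cat("Duration-categorization task config\n")
  cat("  stimuli (s):", paste(x$stimulus_set, collapse = ", "), "\n")
  cat("  boundary:", x$boundary, "s; long rewarded at", x$long_reward_side, "port\n")
  cat("  frame rate:", x$frame_rate, "frames/s\n")
  invisible(x)
}
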