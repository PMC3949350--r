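#' Fit a logistic psychometric function to one session
#'
#' Maximum-likelihood logistic regression of the probability of a "long"
#' report on the (transformed) stimulus duration. The default predictor is
#' log-duration, matching the near-geometric spacing of the stimulus set;
#' linear duration is available. No lapse parameter is fit: well-trained
#' subjects' curves asymptote at 0 and 1. Complete separation is flagged by
#' `converged = FALSE` rather than penalized.
#'
#' @param trials data.frame with columns `stimulus` (seconds) and `choice`
#'   (`"long"`/`"short"`); needs at least two distinct stimulus values.
#' @param transform `"log_duration"` or `"linear_duration"`.
#' @return object of class `psychometric_fit`: `intercept`, `slope` (on the
#'   transformed predictor), `stimulus_transform`, `bias_point` (stimulus in
#'   seconds judged long 50% of the time), `n_trials`, `converged`.
#' @export
#' @examples
#' s <- simulate_session(params = generative_params(seed = 1), n_trials = 400)
#' fit <- fit_psychometric(s$trials)
#' fit$bias_point
fit_psychometric <- function(trials,
                             transform = c("log_duration", "linear_duration")) {
  transform <- match.arg(transform)
  stim <- trials$stimulus
  if (length(unique(stim)) < 2) {
    stop("degenerate design: need >= 2 distinct stimulus values")
  }
  if (transform == "log_duration" && any(stim <= 0)) {
    stop("domain error: non-positive stimulus with log transform")
  }
  y <- trials$choice == "long"
  x <- if (transform == "log_duration") log(stim) else stim
  fit <- suppressWarnings(glm(y ~ x, family = binomial()))
  b <- unname(coef(fit))
  separated <- any(fitted(fit) < 1e-8 | fitted(fit) > 1 - 1e-8) &&
    max(abs(b)) > 25
  converged <- isTRUE(fit$converged) && !separated && all(is.finite(b))
  bias_point <- if (abs(b[2]) > 1e-12) {
    xb <- -b[1] / b[2]
    if (transform == "log_duration") exp(xb) else xb
  } else {
    NA_real_
  }
  structure(
    list(intercept = b[1], slope = b[2], stimulus_transform = transform,
         bias_point = bias_point, n_trials = length(y), converged = converged),
    class = "psychometric_fit"
  )
}

#' Predicted probability of a "long" report
#'
#' @param fit a `psychometric_fit`.
#' @param stimulus stimulus duration(s) in seconds (> 0).
#' @return probability in `(0, 1)`, monotone in stimulus when the slope is
#'   positive.
#' @export
predict_p_long <- function(fit, stimulus) {
  stopifnot(inherits(fit, "psychometric_fit"))
  if (any(stimulus <= 0)) {
    if (fit$stimulus_transform == "log_duration") {
      stop("domain error: non-positive stimulus with log transform")
    }
    stop("stimulus must be positive")
  }
  x <- if (fit$stimulus_transform == "log_duration") log(stimulus) else stimulus
  plogis(fit$intercept + fit$slope * x)
}

#' Summarize a subject by averaging session fit parameters
#'
#' Parameter-wise mean of intercept and slope over the converged session
#' fits; the summary bias point is recomputed from the averaged parameters
#' (and therefore need not equal the mean of session bias points).
#'
#' @param fits list of `psychometric_fit` objects sharing one transform.
#' @return a `psychometric_fit` summarizing the subject.
#' @export
summarize_subject <- function(fits) {
  if (inherits(fits, "psychometric_fit")) fits <- list(fits)
  fits <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(fits) == 0) stop("summary error: no converged session fits")
  transforms <- unique(vapply(fits, `[[`, character(1), "stimulus_transform"))
  if (length(transforms) != 1) {
    stop("summary error: fits use different stimulus transforms")
  }
  a <- mean(vapply(fits, `[[`, numeric(1), "intercept"))
  b <- mean(vapply(fits, `[[`, numeric(1), "slope"))
  bias_point <- if (abs(b) > 1e-12) {
    xb <- -a / b
    if (transforms == "log_duration") exp(xb) else xb
  } else NA_real_
  structure(
    list(intercept = a, slope = b, stimulus_transform = transforms,
         bias_point = bias_point,
         n_trials = sum(vapply(fits, `[[`, numeric(1), "n_trials")),
         converged = TRUE),
    class = "psychometric_fit"
  )
}

#' Filter sessions by performance on the easiest stimuli
#'
#' Keeps sessions whose fraction of correct reports on the extreme (easiest)
#' stimuli reaches `min_easy_correct`, the performance-based screening
#' applied before psychometric analysis.
#'
#' @param trials trial data.frame with `session`, `stimulus`, `choice`.
#' @param boundary categorical boundary, seconds.
#' @param min_easy_correct minimum fraction correct on the shortest and
#'   longest stimuli.
#' @return the trial rows of the retained sessions.
#' @export
filter_sessions <- function(trials, boundary = 1.5, min_easy_correct = 0.9) {
  easiest <- range(trials$stimulus)
  keep <- vapply(split(trials, trials$session), function(d) {
    e <- d[d$stimulus %in% easiest, , drop = FALSE]
    if (nrow(e) == 0) return(FALSE)
    correct <- (e$choice == "long") == (e$stimulus > boundary)
    mean(correct) >= min_easy_correct
  }, logical(1))
  trials[trials$session %in% names(keep)[keep], , drop = FALSE]
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("Psychometric fit (%s): intercept %.3f, slope %.3f, bias point %.3f s, n = %d%s\n",
              x$stimulus_transform, x$intercept, x$slope, x$bias_point,
              x$n_trials, if (x$converged) "" else " [not converged]"))
  invisible(x)
}
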