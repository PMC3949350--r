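#' Fit class-conditional trajectory likelihoods for Bayesian choice probability
#'
#' Fits one Gaussian mixture density per choice class to trajectory vectors
#' **H** (by convention head positions in the 1 s window centered on
#' interval onset, 120 samples at 120 frames/s: the pre-decision window
#' common to all stimuli), by weighted maximum likelihood. Each trial's
#' weight is the binomial choice variance of its (session, stimulus) cell
#' (see [choice_variance_weights()]); zero-weight trials have exactly no
#' influence. Class priors P(C) are the weighted class frequencies. The
#' posterior P(long | **H**) then follows from Bayes' rule via
#' [posterior_choice_probability()].
#'
#' When either class has fewer effective trials (the Kish effective sample
#' size of its weights, which the raw count equals under flat weights) than
#' `stability_factor * n_components * (dim + 1)`, the model is fit in the
#' subspace of leading principal components retaining at least
#' `var_retained` of the pooled trajectory variance (a dimensionality guard
#' for small samples, where full covariances would overfit and saturate the
#' posteriors; a message is emitted).
#'
#' @param features numeric matrix, trials x dimensions (windowed trajectory
#'   vectors, e.g. from [traj_window()] with `window = c(-0.5, 0.5)` and
#'   `target_fps = 120`).
#' @param choices `"long"`/`"short"` per trial.
#' @param weights per-trial non-negative weights; `NULL` for flat weights.
#' @param n_components mixture components per class (default 2).
#' @param seed integer seed for the EM initialization.
#' @param ridge diagonal regularization added to component covariances.
#' @param var_retained variance fraction retained by the PCA guard.
#' @param stability_factor minimum effective trials per dimension-parameter
#'   per component before the PCA guard engages.
#' @return object of class `trajectory_cp_model`: per-class mixtures,
#'   priors, the (possibly identity) feature projection, and fit metadata.
#' @export
fit_trajectory_choice_model <- function(features, choices, weights = NULL,
                                        n_components = 2, seed = 1,
                                        ridge = 1e-6, var_retained = 0.9,
                                        stability_factor = 5) {
  X <- as.matrix(features)
  n <- nrow(X); d <- ncol(X)
  if (length(choices) != n) stop("input error: choices misaligned with features")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("input error: weights misaligned with features")
  if (any(weights < 0)) stop("input error: negative weights")

  keep <- weights > 0
  X <- X[keep, , drop = FALSE]
  ch <- choices[keep]
  w <- weights[keep]
  long <- ch == "long"
  n_class <- c(long = sum(long), short = sum(!long))
  if (any(n_class < n_components)) {
    stop("input error: a choice class has fewer effective trials than components")
  }
  # effective trials per class under the weighting (Kish effective sample
  # size); with flat weights this is the raw count
  ess <- vapply(list(w[long], w[!long]),
                function(v) sum(v)^2 / sum(v^2), numeric(1))

  center <- colMeans(X)
  rotation <- NULL
  # full d-dimensional covariances need several effective trials per
  # dimension per component to be stable; below that the in-sample
  # likelihoods overfit and posteriors saturate
  if (min(ess) < stability_factor * n_components * (d + 1)) {
    pr <- prcomp(X, center = TRUE, scale. = FALSE)
    ev <- pr$sdev^2
    k <- which(cumsum(ev) / sum(ev) >= var_retained)[1]
    k <- max(1, min(k, floor(min(ess) / (stability_factor * n_components)), d))
    rotation <- pr$rotation[, seq_len(k), drop = FALSE]
    center <- pr$center
    message(sprintf(
      "dimensionality guard: fitting in top-%d PCA subspace (%d-D input, min class ESS = %.0f)",
      k, d, min(ess)))
  }
  Z <- if (is.null(rotation)) X else sweep(X, 2, center) %*% rotation

  fit_class <- function(idx, offset) {
    wz <- w[idx] / mean(w[idx])
    set.seed(seed + offset)
    .fit_wgmm(Z[idx, , drop = FALSE], wz, n_components, ridge = ridge)
  }
  mix_long <- fit_class(which(long), 0L)
  mix_short <- fit_class(which(!long), 1L)
  prior_long <- sum(w[long]) / sum(w)

  structure(
    list(likelihood_long = mix_long, likelihood_short = mix_short,
         prior_long = prior_long, prior_short = 1 - prior_long,
         n_components = n_components,
         center = center, rotation = rotation, d_input = d,
         n_effective = n_class),
    class = "trajectory_cp_model"
  )
}

#' Posterior choice probability of single-trial trajectories
#'
#' Bayes' rule applied to the fitted class-conditional mixture densities:
#' `P(C | H) = P(H | C) P(C) / sum_C' P(H | C') P(C')`, evaluated entirely
#' in the log domain so extreme trajectories never yield `NaN`. The
#' posterior is invariant to rescaling both likelihoods by any positive
#' constant, and the two class posteriors sum to 1 by construction.
#'
#' @param model a `trajectory_cp_model`.
#' @param traj one trajectory vector or a matrix of them (rows), matching
#'   the model's input dimensionality.
#' @return numeric vector of `P(long | H)` per trajectory.
#' @export
posterior_choice_probability <- function(model, traj) {
  X <- if (is.matrix(traj)) traj else matrix(traj, nrow = 1)
  if (ncol(X) != model$d_input) {
    stop("input error: trajectory dimensionality does not match model")
  }
  Z <- if (is.null(model$rotation)) X else
    sweep(X, 2, model$center) %*% model$rotation
  ll_long <- .wgmm_logdens(model$likelihood_long, Z) + log(model$prior_long)
  ll_short <- .wgmm_logdens(model$likelihood_short, Z) + log(model$prior_short)
  plogis(ll_long - ll_short)
}

#' Bin trials into equal-count choice-probability bins
#'
#' Quantile binning: trials sorted by CP are split into `n_bins` contiguous
#' groups whose sizes differ by at most one; ties are broken by stable trial
#' order, so identical CPs still yield equal counts. Bin index is
#' non-decreasing in CP.
#'
#' @param cps posterior choice probability per trial.
#' @param n_bins number of bins (default 6, >= 2).
#' @return object of class `cp_binning`: `assignments` (bin per trial),
#'   `counts`, `n_bins`, `bin_edges` (CP values at bin boundaries).
#' @export
bin_trials_by_cp <- function(cps, n_bins = 6) {
  n <- length(cps)
  if (n_bins < 2) stop("input error: n_bins must be >= 2")
  if (n < n_bins) stop("input error: fewer trials than bins")
  ord <- order(cps)  # stable for ties
  sizes <- diff(round(seq(0, n, length.out = n_bins + 1)))
  assignments <- integer(n)
  assignments[ord] <- rep(seq_len(n_bins), sizes)
  sorted <- cps[ord]
  edges <- c(sorted[1], sorted[cumsum(sizes)])
  structure(
    list(assignments = assignments, counts = as.integer(sizes),
         n_bins = n_bins, bin_edges = edges),
    class = "cp_binning"
  )
}

#' Psychometric functions per choice-probability bin
#'
#' Fits a logistic psychometric function to the trials of each CP bin.
#' With trajectory-choice coupling present, bin-wise bias points are
#' ordered in bin index while every bin's curve still asymptotes near 0
#' and 1 at the extreme stimuli: the trajectory shifts the bias, not the
#' lapse rate. Degenerate bins (a single stimulus value, or a failed fit)
#' are flagged rather than fit.
#'
#' @param trials trial data.frame aligned with the binned CPs.
#' @param binning a `cp_binning`.
#' @param transform stimulus transform passed to [fit_psychometric()].
#' @return list of `psychometric_fit` objects (or flagged placeholders with
#'   `converged = FALSE` and `flagged = TRUE`), one per bin.
#' @export
per_bin_psychometrics <- function(trials, binning,
                                  transform = "log_duration") {
  stopifnot(inherits(binning, "cp_binning"))
  if (nrow(trials) != length(binning$assignments)) {
    stop("input error: trials misaligned with binning")
  }
  lapply(seq_len(binning$n_bins), function(b) {
    sub <- trials[binning$assignments == b, , drop = FALSE]
    tryCatch(
      fit_psychometric(sub, transform = transform),
      error = function(e) {
        structure(list(intercept = NA_real_, slope = NA_real_,
                       stimulus_transform = transform, bias_point = NA_real_,
                       n_trials = nrow(sub), converged = FALSE, flagged = TRUE),
                  class = "psychometric_fit")
      }
    )
  })
}
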