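#' Binomial choice variance of a (session, stimulus) cell
#'
#' The within-cell variance of the choice count, `n * p * (1 - p)` with
#' `p` the fraction of long choices. It is zero exactly when choices are
#' unanimous and at most `n / 4`; it is used to weight trials when fitting
#' trajectory likelihoods, concentrating influence on stimuli whose
#' ambiguity lets non-stimulus factors drive choice.
#'
#' @param n_long number of long choices in the cell.
#' @param n_total total trials in the cell (>= 1).
#' @return list: `n`, `n_long`, `p_long`, `variance`.
#' @export
#' @examples
#' choice_variance(34, 56)$variance  # 13.3571...
choice_variance <- function(n_long, n_total) {
  if (n_total < 1) stop("input error: n_total must be >= 1")
  if (n_long < 0 || n_long > n_total) stop("input error: 0 <= n_long <= n_total")
  p <- n_long / n_total
  list(n = n_total, n_long = n_long, p_long = p,
       variance = n_total * p * (1 - p))
}

#' Per-trial weights from (session, stimulus) choice variance
#'
#' Every trial receives the binomial choice variance of its
#' (session, stimulus) cell, so unanimously decided cells contribute zero
#' weight.
#'
#' @param trials trial data.frame with `session`, `stimulus`, `choice`.
#' @return numeric weight per trial.
#' @export
choice_variance_weights <- function(trials) {
  cell <- interaction(trials$session, trials$stimulus, drop = TRUE)
  y <- as.numeric(trials$choice == "long")
  stats::ave(y, cell, FUN = function(ch) length(ch) * mean(ch) * (1 - mean(ch)))
}

#' Stimulus of highest choice variance, pooled across sessions
#'
#' For time-resolved choice-probability profiles one near-boundary stimulus
#' is analyzed per subject: the one whose pooled (across sessions) binomial
#' choice variance is highest.
#'
#' @param trials trial data.frame with `stimulus`, `choice`.
#' @return the selected stimulus duration (seconds).
#' @export
select_max_variance_stimulus <- function(trials) {
  v <- vapply(split(trials$choice == "long", trials$stimulus), function(y) {
    length(y) * mean(y) * (1 - mean(y))
  }, numeric(1))
  as.numeric(names(v)[which.max(v)])
}

#' Instantaneous choice probability: rectified auROC
#'
#' The area under the ROC curve comparing head positions on long- versus
#' short-choice trials equals the probability that a random long-trial
#' position exceeds a random short-trial position (ties counted one half).
#' The area is rectified about 0.5, so the returned value in `[0.5, 1]`
#' measures separability regardless of direction; the unrectified area is
#' kept in attribute `raw`.
#'
#' @param pos_long,pos_short numeric samples of head position on long- and
#'   short-choice trials; both non-empty.
#' @return rectified auROC with attribute `raw`.
#' @export
#' @examples
#' instantaneous_cp(c(0, 2), c(0, 1))  # 0.625
instantaneous_cp <- function(pos_long, pos_short) {
  nl <- length(pos_long); ns <- length(pos_short)
  if (nl == 0 || ns == 0) stop("undefined: empty choice class")
  r <- rank(c(pos_long, pos_short), ties.method = "average")
  a <- (sum(r[seq_len(nl)]) - nl * (nl + 1) / 2) / (nl * ns)
  structure(max(a, 1 - a), raw = a)
}

# auROC per column from a precomputed midrank matrix; ranks are independent
# of the labels, so shuffle nulls reduce to re-selecting rows.
.auroc_cols <- function(rank_mat, long_idx, ns) {
  nl <- length(long_idx)
  (colSums(rank_mat[long_idx, , drop = FALSE]) - nl * (nl + 1) / 2) / (nl * ns)
}

#' Time-resolved choice probability with a shuffle null band
#'
#' Computes the rectified auROC between long- and short-choice head
#' positions at every timepoint, plus a one-sided 95% chance band: choice
#' labels are shuffled `n_shuffles` times, the rectified auROC recomputed,
#' and the per-timepoint 95th percentile of the shuffle distribution taken
#' as the significance threshold. A timepoint is significant when its CP
#' exceeds that threshold. By convention the analysis is applied separately
#' per subject and stimulus; this function operates on whatever trial slice
#' it is given.
#'
#' @param trajs trajectory matrix (trials x time) with a time axis.
#' @param choices vector of `"long"`/`"short"` labels, one per trial.
#' @param window optional `[t0, t1)` restriction in seconds (default: the
#'   full support, nominally -0.5 s to 2.5 s around initiation).
#' @param n_shuffles number of label shuffles for the null (default 100).
#' @param seed optional integer seed for the shuffles.
#' @return data.frame of class `cp_series`: `time`, `cp`, `null_upper`,
#'   `significant`; attribute `usable` is `FALSE` (and values `NA`) when a
#'   choice class has fewer than 2 trials.
#' @export
cp_timecourse <- function(trajs, choices, window = NULL, n_shuffles = 100,
                          seed = NULL) {
  pos <- unclass(trajs)
  ta <- attr(trajs, "time_axis")
  if (is.null(ta)) ta <- seq_len(ncol(pos))
  if (!is.null(window)) {
    keep <- ta >= window[1] - 1e-9 & ta < window[2] - 1e-9
    pos <- pos[, keep, drop = FALSE]
    ta <- ta[keep]
  }
  long <- choices == "long"
  nl <- sum(long); ns <- sum(!long)
  if (nl < 2 || ns < 2) {
    out <- data.frame(time = ta, cp = NA_real_, null_upper = NA_real_,
                      significant = NA)
    attr(out, "usable") <- FALSE
    class(out) <- c("cp_series", class(out))
    return(out)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(pos)
  rank_mat <- apply(pos, 2, rank, ties.method = "average")
  a_obs <- .auroc_cols(rank_mat, which(long), ns)
  cp <- pmax(a_obs, 1 - a_obs)
  null_cp <- matrix(NA_real_, n_shuffles, ncol(pos))
  for (s in seq_len(n_shuffles)) {
    idx <- sample.int(n, nl)
    a <- .auroc_cols(rank_mat, idx, ns)
    null_cp[s, ] <- pmax(a, 1 - a)
  }
  null_upper <- apply(null_cp, 2, quantile, probs = 0.95, names = FALSE)
  out <- data.frame(time = ta, cp = cp, null_upper = null_upper,
                    significant = cp > null_upper)
  attr(out, "usable") <- TRUE
  attr(out, "n_shuffles") <- n_shuffles
  class(out) <- c("cp_series", class(out))
  out
}
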