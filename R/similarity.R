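#' Pairwise Pearson correlations between trial trajectories
#'
#' Correlates every pair of trials' head-position time series. Rows with
#' (numerically) zero variance have undefined correlations; they are
#' returned as `NA` and their indices recorded in attribute `undefined`.
#'
#' @param trajs a [trajectory_matrix()] or plain matrix (trials x time);
#'   by convention the window restricted to the longest-interval trials'
#'   common support (see [traj_window()]).
#' @return symmetric correlation matrix with unit diagonal (for defined
#'   rows) and attribute `undefined`.
#' @export
pairwise_trajectory_correlations <- function(trajs) {
  m <- unclass(trajs)
  if (nrow(m) < 2) stop("input error: need >= 2 trials")
  rv <- apply(m, 1, var)
  flat <- which(rv < 1e-24)
  cm <- suppressWarnings(cor(t(m)))
  if (length(flat) > 0) {
    cm[flat, ] <- NA_real_
    cm[, flat] <- NA_real_
  }
  d <- diag(cm)
  d[setdiff(seq_len(nrow(m)), flat)] <- 1
  diag(cm) <- d
  attr(cm, "undefined") <- flat
  cm
}

#' Partition pairwise correlations by subject and session identity
#'
#' Routes every upper-triangle coefficient to exactly one of three groups:
#' same session, same subject but different session, or different subjects.
#' Undefined (`NA`) coefficients are excluded, with a count recorded.
#'
#' @param corr_matrix symmetric matrix from
#'   [pairwise_trajectory_correlations()].
#' @param subject_labels,session_labels vectors aligned with the matrix rows.
#' @return object of class `correlation_partition`: the three coefficient
#'   vectors, a `summary` data.frame of medians and interquartile ranges,
#'   and `n_undefined`.
#' @export
partition_correlations <- function(corr_matrix, subject_labels, session_labels) {
  n <- nrow(corr_matrix)
  if (length(subject_labels) != n || length(session_labels) != n) {
    stop("input error: label length does not match matrix")
  }
  ut <- which(upper.tri(corr_matrix), arr.ind = TRUE)
  r <- corr_matrix[ut]
  same_subj <- subject_labels[ut[, 1]] == subject_labels[ut[, 2]]
  same_sess <- same_subj & (session_labels[ut[, 1]] == session_labels[ut[, 2]])
  ok <- !is.na(r)
  groups <- list(
    same_session = r[ok & same_sess],
    same_subject_diff_session = r[ok & same_subj & !same_sess],
    diff_subject = r[ok & !same_subj]
  )
  summ <- data.frame(
    group = names(groups),
    n = vapply(groups, length, integer(1)),
    median = vapply(groups, function(g) if (length(g)) median(g) else NA_real_,
                    numeric(1)),
    iqr = vapply(groups, function(g) if (length(g)) IQR(g) else NA_real_,
                 numeric(1)),
    row.names = NULL
  )
  structure(c(groups, list(summary = summ, n_undefined = sum(!ok))),
            class = "correlation_partition")
}

#' Two-sample Kolmogorov-Smirnov comparison of coefficient distributions
#'
#' @param a,b non-empty numeric samples (e.g. two groups from
#'   [partition_correlations()]).
#' @return named vector: `D` (sup-distance between ECDFs) and `p` (two-sided
#'   p-value).
#' @export
compare_distributions_ks <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("input error: empty sample")
  kt <- suppressWarnings(ks.test(a, b))
  p <- unname(kt$p.value)
  if (is.na(p)) {
    # the asymptotic Kolmogorov tail can underflow to NA at extreme D;
    # evaluate the series Q(t) = 2 * sum (-1)^(k-1) exp(-2 k^2 t^2) directly
    t_stat <- sqrt(length(a) * length(b) / (length(a) + length(b))) *
      unname(kt$statistic)
    k <- 1:100
    p <- min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t_stat^2))))
  }
  c(D = unname(kt$statistic), p = p)
}

#' Pointwise mean trajectory over a group of trials
#'
#' @param trajs trajectory matrix (trials x time).
#' @param group trial (row) indices; non-empty.
#' @return numeric vector, one value per timepoint.
#' @export
mean_trajectory <- function(trajs, group = seq_len(nrow(trajs))) {
  if (length(group) == 0) stop("input error: empty group")
  colMeans(unclass(trajs)[group, , drop = FALSE])
}

#' @export
print.correlation_partition <- function(x, ...) {
  print(x$summary)
  if (x$n_undefined > 0) cat(x$n_undefined, "undefined coefficients excluded\n")
  invisible(x)
}
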