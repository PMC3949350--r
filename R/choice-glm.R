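#' Initial specifications of the four choice-prediction models
#'
#' The model ladder: (1) subject and current interval; (2) plus the two
#' trajectory principal-component scores; (3) plus previous-trial history
#' (signed reward code, previous difficulty, previous interval); (4) the
#' full model with both trajectory and history terms. All start as main
#' effects; interactions are introduced by [stepwise_select()].
#'
#' Term labels name design-matrix columns: `subject` (categorical),
#' `interval` (current stimulus, seconds, linear scale), `t_pc1`/`t_pc2`
#' (trajectory PC scores), `r_prev` (previous reward in {-1, 0, 1}: +1
#' reward after long, -1 reward after short, 0 no reward), `d_prev`
#' (previous difficulty `|I_{t-1} - boundary|`), `i_prev` (previous
#' interval). Interactions use `":"`, e.g. `"subject:interval"`.
#'
#' @return named list of character vectors (`m1`..`m4`).
#' @export
model_specs <- function() {
  list(
    m1 = c("subject", "interval"),
    m2 = c("subject", "interval", "t_pc1", "t_pc2"),
    m3 = c("subject", "interval", "r_prev", "d_prev", "i_prev"),
    m4 = c("subject", "interval", "t_pc1", "t_pc2",
           "r_prev", "d_prev", "i_prev")
  )
}

#' Principal-component trajectory features
#'
#' Mean-centered PCA of the windowed trajectory vectors, pooled across all
#' trials of all subjects; the scores on the first two components summarize
#' each trial's trajectory for the choice GLMs.
#'
#' @param features matrix, trials x dimensions (the common 1 s window, 120
#'   columns at 120 frames/s).
#' @param n_components number of score columns returned (default 2).
#' @return object of class `trajectory_features`: `pc_scores` (trials x
#'   `n_components`, columns `t_pc1`, ...), `explained_variance_fraction`
#'   (all components, non-increasing), `loadings`.
#' @export
trajectory_pca <- function(features, n_components = 2) {
  X <- as.matrix(features)
  if (nrow(X) < 3) stop("input error: need >= 3 trials for PCA")
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  n_components <- min(n_components, ncol(pr$x))
  scores <- pr$x[, seq_len(n_components), drop = FALSE]
  colnames(scores) <- paste0("t_pc", seq_len(n_components))
  structure(
    list(pc_scores = scores,
         explained_variance_fraction = ev / sum(ev),
         loadings = pr$rotation[, seq_len(n_components), drop = FALSE],
         center = pr$center),
    class = "trajectory_features"
  )
}

#' Build the choice-GLM design matrix with history coding and exclusions
#'
#' Constructs the predictor table for the model ladder from an ordered trial
#' table (within each session trials must appear in temporal order and
#' sessions must be contiguous). History variables refer to the immediately
#' preceding trial of the same session: `r_prev` is +1 for a rewarded long
#' choice, -1 for a rewarded short choice, 0 otherwise; `d_prev` is
#' `|i_prev - boundary|`. Excluded rows: the first trial of every session
#' (no history), premature trials, and the immediate successors of premature
#' trials.
#'
#' @param trials trial data.frame (`subject`, `session`, `stimulus`,
#'   `choice`, `rewarded`, `premature`).
#' @param features optional `trajectory_features` (or a bare score matrix)
#'   aligned with `trials`; adds `t_pc1`, `t_pc2`, ...
#' @param boundary categorical boundary, seconds.
#' @return data.frame with the response `choice_long` and predictor columns;
#'   attribute `kept_rows` gives the retained row indices of `trials`.
#' @export
build_design_matrix <- function(trials, features = NULL, boundary = 1.5) {
  n <- nrow(trials)
  scores <- NULL
  if (!is.null(features)) {
    scores <- if (inherits(features, "trajectory_features"))
      features$pc_scores else as.matrix(features)
    if (nrow(scores) != n) stop("input error: features misaligned with trials")
  }
  sess <- paste(trials$subject, trials$session, sep = "\r")
  first <- !duplicated(sess)
  lag1 <- function(x) {
    out <- c(NA, x[-length(x)])
    out[first] <- NA
    out
  }
  prev_choice_long <- lag1(trials$choice == "long")
  prev_rewarded <- lag1(trials$rewarded)
  r_prev <- ifelse(is.na(prev_rewarded) | !prev_rewarded, 0,
                   ifelse(prev_choice_long, 1, -1))
  i_prev <- lag1(trials$stimulus)
  prev_premature <- lag1(trials$premature)

  keep <- !first & !trials$premature & !(prev_premature %in% TRUE)
  design <- data.frame(
    choice_long = trials$choice == "long",
    subject = factor(trials$subject),
    interval = trials$stimulus,
    r_prev = r_prev,
    d_prev = abs(i_prev - boundary),
    i_prev = i_prev,
    stringsAsFactors = FALSE
  )
  if (!is.null(scores)) {
    for (j in seq_len(ncol(scores))) design[[colnames(scores)[j]]] <- scores[, j]
  }
  design <- design[keep, , drop = FALSE]
  design$subject <- droplevels(design$subject)
  rownames(design) <- NULL
  attr(design, "kept_rows") <- which(keep)
  design
}

# Minimal ridge-penalized logistic refit used when ML hits separation.
.ridge_logistic <- function(X, y, lambda = 1e-3, max_iter = 100) {
  p <- ncol(X)
  beta <- rep(0, p)
  pen <- rep(lambda, p)
  pen[1] <- 0  # no penalty on the intercept
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    Wv <- pmax(mu * (1 - mu), 1e-10)
    g <- drop(crossprod(X, y - mu)) - pen * beta
    H <- crossprod(X, X * Wv) + diag(pen, p)
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  beta
}

#' Fit one logistic choice model
#'
#' Maximum-likelihood logistic regression of `choice_long` on the given
#' terms. Reported criteria use the binary-response identities
#' `deviance = -2 log L`, `aic = deviance + 2 k`,
#' `bic = deviance + k log n` with `k` the number of estimated
#' coefficients (intercept included). Prediction success is the percentage
#' of trials whose fitted `P(long) >= 0.5` matches the observed choice
#' (ties predicted long). Perfect separation is flagged and the
#' coefficients replaced by a lightly ridge-penalized refit.
#'
#' @param design data.frame from [build_design_matrix()].
#' @param terms character vector of term labels (see [model_specs()]);
#'   empty for the intercept-only model.
#' @param model_id optional identifier carried into comparison tables.
#' @return object of class `choice_glm`: `coefficients` (named vector),
#'   `coef_table`, `deviance`, `aic`, `bic`, `prediction_success`,
#'   `n_params`, `n_trials`, `terms`, `separation`, `fit` (the underlying
#'   `glm`).
#' @export
fit_choice_glm <- function(design, terms, model_id = NULL) {
  if (!all(design$choice_long %in% c(TRUE, FALSE))) {
    stop("input error: response must be logical")
  }
  if (length(unique(design$choice_long)) < 2) {
    stop("input error: both response classes must be present")
  }
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  f <- as.formula(paste("choice_long ~", rhs))
  fit <- suppressWarnings(glm(f, data = design, family = binomial()))
  b <- coef(fit)
  k <- sum(!is.na(b))
  n <- nrow(design)
  separation <- any(fitted(fit) < 1e-8 | fitted(fit) > 1 - 1e-8) &&
    max(abs(b), na.rm = TRUE) > 25
  dev <- deviance(fit)
  coefs <- b
  if (separation) {
    X <- stats::model.matrix(fit)
    cols <- !is.na(b)
    beta <- .ridge_logistic(X[, cols, drop = FALSE],
                            as.numeric(design$choice_long))
    coefs[cols] <- beta
    eta <- drop(X[, cols, drop = FALSE] %*% beta)
    dev <- -2 * sum(ifelse(design$choice_long, plogis(eta, log.p = TRUE),
                           plogis(-eta, log.p = TRUE)))
  }
  st <- summary(fit)$coefficients
  pred_long <- fitted(fit) >= 0.5
  structure(
    list(model_id = model_id, terms = terms,
         coefficients = coefs, coef_table = st,
         deviance = dev, aic = dev + 2 * k, bic = dev + k * log(n),
         prediction_success = 100 * mean(pred_long == design$choice_long),
         n_params = k, n_trials = n,
         separation = separation, converged = fit$converged,
         fit = fit),
    class = "choice_glm"
  )
}

#' @export
print.choice_glm <- function(x, ...) {
  cat(sprintf(
    "Choice GLM%s: %s\n  deviance %.1f, AIC %.1f, BIC %.1f, prediction success %.1f%% (n = %d, k = %d)%s\n",
    if (is.null(x$model_id)) "" else paste0(" ", x$model_id),
    if (length(x$terms)) paste(x$terms, collapse = " + ") else "(intercept only)",
    x$deviance, x$aic, x$bic, x$prediction_success, x$n_trials, x$n_params,
    if (x$separation) " [separation: ridge refit]" else ""))
  invisible(x)
}

# expand a:b interactions into their constituent mains plus the interaction
.expand_terms <- function(terms) {
  unique(unlist(lapply(terms, function(t) {
    if (grepl(":", t, fixed = TRUE)) c(strsplit(t, ":", fixed = TRUE)[[1]], t)
    else t
  })))
}

#' Stepwise BIC refinement of a model specification
#'
#' Greedy best-first search over single moves: removing one current term
#' (main effects only if not involved in a retained interaction) or adding
#' one pairwise interaction between current main effects. At each step every
#' candidate is fit, the move with the lowest BIC is taken, and the search
#' stops when no move improves on the current BIC. Deterministic given the
#' data (ties resolved by candidate order: removals in term order, then
#' additions in main-effect order).
#'
#' @param terms initial character vector of term labels.
#' @param design data.frame from [build_design_matrix()].
#' @param verbose print each accepted move.
#' @return list: `terms` (final specification), `fit` (its `choice_glm`),
#'   `trace` (data.frame of accepted moves and BICs).
#' @export
stepwise_select <- function(terms, design, verbose = FALSE) {
  current <- terms
  best_fit <- fit_choice_glm(design, current)
  best <- best_fit$bic
  trace <- data.frame(move = "initial", bic = best,
                      stringsAsFactors = FALSE)
  repeat {
    mains <- current[!grepl(":", current, fixed = TRUE)]
    ints <- current[grepl(":", current, fixed = TRUE)]
    in_int <- unique(unlist(strsplit(ints, ":", fixed = TRUE)))
    cands <- list()
    labels <- character(0)
    for (tm in current) {
      if (!grepl(":", tm, fixed = TRUE) && tm %in% in_int) next
      cands[[length(cands) + 1]] <- setdiff(current, tm)
      labels <- c(labels, paste("remove", tm))
    }
    if (length(mains) >= 2) {
      for (i in seq_len(length(mains) - 1)) {
        for (j in (i + 1):length(mains)) {
          key <- paste(mains[i], mains[j], sep = ":")
          rev_key <- paste(mains[j], mains[i], sep = ":")
          if (key %in% ints || rev_key %in% ints) next
          cands[[length(cands) + 1]] <- c(current, key)
          labels <- c(labels, paste("add", key))
        }
      }
    }
    if (length(cands) == 0) break
    fits <- lapply(cands, function(tt) {
      tryCatch(fit_choice_glm(design, tt), error = function(e) NULL)
    })
    bics <- vapply(fits, function(f) if (is.null(f)) Inf else f$bic, numeric(1))
    i_best <- which.min(bics)
    if (bics[i_best] >= best - 1e-8) break
    current <- cands[[i_best]]
    best <- bics[i_best]
    best_fit <- fits[[i_best]]
    trace <- rbind(trace, data.frame(move = labels[i_best], bic = best,
                                     stringsAsFactors = FALSE))
    if (verbose) message(labels[i_best], " -> BIC ", round(best, 2))
  }
  list(terms = current, fit = best_fit, trace = trace)
}

#' Compare the fitted choice models
#'
#' Produces the comparison table (prediction success, deviance, BIC, AIC
#' per model) and likelihood-ratio tests for declared nested pairs:
#' chi-squared equals the deviance difference, degrees of freedom the
#' parameter-count difference, p-value from the chi-squared tail. A pair is
#' accepted as nested only when the smaller model's expanded term set is a
#' subset of the larger's; otherwise the test is refused.
#'
#' @param results named list of `choice_glm` fits.
#' @param pairs list of length-2 character vectors `c(smaller, larger)`;
#'   defaults to the ladder's nesting map (m1 in m2, m1 in m3, m2 in m4,
#'   m3 in m4) when those names are present.
#' @return object of class `model_comparison`: `table` (one row per model)
#'   and `lr_tests` (one row per pair: `chisq`, `df`, `p`).
#' @export
compare_models <- function(results, pairs = NULL) {
  stopifnot(is.list(results), length(names(results)) == length(results))
  if (is.null(pairs)) {
    ladder <- list(c("m1", "m2"), c("m1", "m3"), c("m2", "m4"), c("m3", "m4"))
    pairs <- Filter(function(p) all(p %in% names(results)), ladder)
  }
  tab <- data.frame(
    model = names(results),
    prediction_success = vapply(results, `[[`, numeric(1), "prediction_success"),
    deviance = vapply(results, `[[`, numeric(1), "deviance"),
    bic = vapply(results, `[[`, numeric(1), "bic"),
    aic = vapply(results, `[[`, numeric(1), "aic"),
    n_params = vapply(results, `[[`, numeric(1), "n_params"),
    row.names = NULL
  )
  lr <- do.call(rbind, lapply(pairs, function(p) {
    small <- results[[p[1]]]; large <- results[[p[2]]]
    if (!all(.expand_terms(small$terms) %in% .expand_terms(large$terms))) {
      stop("LR test refused: model '", p[1], "' is not nested in '", p[2],
           "' (term sets are not ordered by inclusion)")
    }
    chisq <- small$deviance - large$deviance
    df <- large$n_params - small$n_params
    pval <- if (df == 0) {
      if (abs(chisq) < 1e-8) 1 else NA_real_
    } else {
      pchisq(chisq, df, lower.tail = FALSE)
    }
    data.frame(smaller = p[1], larger = p[2], chisq = chisq, df = df,
               p = pval, stringsAsFactors = FALSE)
  }))
  structure(list(table = tab, lr_tests = lr), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  print(x$table, digits = 4)
  cat("\nLikelihood-ratio tests:\n")
  print(x$lr_tests, digits = 4)
  invisible(x)
}
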