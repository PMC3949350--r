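test_that("choice variance follows the binomial formula", {
  expect_equal(choice_variance(34, 56)$variance, 13.3571, tolerance = 1e-4)
  expect_equal(choice_variance(0, 10)$variance, 0)
  expect_equal(choice_variance(10, 10)$variance, 0)
  expect_equal(choice_variance(2, 4)$variance, 1)
  expect_error(choice_variance(3, 0), "n_total")
  expect_error(choice_variance(5, 4), "n_long")
  # bounds: 0 <= variance <= n/4, zero iff unanimous
  for (k in 0:8) {
    v <- choice_variance(k, 8)$variance
    expect_gte(v, 0); expect_lte(v, 2)
    expect_equal(v == 0, k %in% c(0, 8))
  }
})

test_that("per-trial weights equal their (session, stimulus) cell variance", {
  trials <- data.frame(
    session = c("s1", "s1", "s1", "s1", "s2", "s2"),
    stimulus = c(1.38, 1.38, 1.38, 2.4, 1.38, 1.38),
    choice = c("long", "short", "long", "long", "long", "long"))
  w <- choice_variance_weights(trials)
  expect_equal(w[1:3], rep(3 * (2 / 3) * (1 / 3), 3))
  expect_equal(w[4], 0)    # unanimous single-trial cell
  expect_equal(w[5:6], c(0, 0))
})

test_that("the highest-variance stimulus is selected pooled across sessions", {
  trials <- data.frame(
    session = rep(c("s1", "s2"), each = 8),
    stimulus = rep(c(1.38, 2.4), 8),
    choice = c(rep(c("long", "long"), 4), rep(c("short", "long"), 4)))
  # 1.38: 8 trials, 4 long -> variance 2; 2.4: 8 trials all long -> 0
  expect_equal(select_max_variance_stimulus(trials), 1.38)
})

test_that("instantaneous CP matches brute-force pair counting and rectifies", {
  expect_equal(as.numeric(instantaneous_cp(c(2, 3), c(0, 1))), 1)
  a <- instantaneous_cp(c(0, 2), c(0, 1))
  expect_equal(as.numeric(a), 0.625)
  expect_equal(attr(a, "raw"), 0.625)
  same <- instantaneous_cp(c(1, 2, 3), c(1, 2, 3))
  expect_equal(as.numeric(same), 0.5)
  expect_error(instantaneous_cp(numeric(0), 1), "empty")

  set.seed(51)
  for (i in 1:200) {
    nl <- sample(1:20, 1); ns <- sample(1:20, 1)
    l <- sample(0:8, nl, replace = TRUE) + sample(c(0, 0.5), nl, replace = TRUE)
    s <- sample(0:8, ns, replace = TRUE) + sample(c(0, 0.5), ns, replace = TRUE)
    raw <- attr(instantaneous_cp(l, s), "raw")
    expect_equal(raw, brute_force_auroc(l, s), tolerance = 1e-12)
  }
})

test_that("rectified CP is label-swap invariant and at least 0.5", {
  set.seed(52)
  for (i in 1:50) {
    l <- rnorm(sample(2:15, 1)); s <- rnorm(sample(2:15, 1))
    cp_a <- as.numeric(instantaneous_cp(l, s))
    cp_b <- as.numeric(instantaneous_cp(s, l))
    expect_equal(cp_a, cp_b, tolerance = 1e-12)
    expect_gte(cp_a, 0.5)
    expect_lte(cp_a, 1)
  }
})

test_that("instantaneous CP agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(53)
  l <- rnorm(40, 0.8); s <- rnorm(35)
  raw <- attr(instantaneous_cp(l, s), "raw")
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = rep(c(1, 0), c(40, 35)), predictor = c(l, s),
    direction = "<", quiet = TRUE)))
  expect_equal(raw, ref, tolerance = 1e-10)
})

test_that("CP timecourse is deterministic under a seed and flags tiny classes", {
  s <- quick_session(n = 120, seed = 54)
  sel <- s$trials$stimulus == 1.38
  a <- cp_timecourse(s$trajectories, s$trials$choice, n_shuffles = 30, seed = 9)
  b <- cp_timecourse(s$trajectories, s$trials$choice, n_shuffles = 30, seed = 9)
  expect_identical(a$null_upper, b$null_upper)
  expect_true(all(a$cp >= 0.5))
  expect_identical(a$significant, a$cp > a$null_upper)

  tiny <- cp_timecourse(s$trajectories[1:3, ], c("long", "long", "short"),
                        n_shuffles = 10)
  expect_false(attr(tiny, "usable"))
  expect_true(all(is.na(tiny$cp)))
})

test_that("posterior choice probability follows Bayes' rule", {
  # 1-D, single-component model built by hand via well-separated classes
  set.seed(55)
  X <- rbind(matrix(rnorm(200, 6), ncol = 2), matrix(rnorm(200, 0), ncol = 2))
  ch <- rep(c("long", "short"), each = 100)
  m <- fit_cp_model_quiet(X, ch, n_components = 1, seed = 1)
  # each class's own mean is classified with near certainty
  expect_gt(posterior_choice_probability(m, matrix(6, 1, 2)), 0.99)
  expect_lt(posterior_choice_probability(m, matrix(0, 1, 2)), 0.01)
  # posteriors over both classes sum to 1 (plogis construction is exact)
  probe <- matrix(rnorm(2000, 3, 4), ncol = 2)
  p <- posterior_choice_probability(m, probe)
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(is.finite(p)))
  # extreme trajectories never yield NaN (log-domain evaluation)
  far <- matrix(c(1e4, -1e4), 1, 2)
  expect_true(is.finite(posterior_choice_probability(m, far)))
})

test_that("likelihood ratio 3:1 with equal priors gives posterior 0.75", {
  # direct check of the Bayes inversion arithmetic on a hand-built model
  model <- structure(list(
    likelihood_long = list(weights = 1, means = list(0), chols = list(matrix(1))),
    likelihood_short = list(weights = 1, means = list(0), chols = list(matrix(1))),
    prior_long = 0.5, prior_short = 0.5, n_components = 1,
    center = 0, rotation = NULL, d_input = 1), class = "trajectory_cp_model")
  # same densities -> 0.5
  expect_equal(as.numeric(posterior_choice_probability(model, 0.3)), 0.5)
  # shift the short class so the density ratio at the origin is exactly 3:
  # long density there is 1/sqrt(2*pi), short is exp(-log 3)/sqrt(2*pi)
  model$likelihood_short$means <- list(sqrt(2 * log(3)))
  p_at_0 <- posterior_choice_probability(model, matrix(0, 1, 1))
  expect_equal(as.numeric(p_at_0), 0.75, tolerance = 1e-9)
})

test_that("uniform weights with one component reduce to the ordinary MLE Gaussian", {
  set.seed(56)
  X <- matrix(rnorm(300), ncol = 3)
  ch <- rep(c("long", "short"), each = 50)
  m <- fit_cp_model_quiet(X, ch, weights = rep(2, 100), n_components = 1, seed = 1)
  Xl <- X[1:50, ]
  expect_equal(m$likelihood_long$means[[1]], colMeans(Xl), tolerance = 1e-8,
               ignore_attr = TRUE)
  S <- crossprod(sweep(Xl, 2, colMeans(Xl))) / 50
  fitted_S <- crossprod(m$likelihood_long$chols[[1]])
  expect_equal(fitted_S, S + diag(1e-6, 3), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(m$prior_long, 0.5)
})

test_that("zero-weight trials have exactly no influence on the fit", {
  set.seed(57)
  X <- matrix(rnorm(400), ncol = 2)
  ch <- rep(c("long", "short"), 100)
  w <- rep(1, 200); w[c(3, 50, 120)] <- 0
  m_all <- fit_cp_model_quiet(X, ch, weights = w, n_components = 2, seed = 4)
  keep <- w > 0
  m_sub <- fit_cp_model_quiet(X[keep, ], ch[keep], weights = w[keep],
                              n_components = 2, seed = 4)
  expect_equal(m_all$likelihood_long$means, m_sub$likelihood_long$means)
  expect_equal(m_all$likelihood_short$loglik, m_sub$likelihood_short$loglik)
  expect_equal(m_all$prior_long, m_sub$prior_long)
})

test_that("well-separated classes are classified almost perfectly out of sample", {
  set.seed(58)
  n <- 300
  gen <- function(mu, n) cbind(rnorm(n, mu), rnorm(n, -mu), rnorm(n))
  Xtrain <- rbind(gen(3, n), gen(-3, n))
  ch <- rep(c("long", "short"), each = n)
  m <- fit_cp_model_quiet(Xtrain, ch, n_components = 2, seed = 2)
  Xtest <- rbind(gen(3, 200), gen(-3, 200))
  truth <- rep(c("long", "short"), each = 200)
  pred <- ifelse(posterior_choice_probability(m, Xtest) >= 0.5, "long", "short")
  expect_gt(mean(pred == truth), 0.95)
})

test_that("mixture fit agrees with an independent GMM classifier", {
  skip_if_not_installed("mclust")
  set.seed(59)
  X1 <- matrix(rnorm(300, 2), ncol = 2)
  X2 <- matrix(rnorm(300, -2), ncol = 2)
  ch <- rep(c("long", "short"), each = 150)
  m <- fit_cp_model_quiet(rbind(X1, X2), ch, n_components = 1, seed = 3)
  d_long <- mclust::densityMclust(X1, G = 1, modelNames = "VVV",
                                  verbose = FALSE, plot = FALSE)
  d_short <- mclust::densityMclust(X2, G = 1, modelNames = "VVV",
                                   verbose = FALSE, plot = FALSE)
  Xnew <- matrix(rnorm(400, 0, 2.5), ncol = 2)
  ours <- posterior_choice_probability(m, Xnew)
  ll <- predict(d_long, Xnew, what = "dens", logarithm = TRUE)
  ls <- predict(d_short, Xnew, what = "dens", logarithm = TRUE)
  theirs <- plogis(ll - ls)  # equal priors by construction
  expect_equal(as.numeric(ours), as.numeric(theirs), tolerance = 0.02)
})

test_that("CP binning yields equal counts with stable tie handling", {
  b <- bin_trials_by_cp(seq(0.05, 0.95, length.out = 12), 6)
  expect_equal(b$counts, rep(2L, 6))
  expect_equal(b$assignments, rep(1:6, each = 2))

  ties <- bin_trials_by_cp(rep(0.5, 13), 6)
  expect_true(all(abs(ties$counts - 13 / 6) < 1))
  expect_equal(sum(ties$counts), 13)
  expect_equal(ties$assignments[1], 1L)  # stable order: earliest trials first

  cps <- runif(100)
  b2 <- bin_trials_by_cp(cps, 6)
  expect_true(all(diff(range(b2$counts)) <= 1))
  ord <- order(cps)
  expect_true(all(diff(b2$assignments[ord]) >= 0))

  expect_error(bin_trials_by_cp(c(0.4, 0.6), 6), "fewer trials")
  expect_error(bin_trials_by_cp(runif(10), 1), "n_bins")
})

test_that("per-bin psychometrics flag degenerate bins and fit the rest", {
  s <- quick_session(n = 600, seed = 60)
  feats <- traj_window(s$trajectories, c(-0.5, 0.5), target_fps = 120)
  m <- fit_cp_model_quiet(feats, s$trials$choice,
                          weights = choice_variance_weights(s$trials), seed = 5)
  cps <- posterior_choice_probability(m, feats)
  binning <- bin_trials_by_cp(cps, 6)
  fits <- per_bin_psychometrics(s$trials, binning)
  expect_length(fits, 6)
  expect_true(all(vapply(fits, inherits, logical(1), "psychometric_fit")))
  # a bin whose trials share one stimulus is flagged rather than fit
  fake <- s$trials[1:12, ]
  fake$stimulus <- 1.38
  flagged <- per_bin_psychometrics(fake, bin_trials_by_cp(runif(12), 6))
  expect_true(all(!vapply(flagged, `[[`, logical(1), "converged")))
})
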