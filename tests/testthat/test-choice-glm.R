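make_design <- function(seed = 71, n_per = 1200, n_subjects = 3) {
  exp <- simulate_experiment(n_subjects = n_subjects, sessions_per_subject = 1,
                             trials_per_session = n_per, seed = seed)
  feats <- trajectory_pca(traj_window(exp$trajectories, c(-0.5, 0.5),
                                      target_fps = 120))
  list(exp = exp,
       design = build_design_matrix(exp$trials, feats))
}

test_that("trajectory PCA recovers planted variance structure", {
  # all rows proportional to one profile: PC1 explains everything
  prof <- sin(seq(0, 2 * pi, length.out = 50))
  X <- outer(rnorm(30), prof)
  f1 <- trajectory_pca(X)
  expect_equal(f1$explained_variance_fraction[1], 1, tolerance = 1e-10)

  # two orthogonal modes with variance ratio 4:1 and no noise -> (0.8, 0.2)
  t <- seq(0, 1, length.out = 60)
  m1 <- sin(2 * pi * t); m1 <- m1 / sqrt(sum(m1^2))
  m2 <- cos(2 * pi * t); m2 <- m2 / sqrt(sum(m2^2))
  set.seed(72)
  n <- 4000
  X2 <- outer(rnorm(n, sd = 2), m1) + outer(rnorm(n, sd = 1), m2)
  f2 <- trajectory_pca(X2)
  expect_equal(f2$explained_variance_fraction[1], 0.8, tolerance = 0.02)
  expect_equal(f2$explained_variance_fraction[2], 0.2, tolerance = 0.02)
  expect_true(all(diff(f2$explained_variance_fraction) <= 1e-12))

  # scores are uncorrelated and loadings orthonormal
  expect_equal(cor(f2$pc_scores[, 1], f2$pc_scores[, 2]), 0, tolerance = 1e-10)
  expect_equal(crossprod(f2$loadings), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(trajectory_pca(X2[1:2, ]), ">= 3 trials")
})

test_that("design matrix codes history and applies the exclusion rules", {
  trials <- data.frame(
    subject = "a", session = "s1", trial = 1:10,
    stimulus = c(1.38, 2.4, 0.6, 1.62, 1.62, 1.05, 1.95, 1.26, 1.74, 0.6),
    choice = c("long", "long", "short", "short", "long", "short",
               "long", "short", "long", "short"),
    rewarded = c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    premature = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
                  FALSE, FALSE))
  trials$rewarded[4] <- FALSE  # premature trials are never rewarded
  d <- build_design_matrix(trials)
  # kept rows: drop 1 (first), 4 (premature), 5 (successor of premature)
  expect_equal(attr(d, "kept_rows"), c(2, 3, 6, 7, 8, 9, 10))
  # reward coding: +1 after rewarded long, -1 after rewarded short, else 0
  expect_equal(d$r_prev[attr(d, "kept_rows") == 2], 0)   # previous unrewarded
  expect_equal(d$r_prev[attr(d, "kept_rows") == 3], 1)   # after rewarded long
  expect_equal(d$r_prev[attr(d, "kept_rows") == 7], -1)  # after rewarded short
  # difficulty of the previous interval
  expect_equal(d$d_prev, abs(d$i_prev - 1.5))
  expect_equal(d$d_prev[attr(d, "kept_rows") == 9], abs(1.26 - 1.5))
  # no retained row is premature or follows a premature trial
  expect_false(any(trials$premature[attr(d, "kept_rows")]))
  expect_false(any(trials$premature[attr(d, "kept_rows") - 1]))
})

test_that("exclusion rules hold on generated data with premature responses", {
  md <- make_design(seed = 73, n_per = 500, n_subjects = 2)
  kept <- attr(md$design, "kept_rows")
  tr <- md$exp$trials
  expect_false(any(tr$premature[kept]))
  prev_idx <- kept - 1
  same_sess <- paste(tr$subject[kept], tr$session[kept]) ==
    paste(tr$subject[prev_idx], tr$session[prev_idx])
  expect_true(all(same_sess))
  expect_false(any(tr$premature[prev_idx]))
})

test_that("intercept-only fit matches the closed form on balanced classes", {
  d <- data.frame(choice_long = rep(c(TRUE, FALSE), 100))
  fit <- fit_choice_glm(d, character(0))
  expect_equal(fit$deviance, 2 * 200 * log(2), tolerance = 1e-8)
  expect_equal(fit$prediction_success, 50)
  expect_equal(fit$n_params, 1)
  expect_equal(fit$aic, fit$deviance + 2)
  expect_equal(fit$bic, fit$deviance + log(200))
})

test_that("ML estimate matches a brute-force likelihood grid", {
  set.seed(74)
  x <- rnorm(20)
  b_true <- c(0.3, 1.1)
  y <- runif(20) < plogis(b_true[1] + b_true[2] * x)
  d <- data.frame(choice_long = y, interval = x)
  fit <- fit_choice_glm(d, "interval")
  nll <- function(b) -sum(ifelse(y, plogis(b[1] + b[2] * x, log.p = TRUE),
                                 plogis(-(b[1] + b[2] * x), log.p = TRUE)))
  # refine a coarse grid around the optimum to 1e-3 resolution
  grid <- as.matrix(expand.grid(seq(-4, 4, 0.05), seq(-4, 4, 0.05)))
  vals <- apply(grid, 1, nll)
  coarse <- grid[which.min(vals), ]
  fine <- as.matrix(expand.grid(seq(coarse[1] - 0.1, coarse[1] + 0.1, 0.001),
                                seq(coarse[2] - 0.1, coarse[2] + 0.1, 0.001)))
  best <- fine[which.min(apply(fine, 1, nll)), ]
  expect_equal(unname(fit$coefficients), unname(best), tolerance = 2e-3)
})

test_that("the ladder is monotone in deviance and the criteria identities hold", {
  md <- make_design(seed = 75, n_per = 700)
  specs <- model_specs()
  fits <- lapply(names(specs), function(m) fit_choice_glm(md$design, specs[[m]], m))
  names(fits) <- names(specs)
  dev <- vapply(fits, `[[`, numeric(1), "deviance")
  expect_lte(dev["m4"], dev["m2"] + 1e-8)
  expect_lte(dev["m4"], dev["m3"] + 1e-8)
  expect_lte(dev["m2"], dev["m1"] + 1e-8)
  expect_lte(dev["m3"], dev["m1"] + 1e-8)
  for (f in fits) {
    expect_equal(f$aic, f$deviance + 2 * f$n_params)
    expect_equal(f$bic, f$deviance + f$n_params * log(f$n_trials))
  }
  # adding a pure-noise column cannot raise the deviance
  set.seed(76)
  md$design$noise <- rnorm(nrow(md$design))
  f_noise <- fit_choice_glm(md$design, c(specs$m1, "noise"))
  expect_lte(f_noise$deviance, fits$m1$deviance + 1e-8)
})

test_that("a simulated previous-reward effect is recovered with the right sign", {
  hits <- 0
  for (r in 1:20) {
    exp <- simulate_experiment(n_subjects = 1, sessions_per_subject = 1,
                               trials_per_session = 2000, seed = 700 + r)
    d <- build_design_matrix(exp$trials)
    f <- fit_choice_glm(d, c("interval", "r_prev"))
    if (unname(f$coefficients["r_prev"]) > 0) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("stepwise search finds a planted subject-by-interval interaction", {
  found <- 0
  for (r in 1:10) {
    set.seed(800 + r)
    n <- 2500
    subject <- factor(sample(c("a", "b"), n, replace = TRUE))
    interval <- sample(task_config()$stimulus_set, n, replace = TRUE)
    # slope differs strongly by subject: a true subject:interval interaction
    slope <- ifelse(subject == "a", 9, 2.5)
    y <- runif(n) < plogis(slope * (log(interval) - log(1.5)))
    d <- data.frame(choice_long = y, subject = subject, interval = interval)
    res <- stepwise_select(c("subject", "interval"), d)
    if ("subject:interval" %in% res$terms) found <- found + 1
  }
  expect_gte(found, 9)
})

test_that("stepwise removes useless history terms and respects fixed points", {
  exp <- simulate_experiment(
    n_subjects = 2, sessions_per_subject = 1, trials_per_session = 2000,
    params = generative_params(history_reward_weight = 0,
                               traj_coupling_gain = 0),
    seed = 77)
  d <- build_design_matrix(exp$trials)
  res <- stepwise_select(model_specs()$m3, d)
  expect_false(all(c("r_prev", "d_prev", "i_prev") %in% res$terms))

  # a spec already BIC-minimal among one-move neighbors is returned unchanged
  fixed <- stepwise_select(res$terms, d)
  expect_setequal(fixed$terms, res$terms)
  expect_equal(nrow(fixed$trace), 1)
})

test_that("model comparison runs LR tests only on nested pairs", {
  md <- make_design(seed = 78, n_per = 600)
  specs <- model_specs()
  fits <- lapply(names(specs), function(m) fit_choice_glm(md$design, specs[[m]], m))
  names(fits) <- names(specs)
  cmp <- compare_models(fits)
  expect_equal(nrow(cmp$table), 4)
  expect_equal(nrow(cmp$lr_tests), 4)
  expect_true(all(cmp$lr_tests$chisq >= -1e-8))
  expect_true(all(cmp$lr_tests$df > 0))

  # identical models: chi-squared 0, p = 1
  twin <- compare_models(list(a = fits$m1, b = fits$m1),
                         pairs = list(c("a", "b")))
  expect_equal(twin$lr_tests$chisq, 0)
  expect_equal(twin$lr_tests$p, 1)

  # hand-checkable tail probability: deviances 100 vs 90 with 2 df
  f_small <- fits$m1; f_large <- fits$m2
  f_small$deviance <- 100; f_small$n_params <- 2
  f_large$deviance <- 90; f_large$n_params <- 4
  hand <- compare_models(list(s = f_small, l = f_large),
                         pairs = list(c("s", "l")))
  expect_equal(hand$lr_tests$chisq, 10)
  expect_equal(hand$lr_tests$p, pchisq(10, 2, lower.tail = FALSE))
  expect_equal(hand$lr_tests$p, 0.0067, tolerance = 1e-2)

  # non-nested pair is refused
  expect_error(compare_models(list(x = fits$m2, y = fits$m3),
                              pairs = list(c("x", "y"))), "not nested")
})

test_that("separation is flagged and replaced by a penalized refit", {
  d <- data.frame(choice_long = rep(c(FALSE, TRUE), each = 30),
                  interval = rep(c(0.6, 2.4), each = 30))
  fit <- fit_choice_glm(d, "interval")
  expect_true(fit$separation)
  expect_true(all(is.finite(fit$coefficients)))
  expect_lt(max(abs(fit$coefficients)), 100)
})
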