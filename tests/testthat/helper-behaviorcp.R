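# Exhaustive pair-counting auROC: P(long > short) with ties counted half.
# Independent oracle for the rank-based implementation.
brute_force_auroc <- function(pos_long, pos_short) {
  cmp <- outer(pos_long, pos_short, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Small deterministic session for structural tests.
quick_session <- function(n = 200, seed = 101, ...) {
  simulate_session(params = generative_params(seed = seed, ...), n_trials = n)
}

# Fit the trajectory CP model quietly (the dimensionality guard messages on
# small samples by design).
fit_cp_model_quiet <- function(...) {
  withCallingHandlers(fit_trajectory_choice_model(...),
                      message = function(m) invokeRestart("muffleMessage"))
}

run_quiet <- function(...) {
  withCallingHandlers(run_full_analysis(...),
                      message = function(m) invokeRestart("muffleMessage"))
}
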