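test_that("sigmoid saturates, passes through its neutral point exactly", {
  k <- sigmoid_constants()
  expect_equal(sigmoid_dexp(-30, k), k$B, tolerance = 1e-9)
  expect_equal(sigmoid_dexp(30, k), k$B + k$A, tolerance = 1e-9)
  expect_equal(sigmoid_dexp(k$x0, k), k$B + k$A * exp(-1), tolerance = 1e-12)
  expect_identical(sigmoid_dexp(1, k), 1)  # exact neutral pass-through
  x <- seq(-5, 5, by = 0.1)
  expect_true(all(diff(sigmoid_dexp(x, k)) > 0))
  # numerical derivative matches the analytic one used by the optimizer
  h <- 1e-6
  num <- (sigmoid_dexp(x + h, k) - sigmoid_dexp(x - h, k)) / (2 * h)
  expect_equal(pupilstate:::sigmoid_dexp_deriv(x, k), num, tolerance = 1e-6)
  idc <- sigmoid_constants(identity = TRUE)
  expect_identical(sigmoid_dexp(x, idc), x)
})

test_that("neutral coefficients reduce the full model to s0 + r0 bitwise", {
  set.seed(5)
  for (i in 1:20) {
    n <- 50
    s0 <- runif(1, 0, 10)
    r0 <- runif(n, 0, 30)
    p <- runif(n)
    b <- rbinom(n, 1, 0.5)
    pred <- evaluate_state_model(pupilstate:::neutral_params(),
                                 s0, r0, p, b)
    expect_identical(pred, s0 + r0)
  }
  # identity-nonlinearity arithmetic case
  pm <- c(d0 = 1, dp = 2, db = 0, g0 = 1, gp = 1, gb = 0)
  out <- evaluate_state_model(pm, 2, 4, 0.5, 0,
                              sigmoid_constants(identity = TRUE))
  expect_equal(out, 10)
  expect_error(evaluate_state_model(pm, 2, c(1, 2), 0.5, 0), "misaligned")
})

test_that("trial shuffling preserves per-trial structure and is seeded", {
  trial <- rep(c("a", "b", "c", "d"), each = 5)
  x <- rnorm(20)
  expect_equal(shuffle_state_signal(rep(2, 20), trial, 1), rep(2, 20))
  sh <- shuffle_state_signal(x, trial, seed = 7)
  # multiset of per-trial mean values preserved
  expect_equal(sort(unname(tapply(sh, trial, mean))),
               sort(unname(tapply(x, trial, mean))))
  # trial blocks stay contiguous: each output block is some input block
  in_blocks <- split(x, trial)
  out_blocks <- split(sh, trial)
  expect_true(all(vapply(out_blocks, function(bl)
    any(vapply(in_blocks, identical, logical(1), y = bl)), logical(1))))
  expect_identical(sh, shuffle_state_signal(x, trial, seed = 7))
  expect_false(identical(sh, shuffle_state_signal(x, trial, seed = 8)))
  # unequal trial lengths only swap within equal-length groups
  x2 <- rnorm(16)
  trial2 <- c(rep("a", 3), rep("b", 5), rep("c", 3), rep("d", 5))
  sh2 <- shuffle_state_signal(x2, trial2, seed = 1)
  expect_equal(as.vector(tapply(sh2, trial2, length)), c(3, 5, 3, 5))
  expect_equal(sort(sh2), sort(x2))
})

test_that("r-squared is squared Pearson correlation with a constant convention", {
  x <- rnorm(50)
  expect_equal(compute_r2(x, x), 1)
  expect_equal(compute_r2(rep(1, 50), x), 0)
  obs <- c(1, 2, 3, 4); pred <- c(1, 1, 3, 3)
  # frozen from the covariance formula: r = cov/(sd sd) = 2/sqrt(5)
  expect_equal(compute_r2(pred, obs), 0.8, tolerance = 1e-9)
})

test_that("unique variance is the full-minus-partial difference", {
  uv <- unique_variance(0.30, r2_task_only = NA, r2_pupil_only = 0.21)
  expect_equal(uv$task_unique, 0.09)
  uv2 <- unique_variance(0.53, r2_task_only = 0.39, r2_pupil_only = NA)
  expect_equal(uv2$pupil_unique, 0.14)
  uv3 <- unique_variance(0.4, 0.4, 0.4)
  expect_equal(uv3$task_unique, 0)
  expect_equal(uv3$pupil_unique, 0)
})

test_that("unit classification follows the significance gates", {
  expect_equal(classify_unit(0.2, 0.01, 0.01), "none")
  expect_equal(classify_unit(0.01, 0.01, 0.5), "task_only")
  expect_equal(classify_unit(0.01, 0.5, 0.01), "pupil_only")
  expect_equal(classify_unit(0.01, 0.01, 0.04), "both")
  expect_equal(classify_unit(0.01, 0.5, 0.5), "ambiguous_state")
})

test_that("jackknife test returns p = 1 for identical predictions", {
  set.seed(2)
  obs <- rnorm(100)
  pred <- obs + rnorm(100, sd = 0.5)
  folds <- rep(1:10, each = 10)
  jk <- jackknife_significance(pred, pred, obs, folds)
  expect_equal(jk$p, 1)
  expect_equal(jk$estimate, 0)
  expect_warning(
    jk2 <- jackknife_significance(pred[1:20], pred[1:20] + 1, obs[1:20],
                                  rep(1:2, each = 10)),
    "folds")
  expect_true(is.na(jk2$p))
})

test_that("noiseless identity-mode fits recover the generating coefficients", {
  idc <- sigmoid_constants(identity = TRUE)
  cfg <- generative_config(
    trials_per_block = 8, n_stim = 8, noise = "none", constants = idc,
    units = list(n = 1, effect_types = "x",
                 coef = list(x = c(dp = 0.4, db = 0.3, gp = 0.2, gb = 0.5))))
  g <- generate_session(cfg, seed = 11)
  rs <- extract_reference_responses(g$session)
  md <- build_model_data(g$session, rs)
  fit <- fit_state_model(md, "u01", "full", n_folds = 5, constants = idc,
                         refset_fixed = truth_refset(g$truth, "u01"), seed = 1)
  for (f in seq_len(ncol(fit$params))) {
    expect_equal(unname(fit$params[, f]), unname(g$truth$params["u01", ]),
                 tolerance = 1e-3)
  }
  # evaluating the generating parameters reproduces the noiseless rate
  expect_identical(
    evaluate_state_model(g$truth$params["u01", ], g$truth$s0,
                         g$truth$r0_bin["u01", ], g$truth$p, g$truth$b, idc),
    g$truth$noiseless["u01", ])
})

test_that("cross-validation covers every bin once and fitting is sane", {
  cfg <- quick_cfg(trials_per_block = 10, n_units = 1)
  cfg$units$effect_types <- "task"
  g <- generate_session(cfg, seed = 12)
  rs <- extract_reference_responses(g$session)
  md <- build_model_data(g$session, rs)
  fits <- lapply(c("full", "task_only", "null"), function(ms)
    fit_state_model(md, "u01", ms, n_folds = 10, seed = 2))
  names(fits) <- c("full", "task_only", "null")
  for (f in fits) {
    expect_false(anyNA(f$prediction))  # every bin predicted exactly once
    expect_true(all(f$convergence == 0))
    # optimizer sanity: fitted training MSE never exceeds the neutral
    # (state-independent) starting point
    for (k in seq_len(f$n_folds)) {
      tr <- f$fold_of_bin != k
      neutral_mse <- mean((md$y["u01", tr] -
                             pupilstate:::predict_neutral(md, "u01", tr))^2)
      expect_lte(f$train_mse[k], neutral_mse + 1e-9)
    }
  }
  # strong real regressors beat their shuffled counterparts in training
  expect_true(mean(fits$full$train_mse) <= mean(fits$task_only$train_mse) + 1e-9)
  expect_true(mean(fits$task_only$train_mse) <= mean(fits$null$train_mse) + 1e-9)
  # the null fit encodes an (at most) slightly state-dependent function:
  # its cross-validated prediction tracks the state-independent s0 + r0
  # prediction far more closely than the full fit does
  neutral_cv <- rep(NA_real_, ncol(md$y))
  for (k in 1:10) {
    te <- fits$null$fold_of_bin == k
    tr <- !te
    tab <- pupilstate:::estimate_r0(md$y["u01", ], md$stim, md$tbin, tr)
    s0k <- mean(md$s0_y["u01", md$s0_trial %in% unique(md$trial[tr])])
    neutral_cv[te] <- s0k +
      pupilstate:::r0_lookup(tab, md$stim[te], md$tbin[te])
  }
  expect_gt(cor(fits$null$prediction, neutral_cv), 0.98)
  r2_neutral <- compute_r2(neutral_cv, md$y["u01", ])
  expect_lt(abs(compute_r2(fits$null$prediction, md$y["u01", ]) - r2_neutral),
            0.02)
})

test_that("strong task modulation is detected in nearly all replicates", {
  hits <- 0
  n_rep <- 15
  for (r in seq_len(n_rep)) {
    cfg <- quick_cfg(trials_per_block = 16, n_units = 1)
    cfg$units$effect_types <- "strong"
    cfg$units$coef <- list(strong = c(dp = 0, db = 1, gp = 0, gb = 1))
    g <- generate_session(cfg, seed = 600 + r)
    rs <- extract_reference_responses(g$session)
    md <- build_model_data(g$session, rs)
    full <- fit_state_model(md, "u01", "full", n_folds = 10, seed = r)
    null <- fit_state_model(md, "u01", "null", n_folds = 10, seed = r)
    p <- jackknife_significance(full$prediction, null$prediction,
                                md$y["u01", ], full$fold_of_bin)$p
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits, n_rep - 1)
})
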