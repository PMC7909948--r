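#' Sigmoid nonlinearity constants
#'
#' The state model passes each summed state signal through a saturating
#' difference-of-exponentials (Gompertz) sigmoid
#' `F(x) = B + A * exp(-exp(-k * (x - x0)))`, bounded in `[B, B + A]`.
#' The inflection `x0` is solved once so that `F(1) = 1`: a unit state sum
#' passes through neutrally, which is what reduces the full model to the
#' state-independent `s0 + r0(t)` when all state coefficients are zero and
#' the constant terms are 1. With the default `(B, A, k) = (0, 2, 1)` the
#' implementation uses the algebraically identical form
#' `A * ((1 - B)/A) ^ exp(-k (x - 1))`, for which `F(1) == 1` holds exactly
#' in floating point.
#'
#' @param B Lower asymptote (default 0).
#' @param A Amplitude; upper asymptote is `B + A` (default 2).
#' @param k Slope (default 1).
#' @param identity If `TRUE`, `F(x) = x` (test mode; removes the
#'   nonlinearity so fits are linear in the state regressors).
#' @return A list of class `sigmoid_constants` with fields `B`, `A`, `k`,
#'   `q = (1 - B)/A`, `x0` and `identity`.
#' @export
sigmoid_constants <- function(B = 0, A = 2, k = 1, identity = FALSE) {
  stopifnot(A > 0, k > 0, B < 1)
  q <- (1 - B) / A
  structure(list(B = B, A = A, k = k, q = q,
                 x0 = 1 + log(log(1 / q)) / k, identity = identity),
            class = "sigmoid_constants")
}

#' Evaluate the sigmoid nonlinearity
#'
#' @param x Numeric vector.
#' @param constants A [sigmoid_constants()] object.
#' @return `F(x)`, monotone non-decreasing, bounded in `[B, B + A]`.
#' @export
sigmoid_dexp <- function(x, constants = sigmoid_constants()) {
  if (constants$identity) return(x)
  constants$B + constants$A * constants$q ^ exp(-constants$k * (x - 1))
}

# derivative of sigmoid_dexp wrt x (used by the optimizer gradient)
sigmoid_dexp_deriv <- function(x, constants = sigmoid_constants()) {
  if (constants$identity) return(rep(1, length(x)))
  w <- exp(-constants$k * (x - 1))
  constants$k * log(1 / constants$q) * w *
    (constants$A * constants$q ^ w)
}

neutral_params <- function() {
  c(d0 = 1, dp = 0, db = 0, g0 = 1, gp = 0, gb = 0)
}

#' Forward pass of the state-dependent encoding model
#'
#' Predicted single-trial rate at each bin:
#' `r(t) = s0 * F_d(d0 + dp p(t) + db b(t)) + r0(t) * F_g(g0 + gp p(t) + gb b(t))`
#' where `p(t)` is the (lagged, normalized) pupil regressor, `b(t)` the
#' binary task-engagement regressor, `s0` the spontaneous rate and `r0(t)`
#' the stimulus-specific PSTH value at that bin. Raw values are returned
#' (no rectification); rectify at 0 before computing modulation indices.
#'
#' @param params Named numeric vector `c(d0, dp, db, g0, gp, gb)`.
#' @param s0 Spontaneous rate (spikes/s).
#' @param r0 PSTH value per bin (spikes/s), same length as `p`.
#' @param p,b State regressors per bin.
#' @param constants [sigmoid_constants()].
#' @return Predicted rate per bin.
#' @export
evaluate_state_model <- function(params, s0, r0, p, b,
                                 constants = sigmoid_constants()) {
  if (length(r0) != length(p) || length(p) != length(b)) {
    stop("misaligned lengths: r0/p/b must match")
  }
  u <- params[["d0"]] + params[["dp"]] * p + params[["db"]] * b
  v <- params[["g0"]] + params[["gp"]] * p + params[["gb"]] * b
  s0 * sigmoid_dexp(u, constants) + r0 * sigmoid_dexp(v, constants)
}

#' Shuffle a state signal across trials
#'
#' Permutes per-trial blocks of the signal across trial slots of equal
#' length: values within a trial stay contiguous, the multiset of per-trial
#' values is preserved, and within-trial autocorrelation survives. This is
#' the shuffle behind the null and partial models — it destroys any
#' alignment between the state variable and the response while leaving its
#' marginal statistics intact.
#'
#' @param signal Numeric vector (one value per bin).
#' @param trial_ids Trial label per bin (bins of one trial contiguous).
#' @param seed Integer seed (deterministic output), or `NULL` to draw from
#'   the current RNG stream.
#' @return Shuffled signal, same length.
#' @export
shuffle_state_signal <- function(signal, trial_ids, seed = NULL) {
  do_shuffle <- function() {
    idx <- split(seq_along(signal), factor(trial_ids, levels = unique(trial_ids)))
    lens <- lengths(idx)
    out <- signal
    for (L in unique(lens)) {
      grp <- which(lens == L)
      if (length(grp) < 2) next
      perm <- sample(grp)
      for (i in seq_along(grp)) {
        out[idx[[grp[i]]]] <- signal[idx[[perm[i]]]]
      }
    }
    out
  }
  if (is.null(seed)) do_shuffle() else with_seed(seed, do_shuffle())
}

#' Assemble model data from a session
#'
#' Concatenates the bins of all included reference presentations (in
#' temporal order) together with the aligned state regressors: `p` is the
#' pupil trace lagged by `lag` seconds and normalized by the session
#' maximum; `b` is 1 during active blocks and 0 during passive ones.
#'
#' @param session A `Session`.
#' @param refset Matching [extract_reference_responses()] result.
#' @param lag Pupil lag in s (default 0.75).
#' @return A list of class `StateModelData`: `y` (units x bins), `p`, `b`,
#'   `stim`, `tbin`, `pres`, `trial` per bin; `s0_y`/`s0_trial` silence-bin
#'   rates for per-fold spontaneous-rate estimation; presentation-level
#'   `trial_table` (included rows only).
#' @export
build_model_data <- function(session, refset, lag = 0.75) {
  tt <- refset$trial_table
  inc <- which(tt$included)
  if (length(inc) == 0) stop("no included presentations")
  p_series <- lag_pupil(session$pupil, lag, session$bin_rate) /
    max(session$pupil)
  bins <- integer(0); stim <- character(0); tbin <- integer(0)
  pres <- integer(0); trial <- character(0)
  for (i in inc) {
    b <- refset$pres_bins[[i]]
    bins <- c(bins, b)
    stim <- c(stim, rep(tt$stim[i], length(b)))
    tbin <- c(tbin, seq_along(b))
    pres <- c(pres, rep(tt$pres[i], length(b)))
    trial <- c(trial, rep(tt$trial[i], length(b)))
  }
  b_sig <- as.integer(rep(tt$block_type[inc] == "active",
                          vapply(refset$pres_bins[inc], length, integer(1))))
  structure(list(
    y = session$rate[, bins, drop = FALSE],
    p = p_series[bins], b = b_sig,
    stim = stim, tbin = tbin, pres = pres, trial = trial,
    bins = bins,
    s0_y = session$rate[, refset$s0_bins, drop = FALSE],
    s0_trial = refset$s0_trial,
    trial_table = tt[inc, , drop = FALSE],
    units = refset$units, n_ref_bins = refset$n_ref_bins,
    bin_rate = session$bin_rate), class = "StateModelData")
}

# trial-interleaved fold assignment: trials in temporal order are dealt
# round-robin into n_folds folds, so fit and test data interleave in time
fold_assignment <- function(trial_per_bin, n_folds) {
  trials <- unique(trial_per_bin)
  fold_of_trial <- ((seq_along(trials) - 1L) %% n_folds) + 1L
  names(fold_of_trial) <- trials
  fold_of_trial[trial_per_bin]
}

# per-(stim, tbin) PSTH from a subset of bins; missing cells fall back to
# the grand per-tbin mean (a stimulus can drop out of a training fold)
estimate_r0 <- function(y, stim, tbin, use) {
  tab <- tapply(y[use], list(stim[use], tbin[use]), mean)
  grand <- tapply(y[use], tbin[use], mean)
  if (any(is.na(tab))) {
    for (j in seq_len(ncol(tab))) tab[is.na(tab[, j]), j] <- grand[j]
  }
  tab
}

r0_lookup <- function(tab, stim, tbin) {
  out <- tab[cbind(match(stim, rownames(tab)), tbin)]
  miss <- is.na(out)
  if (any(miss)) {
    grand <- colMeans(tab, na.rm = TRUE)
    out[miss] <- grand[tbin[miss]]
  }
  out
}

fit_one_fold <- function(y, p, b, s0, r0v, constants,
                         inits = list(neutral_params()),
                         max_restarts = 3, bounds = 10) {
  m <- length(y)
  # negligible ridge toward the neutral point: once the sigmoid saturates,
  # coefficient directions become MSE-degenerate plateaus; the ridge
  # tie-breaks them toward the smallest state deviation without
  # measurably biasing identified coefficients
  lam <- 1e-6 * stats::var(y)
  np <- neutral_params()
  obj <- function(th) {
    u <- th[1] + th[2] * p + th[3] * b
    v <- th[4] + th[5] * p + th[6] * b
    pr <- s0 * sigmoid_dexp(u, constants) + r0v * sigmoid_dexp(v, constants)
    mean((pr - y)^2) + lam * sum((th - np)^2)
  }
  grad <- function(th) {
    u <- th[1] + th[2] * p + th[3] * b
    v <- th[4] + th[5] * p + th[6] * b
    fdp <- sigmoid_dexp_deriv(u, constants)
    fgp <- sigmoid_dexp_deriv(v, constants)
    pr <- s0 * sigmoid_dexp(u, constants) + r0v * sigmoid_dexp(v, constants)
    r <- 2 * (pr - y) / m
    du <- s0 * fdp; dv <- r0v * fgp
    c(sum(r * du), sum(r * du * p), sum(r * du * b),
      sum(r * dv), sum(r * dv * p), sum(r * dv * b)) + 2 * lam * (th - np)
  }
  run <- function(th0) tryCatch(
    stats::optim(th0, obj, grad, method = "L-BFGS-B",
                 lower = -bounds, upper = bounds,
                 control = list(maxit = 500, factr = 1e7)),
    error = function(e) NULL)
  best <- NULL
  for (th0 in inits) {
    fit <- run(th0)
    if (!is.null(fit) && fit$convergence == 0 &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  # seeded random restarts if no start converged
  tries <- 0
  while (is.null(best) && tries < max_restarts) {
    fit <- run(neutral_params() + stats::rnorm(6, sd = 0.25))
    if (!is.null(fit) && fit$convergence == 0) best <- fit
    tries <- tries + 1
  }
  if (is.null(best)) {
    th0 <- inits[[1]]
    return(list(par = th0, value = obj(th0), convergence = 99L))
  }
  names(best$par) <- names(neutral_params())
  best
}

#' Fit a state model variant with cross-validation
#'
#' Fits the six coefficients `(d0, dp, db, g0, gp, gb)` by minimizing mean
#' squared error (bounded quasi-Newton from the neutral initialization
#' `d0 = g0 = 1`, other coefficients 0, with seeded random restarts on
#' non-convergence). Model variants differ only in which regressors are
#' shuffled across trials before fitting: `full` (none), `pupil_only`
#' (task shuffled), `task_only` (pupil shuffled), `null` (both).
#'
#' Cross-validation is k-fold over interleaved trials: each fold's model is
#' fit on the other folds' trials (with `r0`/`s0` re-estimated from the
#' training trials unless `refset_fixed` pins them, e.g. to generative
#' ground truth for parameter-recovery studies) and predicts the held-out
#' trials, so the concatenated prediction covers every bin exactly once.
#'
#' @param mdata A [build_model_data()] object.
#' @param unit Unit id (row of `mdata$y`).
#' @param model_spec One of `"full"`, `"null"`, `"task_only"`, `"pupil_only"`.
#'   The P1/P2 persistence analysis reuses these with `b` re-interpreted as
#'   the passive-block indicator, so `"task_only"` then means block-only.
#' @param n_folds Number of folds (default 20; fit on 95%, predict 5%).
#' @param constants [sigmoid_constants()].
#' @param seed Seed controlling shuffles and restart jitter.
#' @param refset_fixed Optional list `(r0, s0)` with `r0` a stim x time
#'   matrix; when given, `r0`/`s0` are held at these values in every fold.
#' @param max_restarts Random restarts after a non-converged fit.
#' @return List of class `StateModelFit`: `params` (6 x folds),
#'   `prediction` (per bin, held-out), `fold_of_bin`, `train_mse`,
#'   `convergence` per fold, plus bookkeeping.
#' @export
fit_state_model <- function(mdata, unit,
                            model_spec = c("full", "null", "task_only",
                                           "pupil_only"),
                            n_folds = 20, constants = sigmoid_constants(),
                            seed = 1, refset_fixed = NULL, max_restarts = 3) {
  model_spec <- match.arg(model_spec)
  y <- mdata$y[unit, ]
  p <- mdata$p
  b <- as.numeric(mdata$b)
  shuf_p <- model_spec %in% c("null", "task_only")
  shuf_b <- model_spec %in% c("null", "pupil_only")
  with_seed(seed, {
    if (shuf_p) p <- shuffle_state_signal(p, mdata$trial, seed = NULL)
    if (shuf_b) b <- shuffle_state_signal(b, mdata$trial, seed = NULL)
  })
  fold_bin <- fold_assignment(mdata$trial, n_folds)
  pred <- rep(NA_real_, length(y))
  params <- matrix(NA_real_, 6, n_folds,
                   dimnames = list(names(neutral_params()), NULL))
  train_mse <- conv <- rep(NA_real_, n_folds)
  trial_of_s0 <- mdata$s0_trial
  for (f in seq_len(n_folds)) {
    train <- fold_bin != f
    test <- !train
    if (!any(test)) next
    if (is.null(refset_fixed)) {
      tab <- estimate_r0(y, mdata$stim, mdata$tbin, train)
      train_trials <- unique(mdata$trial[train])
      s0_use <- trial_of_s0 %in% train_trials
      s0 <- if (any(s0_use)) mean(mdata$s0_y[unit, s0_use]) else
        mean(mdata$s0_y[unit, ])
    } else {
      tab <- refset_fixed$r0
      s0 <- refset_fixed$s0
    }
    r0_train <- r0_lookup(tab, mdata$stim[train], mdata$tbin[train])
    r0_test <- r0_lookup(tab, mdata$stim[test], mdata$tbin[test])
    # warm start: folds share 95% of their data, so the previous fold's
    # optimum is an excellent starting point; cold folds multi-start
    # (neutral plus seeded jitters) to escape saturated-sigmoid plateaus
    warm <- f > 1 && !is.na(conv[f - 1]) && conv[f - 1] == 0
    fit <- with_seed(seed + 7919L * f, {
      inits <- if (warm) {
        wp <- params[, f - 1]
        names(wp) <- names(neutral_params())
        list(wp)
      } else {
        c(list(neutral_params()),
          lapply(1:2, function(i) neutral_params() + stats::rnorm(6, sd = 0.25)))
      }
      fit_one_fold(y[train], p[train], b[train], s0, r0_train,
                   constants, inits = inits, max_restarts = max_restarts)
    })
    params[, f] <- fit$par
    train_mse[f] <- fit$value
    conv[f] <- fit$convergence
    if (fit$convergence == 99) {
      warning("fold ", f, " (", model_spec, ") did not converge; flagged")
    }
    pred[test] <- evaluate_state_model(fit$par, s0, r0_test,
                                       p[test], b[test], constants)
  }
  structure(list(model_spec = model_spec, params = params, prediction = pred,
                 fold_of_bin = fold_bin, train_mse = train_mse,
                 convergence = conv, n_folds = n_folds, seed = seed,
                 constants = constants,
                 r0_source = if (is.null(refset_fixed)) "refit" else "fixed"),
            class = "StateModelFit")
}

# state-independent (s0 + r0) prediction on a bin subset, with r0/s0
# estimated from that same subset — the optimizer's starting point
predict_neutral <- function(mdata, unit, use) {
  y <- mdata$y[unit, ]
  tab <- estimate_r0(y, mdata$stim, mdata$tbin, use)
  tr_trials <- unique(mdata$trial[use])
  s0_use <- mdata$s0_trial %in% tr_trials
  s0 <- if (any(s0_use)) mean(mdata$s0_y[unit, s0_use]) else
    mean(mdata$s0_y[unit, ])
  s0 + r0_lookup(tab, mdata$stim[use], mdata$tbin[use])
}

#' Cross-validated prediction accuracy
#'
#' Fraction of variance explained: the squared Pearson correlation between
#' prediction and observation. Defined as 0 when either series is constant.
#'
#' @param pred,obs Equal-length numeric vectors (length >= 2).
#' @return r-squared in `[0, 1]`.
#' @export
compute_r2 <- function(pred, obs) {
  stopifnot(length(pred) == length(obs), length(obs) >= 2)
  ok <- is.finite(pred) & is.finite(obs)
  if (stats::sd(pred[ok]) == 0 || stats::sd(obs[ok]) == 0) return(0)
  stats::cor(pred[ok], obs[ok])^2
}

#' Unique variance attributed to each state variable
#'
#' The variance uniquely explained by a state variable is the difference
#' between cross-validated r-squared for the full model and for the partial
#' model in which that variable was shuffled: task-unique uses the
#' pupil-only partial, pupil-unique the task-only partial. Small negative
#' values are preserved (they are evidence of overfitting noise and feed
#' the significance test), not clamped.
#'
#' @param r2_full,r2_task_only,r2_pupil_only Cross-validated r-squared
#'   values computed on identical held-out bins.
#' @return List with `task_unique` and `pupil_unique`.
#' @export
unique_variance <- function(r2_full, r2_task_only, r2_pupil_only) {
  list(task_unique = r2_full - r2_pupil_only,
       pupil_unique = r2_full - r2_task_only)
}

#' Jackknifed t-test between two model predictions
#'
#' Leave-one-fold-out estimates of the difference in Pearson correlation
#' with the observed response between models A and B; the t statistic is
#' the mean difference over its jackknife standard error (with the standard
#' (n-1)/n inflation) and the two-sided p-value uses n-1 degrees of
#' freedom. Identical predictions give p = 1.
#'
#' @param pred_a,pred_b Held-out predictions from two model fits on the
#'   same bins.
#' @param obs Observed response.
#' @param folds Fold id per bin (matched across models).
#' @return List: `p`, `t`, `estimate` (mean correlation difference), `df`.
#' @export
jackknife_significance <- function(pred_a, pred_b, obs, folds) {
  ids <- sort(unique(folds))
  d <- vapply(ids, function(f) {
    keep <- folds != f & is.finite(pred_a) & is.finite(pred_b)
    if (sum(keep) < 3) return(NA_real_)
    ra <- if (stats::sd(pred_a[keep]) == 0 || stats::sd(obs[keep]) == 0) 0 else
      stats::cor(pred_a[keep], obs[keep])
    rb <- if (stats::sd(pred_b[keep]) == 0 || stats::sd(obs[keep]) == 0) 0 else
      stats::cor(pred_b[keep], obs[keep])
    ra - rb
  }, numeric(1))
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 3) {
    warning("fewer than 3 usable folds; jackknife p undefined")
    return(list(p = NA_real_, t = NA_real_, estimate = NA_real_, df = n - 1))
  }
  m <- mean(d)
  se <- sqrt((n - 1) / n * sum((d - m)^2))
  if (se == 0) {
    return(list(p = if (m == 0) 1 else 0, t = if (m == 0) 0 else Inf,
                estimate = m, df = n - 1))
  }
  t <- m / se
  list(p = 2 * stats::pt(-abs(t), df = n - 1), t = t, estimate = m, df = n - 1)
}

#' Classify a unit by its state modulation
#'
#' Gate on overall state dependence (full vs null model); among
#' state-modulated units, assign `task_only` / `pupil_only` / `both`
#' according to which unique-variance contrasts are significant, and
#' `ambiguous_state` when the state effect cannot be uniquely attributed to
#' either variable.
#'
#' @param p_state Full-vs-null p-value.
#' @param p_task_unique Full-vs-pupil-only p-value.
#' @param p_pupil_unique Full-vs-task-only p-value.
#' @param alpha Significance level (default 0.05).
#' @return One of `"none"`, `"task_only"`, `"pupil_only"`, `"both"`,
#'   `"ambiguous_state"`.
#' @export
classify_unit <- function(p_state, p_task_unique, p_pupil_unique,
                          alpha = 0.05) {
  if (!is.finite(p_state) || p_state >= alpha) return("none")
  st <- is.finite(p_task_unique) && p_task_unique < alpha
  sp <- is.finite(p_pupil_unique) && p_pupil_unique < alpha
  if (st && sp) "both"
  else if (st) "task_only"
  else if (sp) "pupil_only"
  else "ambiguous_state"
}

#' Fit all model variants for one unit and evaluate them
#'
#' Runs the complete per-unit analysis: fits the full, null, task-only and
#' pupil-only models with matched folds and shuffle seeds, computes
#' cross-validated r-squared for each, unique variances, jackknifed
#' p-values (state = full vs null; task-unique = full vs pupil-only;
#' pupil-unique = full vs task-only) and the category label.
#'
#' @inheritParams fit_state_model
#' @param alpha Significance level for classification.
#' @return List of class `ModelEvaluation`: r2 values, unique variances,
#'   p-values, `category`, and the four `StateModelFit` objects in `$fits`.
#' @export
evaluate_unit <- function(mdata, unit, n_folds = 20,
                          constants = sigmoid_constants(), seed = 1,
                          alpha = 0.05, refset_fixed = NULL) {
  specs <- c("full", "null", "task_only", "pupil_only")
  fits <- lapply(specs, function(ms)
    fit_state_model(mdata, unit, ms, n_folds = n_folds, constants = constants,
                    seed = seed, refset_fixed = refset_fixed))
  names(fits) <- specs
  obs <- mdata$y[unit, ]
  r2 <- vapply(fits, function(f) compute_r2(f$prediction, obs), numeric(1))
  uv <- unique_variance(r2[["full"]], r2[["task_only"]], r2[["pupil_only"]])
  folds <- fits$full$fold_of_bin
  p_state <- jackknife_significance(fits$full$prediction,
                                    fits$null$prediction, obs, folds)$p
  p_task <- jackknife_significance(fits$full$prediction,
                                   fits$pupil_only$prediction, obs, folds)$p
  p_pupil <- jackknife_significance(fits$full$prediction,
                                    fits$task_only$prediction, obs, folds)$p
  structure(list(
    unit = unit,
    r2_full = r2[["full"]], r2_null = r2[["null"]],
    r2_task_only = r2[["task_only"]], r2_pupil_only = r2[["pupil_only"]],
    r2_task_unique = uv$task_unique, r2_pupil_unique = uv$pupil_unique,
    p_state = p_state, p_task_unique = p_task, p_pupil_unique = p_pupil,
    category = classify_unit(p_state, p_task, p_pupil, alpha),
    fits = fits), class = "ModelEvaluation")
}
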