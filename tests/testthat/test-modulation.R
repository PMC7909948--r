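test_that("modulation index arithmetic, bounds and conventions", {
  expect_equal(compute_mi(3, 1), 0.5)
  expect_equal(compute_mi(2.7, 2.7), 0)
  expect_equal(compute_mi(2, 0), 1)
  expect_equal(compute_mi(0, 0), 0)  # zero-denominator convention
  expect_error(compute_mi(-1, 2), "negative")
  set.seed(9)
  a <- runif(500, 0, 50); b <- runif(500, 0, 50)
  expect_equal(compute_mi(a, b), -compute_mi(b, a))
  expect_true(all(abs(compute_mi(a, b)) <= 1))
})

# minimal model-data stub: n presentations of one bin each
mi_stub <- function(n, block_type) {
  list(pres = seq_len(n),
       trial_table = data.frame(pres = seq_len(n), block_type = block_type,
                                stringsAsFactors = FALSE))
}

test_that("MI decomposition subtracts partial-model predictions", {
  md <- mi_stub(4, c("active", "active", "passive", "passive"))
  mask <- md$trial_table$block_type == "active"
  # rates chosen so MI_full = 0.30 and MI_pupil_only = 0.05
  preds <- list(full = c(13, 13, 7, 7), task_only = c(11, 11, 9, 9),
                pupil_only = c(10.5, 10.5, 9.5, 9.5))
  res <- mi_decomposition(preds, md, mask, pair = "AP")
  expect_equal(res$mi_full, 0.3)
  expect_equal(res$mi_pupil_only, 0.05)
  expect_equal(res$mi_task_unique, 0.25)
  expect_equal(res$mi_pupil_unique, res$mi_full - res$mi_task_only)
  same <- list(full = rep(5, 4), task_only = rep(5, 4),
               pupil_only = rep(5, 4))
  res0 <- mi_decomposition(same, md, mask)
  expect_true(all(unlist(res0[, -1]) == 0))
  expect_warning(r <- mi_decomposition(preds, md, rep(TRUE, 4)), "empty")
  expect_true(is.na(r$mi_full))
})

test_that("sign normalization flips negative pairs and measures reduction", {
  sn <- sign_normalized_reduction(-0.2, -0.1)
  expect_equal(sn$normalized$only, 0.2)
  expect_equal(sn$normalized$unique, 0.1)
  expect_equal(sign_normalized_reduction(c(0.3, 0.2), c(0.3, 0.2))$reduction, 0)
  # zero pair mean takes sign +1
  expect_equal(sign_normalized_reduction(0.1, -0.1)$normalized$only, 0.1)
  # population arithmetic on the published means
  expect_equal(sign_normalized_reduction(0.141, 0.095)$reduction,
               1 - 0.095 / 0.141)
})

test_that("P1/P2 analysis needs a post-behavior passive block", {
  cfg <- quick_cfg(trials_per_block = 4, n_units = 1)
  cfg$blocks <- c("passive", "active")
  g <- generate_session(cfg, seed = 51)
  rs <- extract_reference_responses(g$session)
  md <- build_model_data(g$session, rs)
  expect_warning(out <- p1p2_analysis(md, "u01", n_folds = 4), "P2")
  expect_null(out)
})

test_that("P1/P2 decomposition separates pupil-mediated from persistent changes", {
  # persistent-change construction: P2 responses scaled up by hand with a
  # flat pupil, so block identity itself must carry the modulation
  cfg <- quick_cfg(trials_per_block = 8, n_units = 1, noise = "gaussian",
                   gaussian_sd = 1)
  cfg$units$effect_types <- "none"
  cfg$pupil$ou_sigma <- 0.5
  cfg$pupil$active_shift <- 0
  cfg$pupil$dilation_amp_active <- 1.5  # same transient in all blocks
  g <- generate_session(cfg, seed = 52)
  ses <- g$session
  p2 <- ses$epochs[ses$epochs$label == "PASSIVE_BLOCK:2", ]
  bi <- pupilstate:::epoch_bins(p2$start, p2$end, ses$bin_rate, ncol(ses$rate))
  ses$rate[, bi] <- ses$rate[, bi] * 1.5
  rs <- extract_reference_responses(ses)
  md <- build_model_data(ses, rs)
  res <- p1p2_analysis(md, "u01", n_folds = 5, seed = 3)
  # block-only modulation is large and survives regressing out pupil
  expect_gt(res$mi_task_only, 0.08)
  expect_gt(res$mi_task_unique, 0.6 * res$mi_task_only)
})

test_that("pupil-mediated P2 changes are absorbed by the pupil regressor", {
  # P2 rate elevation generated entirely through a persistent pupil shift
  # acting on a pupil-modulated unit: block-only MI is substantial, but
  # the block-unique component collapses once pupil is regressed in
  cfg <- quick_cfg(trials_per_block = 10, n_units = 1, noise = "gaussian",
                   gaussian_sd = 1.5)
  cfg$units$effect_types <- "strongpupil"
  cfg$units$coef <- list(strongpupil = c(dp = 1.2, db = 0, gp = 1.2, gb = 0))
  cfg$pupil$ou_sigma <- 1
  cfg$pupil$passive_baseline <- 20
  cfg$pupil$active_shift <- 0
  cfg$pupil$p2_baseline_shift <- 40
  cfg$pupil$dilation_amp_active <- 1.5
  g <- generate_session(cfg, seed = 53)
  rs <- extract_reference_responses(g$session)
  md <- build_model_data(g$session, rs)
  res <- p1p2_analysis(md, "u01", n_folds = 5, seed = 3)
  expect_gt(res$mi_task_only, 0.05)
  expect_lt(abs(res$mi_task_unique), 0.5 * abs(res$mi_task_only))
})
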