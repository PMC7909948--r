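test_that("save/load round trip is the identity, bitwise on signals", {
  g <- generate_session(quick_cfg(), seed = 21)
  dir <- file.path(tempdir(), "ses-rt")
  save_session(g$session, dir)
  s2 <- load_session(dir)
  expect_identical(s2$rate, g$session$rate)
  expect_identical(s2$pupil, g$session$pupil)
  expect_equal(s2$epochs$label, g$session$epochs$label)
  expect_equal(s2$epochs$start, g$session$epochs$start, tolerance = 1e-9)
  expect_identical(s2$bin_rate, g$session$bin_rate)
  expect_identical(s2$meta$session_id, g$session$meta$session_id)
  unlink(dir, recursive = TRUE)
})

test_that("loader reports missing container pieces and invalid epochs", {
  g <- generate_session(quick_cfg(), seed = 22)
  dir <- file.path(tempdir(), "ses-bad")
  save_session(g$session, dir)
  file.remove(file.path(dir, "epochs.csv"))
  expect_error(load_session(dir), "epochs.csv")
  unlink(dir, recursive = TRUE)

  s <- g$session
  s$epochs$end[s$epochs$label == "TRIAL:1"] <-
    ncol(s$rate) / s$bin_rate + 5  # trial extends past the signal end
  expect_error(validate_session(s), "extent")
  s2 <- g$session
  i <- which(grepl("^PASSIVE_BLOCK:1", s2$epochs$label))
  s2$epochs$end[i] <- s2$epochs$end[i] + 3  # overlapping blocks
  expect_error(validate_session(s2), "block")
})

test_that("pupil lagging shifts by whole bins and holds the first value", {
  x <- rnorm(200)
  expect_identical(lag_pupil(x, 0), x)
  imp <- rep(0, 200); imp[100] <- 1
  out <- lag_pupil(imp, 0.75, 20)
  expect_equal(which(out == 1), 115)  # 0.75 s = 15 bins at 20 Hz
  expect_equal(lag_pupil(rep(3.3, 50), 0.75), rep(3.3, 50))
  expect_equal(lag_pupil(x, 0.75)[1:15], rep(x[1], 15))
  expect_error(lag_pupil(x, 0.013), "bin")
  # interior samples equal a plain array shift
  expect_equal(lag_pupil(x, 0.75)[16:200], x[1:185])
})

test_that("reference extraction averages included presentations and excludes errors", {
  expect_warning(rs <- extract_reference_responses(manual_session()),
                 "stimulus 03")
  tt <- rs$trial_table
  # FA-trial reference excluded with the documented reason
  expect_false(any(tt$included[tt$trial == "3"]))
  expect_match(tt$reason[tt$trial == "3"], "fa")
  # presentation overlapping the target excluded
  expect_false(tt$included[tt$stim == "03"])
  expect_match(tt$reason[tt$stim == "03"], "target")
  # identical responses average exactly; spontaneous rate from silence
  expect_equal(unname(rs$r0["u01", "01", ]), rep(5, 15))
  expect_equal(unname(rs$r0["u02", "02", ]), rep(8, 15))
  expect_equal(unname(rs$s0), c(1, 2))
  # no included presentation bin overlaps any TARGET epoch
  tgt <- manual_session()$epochs
  tgt <- tgt[tgt$label == "TARGET", ]
  tgt_bins <- unlist(lapply(seq_len(nrow(tgt)), function(i)
    pupilstate:::epoch_bins(tgt$start[i], tgt$end[i], 20, 800)))
  inc_bins <- unlist(rs$pres_bins[tt$included])
  expect_length(intersect(inc_bins, tgt_bins), 0)
})

test_that("r0 estimates converge to the generative PSTH", {
  # state-independent unit, no noise: r0 - s0 equals the PSTH exactly
  cfg <- quick_cfg(trials_per_block = 5, n_units = 1, n_stim = 4,
                   noise = "none")
  cfg$units$effect_types <- "none"
  g <- generate_session(cfg, seed = 31)
  rs <- extract_reference_responses(g$session)
  for (s in rs$stims) {
    expect_equal(unname(rs$r0["u01", s, ] - rs$s0[["u01"]]),
                 unname(g$truth$psth["u01", s, ]), tolerance = 1e-9)
  }
  # Poisson noise: error shrinks toward truth as presentations accumulate
  cfgN <- quick_cfg(trials_per_block = 40, n_units = 1, n_stim = 2)
  cfgN$units$effect_types <- "none"
  gN <- generate_session(cfgN, seed = 32)
  rsN <- extract_reference_responses(gN$session)
  tt <- rsN$trial_table
  err_for <- function(rows) {
    acc <- rowMeans(vapply(rows, function(i)
      gN$session$rate["u01", rsN$pres_bins[[i]]], numeric(15)))
    mean(abs(acc - rsN$s0[["u01"]] - gN$truth$psth["u01", "01", ]))
  }
  rows <- which(tt$stim == "01" & tt$included)
  set.seed(1)
  e_small <- mean(replicate(20, err_for(sample(rows, 5))))
  e_big <- err_for(rows)
  expect_lt(e_big, e_small)
})

test_that("pupil median split balances classes and ties go to small", {
  rs <- list(trial_table = data.frame(
    mean_pupil = c(1, 2, 3, 4), included = TRUE))
  expect_equal(label_pupil_trials(rs), c("small", "small", "large", "large"))
  rs$trial_table$mean_pupil <- rep(2, 4)
  expect_warning(lab <- label_pupil_trials(rs), "constant")
  expect_equal(lab, rep("small", 4))
  g <- generate_session(quick_cfg(), seed = 33)
  rsg <- extract_reference_responses(g$session)
  labg <- label_pupil_trials(rsg)[rsg$trial_table$included]
  expect_lte(abs(sum(labg == "large") - sum(labg == "small")), 1)
})
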