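test_that("generation is deterministic and respects the noise model", {
  cfg <- quick_cfg()
  g1 <- generate_session(cfg, seed = 61)
  g2 <- generate_session(cfg, seed = 61)
  expect_identical(g1$session$rate, g2$session$rate)
  expect_identical(g1$session$pupil, g2$session$pupil)
  expect_identical(g1$session$epochs, g2$session$epochs)
  g3 <- generate_session(cfg, seed = 62)
  expect_false(identical(g1$session$rate, g3$session$rate))
  cfg0 <- quick_cfg(noise = "none")
  g0 <- generate_session(cfg0, seed = 61)
  expect_identical(g0$session$rate, g0$truth$noiseless)
})

test_that("generated sessions satisfy all epoch invariants", {
  for (s in c(71, 72, 73)) {
    g <- generate_session(quick_cfg(), seed = s)
    expect_true(validate_session(g$session))
    refs <- g$session$epochs[grepl("^REFERENCE:", g$session$epochs$label), ]
    expect_true(all(abs(refs$end - refs$start - 0.75) < 1e-9))
  }
})

test_that("pupil is larger in active blocks, with onset dilations only there", {
  # deterministic limit: zero noise, zero transients -> block baselines
  cfg <- quick_cfg(trials_per_block = 3, n_units = 1)
  cfg$pupil$ou_sigma <- 0
  cfg$pupil$dilation_amp_active <- 0
  cfg$pupil$dilation_amp_passive <- 0
  g <- generate_session(cfg, seed = 81)
  expect_setequal(unique(g$session$pupil),
                  cfg$pupil$passive_baseline +
                    c(0, cfg$pupil$active_shift))
  # active-block mean exceeds passive-block mean in >= 95/100 seeded runs
  # (blocks long enough for slow arousal drift to average out)
  cfg2 <- quick_cfg(trials_per_block = 15, n_units = 1)
  bigger <- 0
  for (s in 1:100) {
    g2 <- generate_session(cfg2, seed = 1000 + s)
    ep <- g2$session$epochs
    n <- length(g2$session$pupil)
    act <- ep[grepl("^ACTIVE_BLOCK", ep$label), ]
    pas <- ep[grepl("^PASSIVE_BLOCK", ep$label), ]
    ab <- unlist(lapply(seq_len(nrow(act)), function(i)
      pupilstate:::epoch_bins(act$start[i], act$end[i], 20, n)))
    pb <- unlist(lapply(seq_len(nrow(pas)), function(i)
      pupilstate:::epoch_bins(pas$start[i], pas$end[i], 20, n)))
    bigger <- bigger + (mean(g2$session$pupil[ab]) > mean(g2$session$pupil[pb]))
  }
  expect_gte(bigger, 95)
  # transients only in active blocks show up in trial-aligned averages
  cfg3 <- quick_cfg(trials_per_block = 6, n_units = 1)
  cfg3$pupil$ou_sigma <- 0
  cfg3$pupil$active_shift <- 0
  cfg3$pupil$dilation_amp_passive <- 0
  g3 <- generate_session(cfg3, seed = 82)
  onset_rise <- function(rows) {
    mean(vapply(rows, function(i) {
      b0 <- round(g3$truth$trials$start[i] * 20)
      mean(g3$session$pupil[(b0 + 10):(b0 + 40)]) - g3$session$pupil[b0]
    }, numeric(1)))
  }
  act_rows <- which(g3$truth$trials$block_type == "active")
  pas_rows <- which(g3$truth$trials$block_type == "passive")
  expect_gt(onset_rise(act_rows), 1)
  expect_equal(onset_rise(pas_rows), 0, tolerance = 1e-9)
})

test_that("trial lengths follow a flat hazard over 2-5 references", {
  set.seed(9)
  draws <- replicate(20000, pupilstate:::draw_n_refs(1 / 3))
  # hazard at k = 2, 3, 4: P(stop at k | reached k), constant by design
  haz <- vapply(2:4, function(k)
    sum(draws == k) / sum(draws >= k), numeric(1))
  expect_true(all(abs(haz - 1 / 3) < 0.02))
  expect_true(all(draws >= 2 & draws <= 5))
})

test_that("stored ground truth is self-consistent with the forward model", {
  g <- generate_session(quick_cfg(trials_per_block = 5), seed = 91)
  cfg <- g$truth$config
  for (u in rownames(g$truth$params)) {
    expect_identical(
      evaluate_state_model(g$truth$params[u, ], g$truth$s0,
                           g$truth$r0_bin[u, ], g$truth$p, g$truth$b,
                           cfg$constants),
      g$truth$noiseless[u, ])
  }
  # stored generative MI equals an independent recomputation from the
  # noiseless rates over included presentations
  rs <- extract_reference_responses(g$session)
  tt <- rs$trial_table
  inc <- which(tt$included)
  u <- rownames(g$truth$params)[1]
  mr <- function(rows) mean(unlist(lapply(rs$pres_bins[rows], function(b)
    g$truth$noiseless[u, b])))
  act <- mr(inc[tt$block_type[inc] == "active"])
  pas <- mr(inc[tt$block_type[inc] == "passive"])
  expect_identical(g$truth$mi$mi_ap[1], (act - pas) / (act + pas))
})

test_that("population generation mixes effect types reproducibly", {
  cfg <- quick_cfg(trials_per_block = 2, n_units = 3)
  pop <- generate_population(3, cfg, proportions = c(task = 0, pupil = 0,
                                                     both = 0, none = 1),
                             seed = 5)
  for (g in pop) expect_true(all(g$truth$effect_types == "none"))
  pop1 <- generate_population(2, cfg, seed = 6)
  pop2 <- generate_population(2, cfg, seed = 6)
  expect_identical(lapply(pop1, function(g) g$session$rate),
                   lapply(pop2, function(g) g$session$rate))
})
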