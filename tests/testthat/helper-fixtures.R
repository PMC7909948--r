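# Small generative config for fast tests: few trials, few stimuli so every
# stimulus gets presentations (avoids exclusion warnings).
quick_cfg <- function(trials_per_block = 6, n_units = 2, n_stim = 6, ...) {
  generative_config(trials_per_block = trials_per_block, n_stim = n_stim,
                    units = list(n = n_units), ...)
}

# Hand-built session with known epochs and piecewise-constant rates:
# P1 [0,20) with one passive trial, A1 [20,40) with a hit trial (whose third
# reference overlaps the target) and an FA trial. Unit u01 fires at 1
# spike/s in silence and 5 during references; u02 at 2 and 8.
manual_session <- function() {
  br <- 20
  n <- 800
  ep <- data.frame(
    label = c("PASSIVE_BLOCK:1", "ACTIVE_BLOCK:1",
              "REFERENCE:01", "REFERENCE:02", "TARGET", "TRIAL:1", "CR",
              "REFERENCE:01", "REFERENCE:02", "REFERENCE:03", "TARGET",
              "LICK", "TRIAL:2", "HIT",
              "REFERENCE:01", "LICK", "TRIAL:3", "FA"),
    start = c(0, 20,
              2, 3.45, 4.9, 2, 2,
              22, 23.45, 24.9, 24.9, 25.4, 22, 22,
              30, 30.95, 30, 30),
    end = c(20, 40,
            2.75, 4.2, 5.65, 6.4, 6.4,
            22.75, 24.2, 25.65, 25.65, 25.45, 26.4, 26.4,
            30.75, 31.0, 31.0, 31.0),
    stringsAsFactors = FALSE)
  rate <- rbind(u01 = rep(1, n), u02 = rep(2, n))
  refs <- ep[grepl("^REFERENCE:", ep$label), ]
  for (i in seq_len(nrow(refs))) {
    bi <- pupilstate:::epoch_bins(refs$start[i], refs$end[i], br, n)
    rate["u01", bi] <- 5
    rate["u02", bi] <- 8
  }
  pupil <- seq_len(n) / 100
  new_session(rate, pupil, ep, bin_rate = br,
              meta = list(session_id = "manual01", animal = "m", area = "A1"))
}
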