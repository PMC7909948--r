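#' Configuration for synthetic session generation
#'
#' Defines the study conditions a generated session emulates: alternating
#' passive/active blocks; trials of 2-5 reference sounds (0.75 s each,
#' 0.7 s inter-stimulus interval) whose count follows a flat hazard, each
#' followed by a target with a 0.1-1.5 s response window; pupil that is
#' larger in active blocks with a trial-onset evoked dilation; spike rates
#' generated by the state model forward pass with known coefficients plus
#' count noise; and hit/miss/false-alarm outcomes at configurable rates.
#'
#' Per-unit state coefficients are set by `effect_types` (each unit one of
#' `"task"`, `"pupil"`, `"both"`, `"none"`), mapped to coefficient vectors
#' in `units$coef`.
#'
#' @param blocks Block ordering, e.g. `c("passive","active","passive")`
#'   (P1-A1-P2).
#' @param trials_per_block Trials in every block (default 60).
#' @param n_stim Reference stimulus set size (default 30).
#' @param bin_rate Bins per second (default 20).
#' @param ref_dur,isi,target_dur Stimulus timing in s (defaults 0.75 / 0.7 /
#'   0.75); must sit on the bin grid.
#' @param resp_window Response window after target onset (default
#'   `c(0.1, 1.5)`).
#' @param iti Inter-trial interval in s (default 2.5).
#' @param hazard Flat hazard: probability the target follows after each
#'   completed reference from the 2nd to the 4th (forced at the 5th).
#' @param refs_range Reference-count support (fixed 2-5).
#' @param pupil Pupil process parameters: `passive_baseline` and
#'   `active_shift` (arbitrary diameter units), Ornstein-Uhlenbeck `ou_tau`
#'   (s) and `ou_sigma` (stationary SD), trial-onset dilation amplitudes
#'   per block type, gamma-kernel `dilation_peak` (s) and `dilation_shape`,
#'   and `p2_baseline_shift` (arousal persisting into the post-behavior
#'   passive block, default 0).
#' @param units Unit parameters: `n`, spontaneous rate `s0` (spikes/s),
#'   PSTH `rate_scale` (spikes/s), `effect_types` (recycled over units;
#'   `NULL` cycles task/pupil/both/none), `coef` lookup per effect type.
#' @param behavior `hit_rate` (per target-reaching trial) and `fa_rate`
#'   (per completed reference).
#' @param noise `"poisson"` (counts per bin, default), `"gaussian"`, or
#'   `"none"` (observed rate equals the noiseless rate bitwise).
#' @param gaussian_sd SD for the Gaussian noise option (spikes/s).
#' @param constants [sigmoid_constants()] shared by generator and fitter.
#' @param area,animal Metadata labels.
#' @return A list of class `GenerativeConfig`.
#' @export
generative_config <- function(
    blocks = c("passive", "active", "passive"),
    trials_per_block = 60,
    n_stim = 30,
    bin_rate = 20,
    ref_dur = 0.75, isi = 0.7, target_dur = 0.75,
    resp_window = c(0.1, 1.5),
    iti = 2.5,
    hazard = 1 / 3,
    refs_range = c(2L, 5L),
    pupil = list(),
    units = list(),
    behavior = list(),
    noise = c("poisson", "gaussian", "none"),
    gaussian_sd = 2,
    constants = sigmoid_constants(),
    area = "A1", animal = "syn01") {
  noise <- match.arg(noise)
  pupil_def <- list(passive_baseline = 40, active_shift = 8,
                    ou_tau = 15, ou_sigma = 6,
                    dilation_amp_active = 6, dilation_amp_passive = 1.5,
                    dilation_peak = 1, dilation_shape = 2,
                    p2_baseline_shift = 0, miss_small_pupil = FALSE)
  pupil <- utils::modifyList(pupil_def, pupil)
  units_def <- list(n = 4, s0 = 5, rate_scale = 20, effect_types = NULL,
                    coef = list(
                      task = c(dp = 0, db = 0.5, gp = 0, gb = 0.5),
                      pupil = c(dp = 0.75, db = 0, gp = 0.75, gb = 0),
                      both = c(dp = 0.5, db = 0.4, gp = 0.5, gb = 0.4),
                      none = c(dp = 0, db = 0, gp = 0, gb = 0)))
  units <- utils::modifyList(units_def, units)
  behavior_def <- list(hit_rate = 0.85, fa_rate = 0.05)
  behavior <- utils::modifyList(behavior_def, behavior)
  for (d in c(ref_dur, isi, target_dur, iti)) snap_int(d * bin_rate)
  structure(list(blocks = blocks, trials_per_block = trials_per_block,
                 n_stim = n_stim, bin_rate = bin_rate, ref_dur = ref_dur,
                 isi = isi, target_dur = target_dur,
                 resp_window = resp_window, iti = iti, hazard = hazard,
                 refs_range = refs_range, pupil = pupil, units = units,
                 behavior = behavior, noise = noise,
                 gaussian_sd = gaussian_sd, constants = constants,
                 area = area, animal = animal),
            class = "GenerativeConfig")
}

# draw a reference count with a flat hazard over 2..5
draw_n_refs <- function(hazard, refs_range = c(2L, 5L)) {
  k <- refs_range[1]
  while (k < refs_range[2] && stats::runif(1) > hazard) k <- k + 1L
  k
}

grid_snap <- function(t, bin_rate) round(t * bin_rate) / bin_rate

# Build the epoch scaffold for one session; uses the current RNG stream.
# Returns list(epochs = data.frame, trials = per-trial info, duration).
generate_epochs_scaffold <- function(config) {
  br <- config$bin_rate
  ep <- list()
  trials <- list()
  add <- function(label, start, end) {
    ep[[length(ep) + 1]] <<- data.frame(label = label, start = start,
                                        end = end, stringsAsFactors = FALSE)
  }
  t <- 0
  trial_id <- 0L
  ord <- c(passive = 0L, active = 0L)
  for (bk in config$blocks) {
    ord[bk] <- ord[bk] + 1L
    block_start <- t
    active <- bk == "active"
    for (j in seq_len(config$trials_per_block)) {
      t <- t + config$iti
      trial_id <- trial_id + 1L
      trial_start <- t
      n_refs <- draw_n_refs(config$hazard, config$refs_range)
      stims <- sample.int(config$n_stim, n_refs, replace = TRUE)
      lick <- NA_real_
      target_onset <- NA_real_
      outcome <- "CR"
      n_played <- n_refs
      if (active) {
        fa_at <- which(stats::runif(n_refs) < config$behavior$fa_rate)
        if (length(fa_at) > 0) {
          outcome <- "FA"
          n_played <- fa_at[1]
        } else {
          outcome <- if (stats::runif(1) < config$behavior$hit_rate)
            "HIT" else "MISS"
        }
      }
      ref_step <- config$ref_dur + config$isi
      for (k in seq_len(n_played)) {
        on <- trial_start + (k - 1) * ref_step
        add(sprintf("REFERENCE:%02d", stims[k]), on, on + config$ref_dur)
      }
      last_ref_end <- trial_start + (n_played - 1) * ref_step + config$ref_dur
      if (outcome == "FA") {
        # early lick in the scoring window after the offending reference
        u <- grid_snap(stats::runif(1, 0.1, 0.5), br)
        lick <- last_ref_end + u
        add("LICK", lick, lick + 1 / br)
        trial_end <- lick + 1 / br
      } else {
        target_onset <- last_ref_end + config$isi
        add("TARGET", target_onset, target_onset + config$target_dur)
        if (outcome == "HIT") {
          u <- grid_snap(stats::runif(1, 0.15, 1.0), br)
          lick <- target_onset + u
          add("LICK", lick, lick + 1 / br)
        }
        trial_end <- target_onset + config$resp_window[2]
      }
      trial_end <- grid_snap(trial_end, br)
      add(sprintf("TRIAL:%d", trial_id), trial_start, trial_end)
      add(toupper(outcome), trial_start, trial_end)
      trials[[trial_id]] <- data.frame(
        trial = trial_id, block = paste0(ifelse(active, "A", "P"), ord[bk]),
        block_type = bk, n_refs = n_played, outcome = tolower(outcome),
        start = trial_start, end = trial_end, target_onset = target_onset,
        lick = lick, stringsAsFactors = FALSE)
      t <- trial_end
    }
    t <- grid_snap(t + config$iti, br)
    add(paste0(toupper(bk), "_BLOCK:", ord[bk]), block_start, t)
  }
  list(epochs = do.call(rbind, ep), trials = do.call(rbind, trials),
       duration = t)
}

#' Generate a synthetic pupil trace
#'
#' Slow arousal fluctuations are an Ornstein-Uhlenbeck process reverting to
#' a block-dependent baseline (larger in active blocks); each trial onset
#' adds a delayed gamma-shaped dilation transient, scaled larger in active
#' blocks. With `ou_sigma = 0` the slow component sits exactly at the block
#' baselines (deterministic limit). Strictly positive output.
#'
#' @param epochs Epochs table containing block and trial epochs.
#' @param config A [generative_config()] (its `$pupil` is used).
#' @param n_bins Output length in bins.
#' @param seed Seed, or `NULL` to draw from the current stream.
#' @return Pupil diameter per bin (arbitrary units).
#' @export
generate_pupil <- function(epochs, config, n_bins, seed = NULL) {
  gen <- function() {
    br <- config$bin_rate
    dt <- 1 / br
    pc <- config$pupil
    base <- rep(pc$passive_baseline, n_bins)
    act <- epochs[grepl("^ACTIVE_BLOCK", epochs$label), , drop = FALSE]
    for (i in seq_len(nrow(act))) {
      base[epoch_bins(act$start[i], act$end[i], br, n_bins)] <-
        pc$passive_baseline + pc$active_shift
    }
    if (pc$p2_baseline_shift != 0) {
      # sustained arousal persisting into the post-behavior passive block
      p2 <- epochs[epochs$label == "PASSIVE_BLOCK:2", , drop = FALSE]
      for (i in seq_len(nrow(p2))) {
        base[epoch_bins(p2$start[i], p2$end[i], br, n_bins)] <-
          pc$passive_baseline + pc$p2_baseline_shift
      }
    }
    if (pc$ou_sigma == 0) {
      slow <- base
    } else {
      slow <- numeric(n_bins)
      slow[1] <- base[1]
      a <- dt / pc$ou_tau
      z <- stats::rnorm(n_bins - 1, sd = pc$ou_sigma * sqrt(2 * a))
      for (i in 2:n_bins) {
        slow[i] <- slow[i - 1] + (base[i] - slow[i - 1]) * a + z[i - 1]
      }
    }
    kern_t <- seq(0, 6, by = dt)
    sh <- pc$dilation_shape
    kern <- (kern_t / pc$dilation_peak)^sh * exp(sh * (1 - kern_t / pc$dilation_peak))
    dil <- numeric(n_bins)
    tr <- epochs[grepl("^TRIAL:", epochs$label), , drop = FALSE]
    act_rng <- act[, c("start", "end"), drop = FALSE]
    for (i in seq_len(nrow(tr))) {
      in_active <- nrow(act_rng) > 0 &&
        any(act_rng$start <= tr$start[i] & act_rng$end > tr$start[i])
      amp <- if (in_active) pc$dilation_amp_active else pc$dilation_amp_passive
      if (amp == 0) next
      b0 <- epoch_bins(tr$start[i], tr$start[i] + dt, br, n_bins)[1]
      if (is.na(b0)) next
      idx <- b0:min(n_bins, b0 + length(kern) - 1)
      dil[idx] <- dil[idx] + amp * kern[seq_along(idx)]
    }
    pmax(slow + dil, 1e-3)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# smooth positive PSTH shapes for one unit: Gaussian bump + sustained
# component, amplitude around rate_scale; uses the current RNG stream
draw_psths <- function(n_stim, n_bins_ref, rate_scale, bin_rate) {
  tt <- (seq_len(n_bins_ref) - 0.5) / bin_rate
  psth <- matrix(0, n_stim, n_bins_ref)
  for (s in seq_len(n_stim)) {
    amp <- rate_scale * stats::runif(1, 0.5, 1.5)
    tp <- stats::runif(1, 0.08, 0.45)
    w <- stats::runif(1, 0.05, 0.2)
    sus <- stats::runif(1, 0.1, 0.4)
    psth[s, ] <- amp * (exp(-(tt - tp)^2 / (2 * w^2)) + sus)
  }
  rownames(psth) <- sprintf("%02d", seq_len(n_stim))
  psth
}

#' Generate a synthetic session with stored ground truth
#'
#' Builds the epoch scaffold (flat-hazard trial lengths, 0.75 s references,
#' 0.7 s gaps, target and outcome per active trial at configured hit/FA
#' rates), the pupil trace, and per-unit firing: the noiseless rate is the
#' state-model forward pass ([evaluate_state_model()]) with the unit's true
#' coefficients applied to the stimulus PSTH and spontaneous rate, using
#' the same lagged max-normalized pupil regressor the analysis will use;
#' observed rates add the configured count noise.
#'
#' @param config A [generative_config()].
#' @param seed Integer seed; identical seeds give identical sessions.
#' @param session_id Session/site id stored in metadata.
#' @return List with `session` (a `Session`) and `truth` (class
#'   `GroundTruth`): per-unit true parameter vectors and effect types,
#'   PSTHs, `s0`, noiseless rate traces, the `p`/`b` regressor series,
#'   per-trial info, and generative MI values computed from the noiseless
#'   rates over included presentations.
#' @export
generate_session <- function(config, seed = 1, session_id = NULL) {
  stopifnot(inherits(config, "GenerativeConfig"))
  if (is.null(session_id)) session_id <- sprintf("syn-%05d", seed)
  with_seed(seed, {
    sc <- generate_epochs_scaffold(config)
    br <- config$bin_rate
    n_bins <- snap_int(sc$duration * br)
    pupil <- generate_pupil(sc$epochs, config, n_bins, seed = NULL)
    p <- lag_pupil(pupil, 0.75, br) / max(pupil)
    b <- rep(0, n_bins)
    act <- sc$epochs[grepl("^ACTIVE_BLOCK", sc$epochs$label), , drop = FALSE]
    for (i in seq_len(nrow(act))) {
      b[epoch_bins(act$start[i], act$end[i], br, n_bins)] <- 1
    }
    uc <- config$units
    n_units <- uc$n
    types <- uc$effect_types
    if (is.null(types)) types <- c("task", "pupil", "both", "none")
    types <- rep_len(types, n_units)
    unit_ids <- sprintf("u%02d", seq_len(n_units))
    n_ref_bins <- snap_int(config$ref_dur * br)
    refs <- sc$epochs[grepl("^REFERENCE:", sc$epochs$label), , drop = FALSE]
    tgts <- sc$epochs[sc$epochs$label == "TARGET", , drop = FALSE]
    rate <- matrix(0, n_units, n_bins, dimnames = list(unit_ids, NULL))
    noiseless <- matrix(0, n_units, n_bins, dimnames = list(unit_ids, NULL))
    psths <- array(0, dim = c(n_units, config$n_stim, n_ref_bins),
                   dimnames = list(unit_ids, sprintf("%02d", seq_len(config$n_stim)),
                                   NULL))
    tgt_psth <- matrix(0, n_units, n_ref_bins, dimnames = list(unit_ids, NULL))
    r0_bin_all <- matrix(0, n_units, n_bins, dimnames = list(unit_ids, NULL))
    params <- matrix(0, n_units, 6,
                     dimnames = list(unit_ids, names(neutral_params())))
    for (u in seq_len(n_units)) {
      pm <- neutral_params()
      cf <- uc$coef[[types[u]]]
      pm[names(cf)] <- cf
      params[u, ] <- pm
      ps <- draw_psths(config$n_stim, n_ref_bins, uc$rate_scale, br)
      psths[u, , ] <- ps
      tgt_psth[u, ] <- draw_psths(1, n_ref_bins, uc$rate_scale, br)[1, ]
      r0_bin <- numeric(n_bins)
      for (i in seq_len(nrow(refs))) {
        sid <- as.integer(sub("^REFERENCE:", "", refs$label[i]))
        bi <- epoch_bins(refs$start[i], refs$end[i], br, n_bins)
        r0_bin[bi] <- ps[sid, seq_along(bi)]
      }
      for (i in seq_len(nrow(tgts))) {
        bi <- epoch_bins(tgts$start[i], tgts$end[i], br, n_bins)
        r0_bin[bi] <- tgt_psth[u, seq_along(bi)]
      }
      r0_bin_all[u, ] <- r0_bin
      noiseless[u, ] <- evaluate_state_model(pm, uc$s0, r0_bin, p, b,
                                             config$constants)
    }
    dt <- 1 / br
    rate <- switch(config$noise,
      none = noiseless,
      poisson = matrix(stats::rpois(length(noiseless),
                                    pmax(noiseless, 0) * dt) / dt,
                       n_units, n_bins, dimnames = dimnames(noiseless)),
      gaussian = noiseless + matrix(stats::rnorm(length(noiseless),
                                                 sd = config$gaussian_sd),
                                    n_units, n_bins,
                                    dimnames = dimnames(noiseless)))
    session <- new_session(rate, pupil, sc$epochs, bin_rate = br,
                           meta = list(session_id = session_id,
                                       animal = config$animal,
                                       area = config$area,
                                       unit_ids = unit_ids))
    truth <- structure(list(
      params = params, effect_types = stats::setNames(types, unit_ids),
      psth = psths, target_psth = tgt_psth, s0 = uc$s0,
      noiseless = noiseless, r0_bin = r0_bin_all, p = p, b = b,
      trials = sc$trials,
      config = config, seed = seed), class = "GroundTruth")
    truth$mi <- generative_mi(session, truth)
    list(session = session, truth = truth)
  })
}

# MI per unit computed from the noiseless rates over included reference
# presentations: active vs passive (AP) and large vs small pupil (LS)
generative_mi <- function(session, truth) {
  refset <- extract_reference_responses(session)
  tt <- refset$trial_table
  inc <- which(tt$included)
  lab <- label_pupil_trials(refset)
  units <- rownames(truth$noiseless)
  out <- NULL
  for (u in units) {
    mrate <- function(rows) {
      if (length(rows) == 0) return(NA_real_)
      mean(unlist(lapply(refset$pres_bins[rows], function(bn)
        truth$noiseless[u, bn])))
    }
    act <- inc[tt$block_type[inc] == "active"]
    pas <- inc[tt$block_type[inc] == "passive"]
    lg <- inc[lab[inc] == "large"]
    sm <- inc[lab[inc] == "small"]
    mi_of <- function(ra, rb) {
      if (!is.finite(ra) || !is.finite(rb)) return(NA_real_)
      compute_mi(pmax(ra, 0), pmax(rb, 0))
    }
    out <- rbind(out, data.frame(
      unit = u,
      mi_ap = mi_of(mrate(act), mrate(pas)),
      mi_ls = mi_of(mrate(lg), mrate(sm)),
      stringsAsFactors = FALSE))
  }
  out
}

#' Generate a population of synthetic recording sites
#'
#' One session per site, each with its own derived seed and with per-unit
#' effect types drawn from the configured proportions (defaults echo the
#' published prevalence pattern: roughly half the units state-independent,
#' task-only effects more common than pupil-only).
#'
#' @param n_sites Number of sites/sessions.
#' @param config Base [generative_config()] applied to every site.
#' @param proportions Named numeric `c(task=,pupil=,both=,none=)` mixing
#'   weights for unit effect types.
#' @param seed Master seed; site seeds are derived from it.
#' @return List of `list(session, truth)` per site.
#' @export
generate_population <- function(n_sites, config = generative_config(),
                                proportions = c(task = 0.30, pupil = 0.12,
                                                both = 0.10, none = 0.48),
                                seed = 1) {
  proportions <- proportions / sum(proportions)
  with_seed(seed, {
    site_seeds <- sample.int(2^31 - 2, n_sites)
    lapply(seq_len(n_sites), function(i) {
      cfg <- config
      cfg$units$effect_types <- sample(names(proportions), cfg$units$n,
                                       replace = TRUE, prob = proportions)
      generate_session(cfg, seed = site_seeds[i],
                       session_id = sprintf("site%03d", i))
    })
  })
}

#' Ground-truth reference set for parameter-recovery fits
#'
#' Packages a unit's generative PSTHs and spontaneous rate in the
#' `refset_fixed` form accepted by [fit_state_model()]. Fitting with the
#' true `r0`/`s0` is the controlled setting in which the state
#' coefficients are identifiable: when `r0` is re-estimated from
#' state-modulated data, the PSTH absorbs part of the average state effect
#' and the generative coefficients are no longer the optimum.
#'
#' @param truth A `GroundTruth` from [generate_session()].
#' @param unit Unit id.
#' @return List `(r0, s0)` with `r0` a stimulus x time matrix.
#' @export
truth_refset <- function(truth, unit) {
  r0 <- truth$psth[unit, , ]
  list(r0 = r0, s0 = truth$s0)
}
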