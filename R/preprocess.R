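#' Lag a pupil trace relative to neural activity
#'
#' Pupil size follows neural state changes with a delay; a 750 ms offset is
#' applied before pupil is used as a regressor. The trace is shifted forward
#' by `lag` seconds and the initial samples are filled by holding the first
#' value so all signals keep equal length.
#'
#' @param pupil Numeric time series.
#' @param lag Lag in seconds; must be a non-negative multiple of the bin
#'   width. Default 0.75.
#' @param bin_rate Bins per second (default 20).
#' @return Lagged series, same length: `out[i] = pupil[i - lag*bin_rate]`.
#' @export
lag_pupil <- function(pupil, lag = 0.75, bin_rate = 20) {
  if (lag < 0) stop("lag must be non-negative")
  k <- lag * bin_rate
  if (abs(k - round(k)) > 1e-6) {
    stop("lag (", lag, " s) is not a multiple of the bin width (",
         1 / bin_rate, " s)")
  }
  k <- as.integer(round(k))
  if (k == 0) return(pupil)
  n <- length(pupil)
  c(rep(pupil[1], k), pupil[seq_len(n - k)])
}

#' Extract reference responses and spontaneous rate from a session
#'
#' Builds the empirical inputs of the state model: per-stimulus PSTHs
#' `r0` averaged across included reference presentations, and the
#' spontaneous rate `s0` estimated from silence. A presentation is included
#' iff it occurs in a passive trial or an active hit trial and does not
#' overlap any `TARGET` epoch; active miss and false-alarm trials are
#' excluded so that behavioral errors and reward events do not contaminate
#' the sensory average.
#'
#' Spontaneous rate is the mean rate over 0.35 s pre-trial windows plus
#' inter-stimulus gaps, excluding the first 0.2 s after each stimulus offset
#' to avoid offset responses (window lengths configurable).
#'
#' @param session A `Session`.
#' @param pre_trial_window Pre-trial silence window in s (default 0.35).
#' @param offset_exclude Post-stimulus-offset exclusion in s (default 0.2).
#' @return An object of class `ReferenceResponseSet`: list with
#'   \describe{
#'     \item{trial_table}{one row per reference presentation: `pres`, `trial`,
#'       `stim`, `block`, `block_type`, `outcome`, `start`, `end`,
#'       `mean_pupil`, `included`, `reason`, `fold` placeholder}
#'     \item{r0}{array units x stimulus x time-in-stimulus (spikes/s)}
#'     \item{s0}{spontaneous rate per unit (spikes/s)}
#'     \item{pres_bins}{list of bin-index vectors per presentation}
#'     \item{s0_bins, s0_trial}{silence bin indices and their trial ids}
#'     \item{n_ref_bins}{bins per 0.75 s reference presentation}
#'   }
#' @export
extract_reference_responses <- function(session, pre_trial_window = 0.35,
                                        offset_exclude = 0.2) {
  ep <- session$epochs
  br <- session$bin_rate
  n <- ncol(session$rate)
  refs <- ep[grepl("^REFERENCE:", ep$label), , drop = FALSE]
  refs <- refs[order(refs$start), , drop = FALSE]
  if (nrow(refs) == 0) stop("session contains no REFERENCE epochs")
  trials <- ep[grepl("^TRIAL:", ep$label), , drop = FALSE]
  trials <- trials[order(trials$start), , drop = FALSE]
  outs <- ep[ep$label %in% outcome_labels(), , drop = FALSE]
  targets <- ep[ep$label == "TARGET", , drop = FALSE]
  blocks <- block_epochs(ep)
  blocks <- blocks[order(blocks$start), , drop = FALSE]

  locate <- function(t, tab) {
    i <- which(tab$start <= t + 1e-9 & tab$end > t + 1e-9)
    if (length(i) == 0) NA_integer_ else i[1]
  }
  n_ref_bins <- length(epoch_bins(refs$start[1], refs$end[1], br, n))

  tt <- data.frame(pres = seq_len(nrow(refs)), stringsAsFactors = FALSE)
  tt$start <- refs$start
  tt$end <- refs$end
  tt$stim <- sub("^REFERENCE:", "", refs$label)
  pres_bins <- vector("list", nrow(refs))
  for (i in seq_len(nrow(refs))) {
    bi <- epoch_bins(refs$start[i], refs$end[i], br, n)
    # pad/trim to the common presentation length at the session edge
    pres_bins[[i]] <- bi[seq_len(min(length(bi), n_ref_bins))]
  }
  ti <- vapply(tt$start, locate, integer(1), tab = trials)
  tt$trial <- ifelse(is.na(ti), NA_character_, sub("^TRIAL:", "", trials$label[ti]))
  bi <- vapply(tt$start, locate, integer(1), tab = blocks)
  blab <- blocks$label[bi]
  tt$block_type <- ifelse(grepl("^ACTIVE", blab), "active", "passive")
  ord <- sub("^.*_BLOCK:", "", blab)
  tt$block <- paste0(ifelse(tt$block_type == "active", "A", "P"), ord)
  oi <- vapply(tt$start, locate, integer(1), tab = outs)
  tt$outcome <- tolower(outs$label[oi])

  overlaps_target <- function(s, e) {
    any(targets$start < e - 1e-9 & targets$end > s + 1e-9)
  }
  tt$included <- TRUE
  tt$reason <- ""
  for (i in seq_len(nrow(tt))) {
    if (tt$block_type[i] == "active" && tt$outcome[i] != "hit") {
      tt$included[i] <- FALSE
      tt$reason[i] <- paste0("active ", tt$outcome[i], " trial")
    } else if (nrow(targets) > 0 && overlaps_target(tt$start[i], tt$end[i])) {
      tt$included[i] <- FALSE
      tt$reason[i] <- "overlaps target"
    }
  }
  tt$mean_pupil <- vapply(pres_bins, function(b) mean(session$pupil[b]), numeric(1))

  # silence bins: pre-trial windows + inter-stimulus gaps minus offset skirts
  sil_bins <- integer(0)
  sil_trial <- character(0)
  for (j in seq_len(nrow(trials))) {
    tid <- sub("^TRIAL:", "", trials$label[j])
    segs <- list(c(trials$start[j] - pre_trial_window, trials$start[j]))
    tr_refs <- which(!is.na(tt$trial) & tt$trial == tid)
    tr_refs <- tr_refs[order(tt$start[tr_refs])]
    if (length(tr_refs) > 1) {
      for (k in seq_len(length(tr_refs) - 1)) {
        segs <- c(segs, list(c(tt$end[tr_refs[k]] + offset_exclude,
                               tt$start[tr_refs[k + 1]])))
      }
    }
    for (sg in segs) {
      if (sg[2] <= sg[1]) next
      b <- epoch_bins(sg[1], sg[2], br, n)
      # drop anything overlapping a stimulus (pre-trial window of trial j+1
      # can never reach into trial j's sounds by construction, but be safe)
      if (nrow(targets) > 0) {
        tb <- unlist(lapply(seq_len(nrow(targets)), function(q)
          epoch_bins(targets$start[q], targets$end[q], br, n)))
        b <- setdiff(b, tb)
      }
      sil_bins <- c(sil_bins, b)
      sil_trial <- c(sil_trial, rep(tid, length(b)))
    }
  }
  keep <- !duplicated(sil_bins)
  sil_bins <- sil_bins[keep]
  sil_trial <- sil_trial[keep]

  stims <- sort(unique(tt$stim))
  units <- rownames(session$rate)
  r0 <- array(NA_real_, dim = c(length(units), length(stims), n_ref_bins),
              dimnames = list(units, stims, NULL))
  for (s in stims) {
    idx <- which(tt$stim == s & tt$included)
    if (length(idx) == 0) {
      warning("stimulus ", s, " has no included presentations; excluded from r0")
      next
    }
    acc <- matrix(0, length(units), n_ref_bins)
    for (i in idx) {
      b <- pres_bins[[i]]
      acc[, seq_along(b)] <- acc[, seq_along(b)] +
        session$rate[, b, drop = FALSE]
    }
    r0[, s, ] <- acc / length(idx)
  }
  s0 <- if (length(sil_bins) > 0) {
    rowMeans(session$rate[, sil_bins, drop = FALSE])
  } else {
    rep(0, length(units))
  }
  names(s0) <- units

  structure(list(trial_table = tt, r0 = r0, s0 = s0, pres_bins = pres_bins,
                 s0_bins = sil_bins, s0_trial = sil_trial,
                 n_ref_bins = n_ref_bins, units = units, stims = stims,
                 bin_rate = br),
            class = "ReferenceResponseSet")
}

#' Label reference presentations by pupil state
#'
#' Splits presentations at the median of per-presentation mean pupil
#' diameter (median taken over included presentations): above the median is
#' `large` (high arousal), at or below is `small` (ties to `small`, a
#' deterministic documented rule).
#'
#' @param refset A [extract_reference_responses()] result.
#' @return Character vector, one label per presentation row of
#'   `trial_table`, in `{"large","small"}`.
#' @export
label_pupil_trials <- function(refset) {
  mp <- refset$trial_table$mean_pupil
  inc <- refset$trial_table$included
  if (all(!is.finite(mp[inc]))) stop("mean pupil undefined for included presentations")
  med <- stats::median(mp[inc])
  if (isTRUE(all(mp[inc] == med))) {
    warning("constant pupil: all presentations labeled 'small'")
    return(rep("small", length(mp)))
  }
  ifelse(mp > med, "large", "small")
}
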