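#' Score a single go/no-go trial
#'
#' Licks within the response window, 0.1-1.5 s after target onset, count as
#' hits; a lick before that window is a false alarm; no lick with a target
#' presented is a miss. A lick after the window end with no earlier lick is
#' scored a miss (documented convention).
#'
#' @param first_lick Time of the first lick (s, session clock) or `NA`.
#' @param target_onset Target onset time (s) or `NA`; may be absent only for
#'   trials terminated by an early lick.
#' @param window Response window relative to target onset (default
#'   `c(0.1, 1.5)`).
#' @return One of `"hit"`, `"miss"`, `"FA"`, `"CR"`.
#' @export
score_trial <- function(first_lick, target_onset, window = c(0.1, 1.5)) {
  no_lick <- is.null(first_lick) || is.na(first_lick)
  no_tgt <- is.null(target_onset) || is.na(target_onset)
  if (no_lick && no_tgt) {
    stop("trial without target and without lick cannot be scored")
  }
  if (no_lick) return("miss")
  if (no_tgt) return("FA")
  lo <- target_onset + window[1]
  hi <- target_onset + window[2]
  if (first_lick >= lo && first_lick <= hi) return("hit")
  if (first_lick < lo) return("FA")
  "miss"
}

#' Hit rate and false-alarm rate from outcome counts
#'
#' `HR = hits/(hits+misses)`, `FAR = FAs/(FAs+CRs)`; exact ratios, no
#' clipping (clipping belongs to [compute_dprime()]).
#'
#' @param hits,misses,fas,crs Non-negative counts.
#' @return List with `hr` and `far`.
#' @export
compute_rates <- function(hits, misses, fas, crs) {
  if (hits + misses == 0) stop("no target trials (hits + misses = 0)")
  if (fas + crs == 0) stop("no reference outcomes (FAs + CRs = 0)")
  list(hr = hits / (hits + misses), far = fas / (fas + crs))
}

#' Behavioral sensitivity d-prime
#'
#' `d' = z(HR) - z(FAR)` with z the standard normal quantile. Rates are
#' clipped to `[1/(2n), 1 - 1/(2n)]` before z-scoring (n the relevant trial
#' count) so perfect rates stay finite — the standard signal-detection
#' correction.
#'
#' @param hr,far Proportions in `[0, 1]`.
#' @param n_target Number of target trials (hits + misses).
#' @param n_ref Number of reference outcomes (FAs + CRs).
#' @return d-prime (unitless). Chance performance gives 0.
#' @export
compute_dprime <- function(hr, far, n_target, n_ref) {
  stopifnot(hr >= 0, hr <= 1, far >= 0, far <= 1, n_target >= 1, n_ref >= 1)
  clip <- function(p, n) min(max(p, 1 / (2 * n)), 1 - 1 / (2 * n))
  stats::qnorm(clip(hr, n_target)) - stats::qnorm(clip(far, n_ref))
}

#' Per-block behavioral summary for a session
#'
#' Scores every active block of a session from its epochs: hits/misses/FAs
#' from the per-trial outcome labels, and one correct rejection per
#' completed, un-licked reference presentation (so FAR is the proportion of
#' reference stimuli that elicited a lick). Passive blocks carry no
#' behavioral report and are skipped.
#'
#' @param session A `Session`.
#' @return Data frame: `session`, `block`, `hits`, `misses`, `fas`, `crs`,
#'   `hr`, `far`, `dprime` (one row per active block).
#' @export
behavior_summary <- function(session) {
  ep <- session$epochs
  blocks <- block_epochs(ep)
  blocks <- blocks[grepl("^ACTIVE", blocks$label), , drop = FALSE]
  trials <- ep[grepl("^TRIAL:", ep$label), , drop = FALSE]
  outs <- ep[ep$label %in% outcome_labels(), , drop = FALSE]
  refs <- ep[grepl("^REFERENCE:", ep$label), , drop = FALSE]
  res <- NULL
  for (i in seq_len(nrow(blocks))) {
    b0 <- blocks$start[i]; b1 <- blocks$end[i]
    tr <- trials[trials$start >= b0 - 1e-9 & trials$start < b1 - 1e-9, , drop = FALSE]
    oc <- character(nrow(tr))
    n_refs <- 0L
    for (j in seq_len(nrow(tr))) {
      o <- outs[outs$start < tr$end[j] - 1e-9 & outs$end > tr$start[j] + 1e-9, ]
      oc[j] <- o$label[1]
      n_refs <- n_refs + sum(refs$start >= tr$start[j] - 1e-9 &
                               refs$start < tr$end[j] - 1e-9)
    }
    hits <- sum(oc == "HIT"); misses <- sum(oc == "MISS"); fas <- sum(oc == "FA")
    crs <- n_refs - fas  # the licked reference of each FA trial is the FA
    rates <- compute_rates(hits, misses, fas, crs)
    res <- rbind(res, data.frame(
      session = session$meta$session_id,
      block = paste0("A", sub("^ACTIVE_BLOCK:", "", blocks$label[i])),
      hits = hits, misses = misses, fas = fas, crs = crs,
      hr = rates$hr, far = rates$far,
      dprime = compute_dprime(rates$hr, rates$far, hits + misses, fas + crs),
      stringsAsFactors = FALSE))
  }
  res
}
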