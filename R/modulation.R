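#' Modulation index between two conditions
#'
#' `MI = (a - b) / (a + b)` for mean evoked rates `a`, `b` (means over the
#' 0.75 s stimulus windows of presentations in each condition). Rates must
#' be non-negative (model predictions are rectified at 0 upstream), which
#' bounds MI in `[-1, 1]`. Defined as 0 when both rates are 0.
#'
#' @param rate_a,rate_b Non-negative mean rates (vectorized).
#' @return MI in `[-1, 1]`.
#' @export
compute_mi <- function(rate_a, rate_b) {
  if (any(rate_a < 0) || any(rate_b < 0)) {
    stop("negative rate passed to compute_mi; rectify predictions first")
  }
  s <- rate_a + rate_b
  out <- ifelse(s == 0, 0, (rate_a - rate_b) / ifelse(s == 0, 1, s))
  out
}

# mean rectified predicted rate over the bins of a set of presentations
condition_mean_rate <- function(pred, mdata, pres_ids) {
  keep <- mdata$pres %in% pres_ids
  if (!any(keep)) return(NA_real_)
  mean(pmax(pred[keep], 0))
}

#' Decompose a modulation index into unique state components
#'
#' Computes the MI between two condition classes from the (rectified)
#' held-out predictions of the full model and of both partial models, then
#' isolates what each state variable uniquely predicts by subtraction:
#' `task_unique = full - pupil_only` (modulation predicted by task
#' engagement above and beyond pupil) and `pupil_unique = full - task_only`.
#'
#' @param preds Named list of per-bin predictions: `full`, `task_only`,
#'   `pupil_only` (identical bins).
#' @param mdata The [build_model_data()] object the predictions cover.
#' @param mask_a Logical per row of `mdata$trial_table`: condition alpha
#'   (e.g. active, or large pupil).
#' @param pair Label for the condition pair (`"AP"`, `"LS"`, `"P1P2"`).
#' @return A one-row data frame of class `ModulationResult`: `pair`,
#'   `mi_full`, `mi_task_only`, `mi_pupil_only`, `mi_task_unique`,
#'   `mi_pupil_unique`.
#' @export
mi_decomposition <- function(preds, mdata, mask_a, pair = "AP") {
  tt <- mdata$trial_table
  stopifnot(length(mask_a) == nrow(tt))
  pa <- tt$pres[mask_a]
  pb <- tt$pres[!mask_a]
  if (length(pa) == 0 || length(pb) == 0) {
    warning("empty condition class for pair ", pair, "; MI undefined")
    return(structure(data.frame(pair = pair, mi_full = NA_real_,
                                mi_task_only = NA_real_,
                                mi_pupil_only = NA_real_,
                                mi_task_unique = NA_real_,
                                mi_pupil_unique = NA_real_),
                     class = c("ModulationResult", "data.frame")))
  }
  mi <- vapply(preds[c("full", "task_only", "pupil_only")], function(pr) {
    compute_mi(condition_mean_rate(pr, mdata, pa),
               condition_mean_rate(pr, mdata, pb))
  }, numeric(1))
  structure(data.frame(
    pair = pair,
    mi_full = mi[["full"]],
    mi_task_only = mi[["task_only"]],
    mi_pupil_only = mi[["pupil_only"]],
    mi_task_unique = mi[["full"]] - mi[["pupil_only"]],
    mi_pupil_unique = mi[["full"]] - mi[["task_only"]]),
    class = c("ModulationResult", "data.frame"))
}

#' Sign-normalized population MI reduction
#'
#' For each unit, both paired MI values (e.g. task-only and task-unique)
#' are multiplied by the sign of their mean, so that population magnitude
#' comparisons are direction-agnostic. The percent reduction is
#' `1 - mean(normalized unique) / mean(normalized only)`: how much of the
#' apparent condition modulation disappears once the other state variable
#' is accounted for. A pair mean of exactly 0 takes sign +1 (documented
#' tie rule).
#'
#' @param mi_only Per-unit MI from the single-variable model.
#' @param mi_unique Per-unit unique MI (full minus other-variable partial).
#' @return List: `normalized` (data frame `only`, `unique`, `sign`),
#'   `mean_only`, `mean_unique`, `reduction` (fraction, e.g. 0.33 = 33%).
#' @export
sign_normalized_reduction <- function(mi_only, mi_unique) {
  stopifnot(length(mi_only) == length(mi_unique))
  s <- sign((mi_only + mi_unique) / 2)
  s[s == 0] <- 1
  no <- s * mi_only
  nu <- s * mi_unique
  m_only <- mean(no)
  m_unique <- mean(nu)
  list(normalized = data.frame(only = no, unique = nu, sign = s),
       mean_only = m_only, mean_unique = m_unique,
       reduction = 1 - m_unique / m_only)
}

#' Persistence analysis across pre- and post-behavior passive blocks
#'
#' Tests whether rate changes that persist from the first (P1) into the
#' second (P2) passive block reflect lasting plasticity or simply a pupil
#' state that has not returned to baseline. The state model is refit on
#' passive presentations only, with the task regressor replaced by a
#' P2-block indicator: `MI_P1P2 block-only` comes from the model with pupil
#' shuffled, and `block_unique = full - pupil_only` is what block identity
#' predicts above pupil.
#'
#' @param mdata A [build_model_data()] object (full session).
#' @param unit Unit id.
#' @param n_folds,constants,seed As in [fit_state_model()].
#' @return A `ModulationResult` row with pair `"P1P2"` where
#'   `mi_task_only`/`mi_task_unique` hold the block-only and block-unique
#'   values, or `NULL` (with a warning) when no post-behavior passive block
#'   exists.
#' @export
p1p2_analysis <- function(mdata, unit, n_folds = 20,
                          constants = sigmoid_constants(), seed = 1) {
  tt <- mdata$trial_table
  pass <- tt$block_type == "passive"
  blocks <- unique(tt$block[pass])
  if (!all(c("P1", "P2") %in% blocks)) {
    warning("session lacks a P2 passive block; P1/P2 analysis skipped")
    return(NULL)
  }
  keep_pres <- tt$pres[pass & tt$block %in% c("P1", "P2")]
  keep <- mdata$pres %in% keep_pres
  sub <- mdata
  sub$y <- mdata$y[, keep, drop = FALSE]
  sub$p <- mdata$p[keep]
  sub$stim <- mdata$stim[keep]
  sub$tbin <- mdata$tbin[keep]
  sub$pres <- mdata$pres[keep]
  sub$trial <- mdata$trial[keep]
  sub$trial_table <- tt[tt$pres %in% keep_pres, , drop = FALSE]
  # block regressor in place of task engagement: 1 in P2, 0 in P1
  blk_of_pres <- tt$block[match(sub$pres, tt$pres)]
  sub$b <- as.integer(blk_of_pres == "P2")
  fits <- lapply(c("full", "task_only", "pupil_only"), function(ms)
    fit_state_model(sub, unit, ms, n_folds = n_folds, constants = constants,
                    seed = seed))
  names(fits) <- c("full", "task_only", "pupil_only")
  preds <- lapply(fits, `[[`, "prediction")
  res <- mi_decomposition(preds, sub,
                          mask_a = sub$trial_table$block == "P2",
                          pair = "P1P2")
  res
}
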