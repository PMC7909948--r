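#' Analyze one session end to end
#'
#' Runs the complete per-session analysis: reference-response extraction,
#' behavioral scoring, per-unit model fitting with all shuffle controls,
#' unique-variance attribution and classification, and the modulation-index
#' decomposition for the active/passive and large/small-pupil condition
#' pairs (plus, when the session has a post-behavior passive block, the
#' P1/P2 persistence analysis).
#'
#' @param session A `Session`.
#' @param n_folds Cross-validation folds (default 20).
#' @param constants [sigmoid_constants()].
#' @param seed Seed for shuffles/restarts.
#' @param alpha Significance level for classification.
#' @param p1p2 Run the P1/P2 persistence analysis (default TRUE when a P2
#'   block exists)?
#' @return List: `units` (per-unit results table: r2 values, unique
#'   variances, p-values, category), `mi` (per-unit MI decomposition rows
#'   for AP/LS and optionally P1P2), `behavior` (per-block summary),
#'   `evals` (the `ModelEvaluation` objects).
#' @export
analyze_session <- function(session, n_folds = 20,
                            constants = sigmoid_constants(), seed = 1,
                            alpha = 0.05, p1p2 = TRUE) {
  refset <- extract_reference_responses(session)
  mdata <- build_model_data(session, refset)
  plab <- label_pupil_trials(refset)
  plab_inc <- plab[refset$trial_table$included]
  has_p2 <- p1p2 && all(c("P1", "P2") %in%
                          refset$trial_table$block[refset$trial_table$included])
  units_tab <- NULL
  mi_tab <- NULL
  evals <- list()
  for (u in mdata$units) {
    ev <- evaluate_unit(mdata, u, n_folds = n_folds, constants = constants,
                        seed = seed, alpha = alpha)
    evals[[u]] <- ev
    units_tab <- rbind(units_tab, data.frame(
      session = session$meta$session_id, unit = u,
      area = session$meta$area %||% NA_character_,
      r2_null = ev$r2_null, r2_full = ev$r2_full,
      r2_task_only = ev$r2_task_only, r2_pupil_only = ev$r2_pupil_only,
      r2_task_unique = ev$r2_task_unique,
      r2_pupil_unique = ev$r2_pupil_unique,
      p_state = ev$p_state, p_task_unique = ev$p_task_unique,
      p_pupil_unique = ev$p_pupil_unique, category = ev$category,
      stringsAsFactors = FALSE))
    preds <- lapply(ev$fits, `[[`, "prediction")
    mi_ap <- mi_decomposition(preds, mdata,
                              mask_a = mdata$trial_table$block_type == "active",
                              pair = "AP")
    mi_ls <- mi_decomposition(preds, mdata,
                              mask_a = plab_inc == "large", pair = "LS")
    rows <- rbind(as.data.frame(mi_ap), as.data.frame(mi_ls))
    if (has_p2) {
      mi_p <- p1p2_analysis(mdata, u, n_folds = n_folds,
                            constants = constants, seed = seed)
      if (!is.null(mi_p)) rows <- rbind(rows, as.data.frame(mi_p))
    }
    rows <- cbind(session = session$meta$session_id, unit = u, rows,
                  stringsAsFactors = FALSE)
    mi_tab <- rbind(mi_tab, rows)
  }
  list(units = units_tab, mi = mi_tab,
       behavior = behavior_summary(session), evals = evals)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analyze a population of sessions
#'
#' Applies [analyze_session()] to every session and row-binds the result
#' tables; deterministic given the seed.
#'
#' @param sessions List of `Session` objects (or of `list(session, truth)`
#'   pairs as returned by [generate_population()]).
#' @inheritParams analyze_session
#' @return List of combined tables `units`, `mi`, `behavior`.
#' @export
analyze_population <- function(sessions, n_folds = 20,
                               constants = sigmoid_constants(), seed = 1,
                               alpha = 0.05, p1p2 = FALSE) {
  units_tab <- mi_tab <- beh_tab <- NULL
  for (s in sessions) {
    ses <- if (inherits(s, "Session")) s else s$session
    res <- analyze_session(ses, n_folds = n_folds, constants = constants,
                           seed = seed, alpha = alpha, p1p2 = p1p2)
    units_tab <- rbind(units_tab, res$units)
    mi_tab <- rbind(mi_tab, res$mi)
    beh_tab <- rbind(beh_tab, res$behavior)
  }
  list(units = units_tab, mi = mi_tab, behavior = beh_tab)
}
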