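#' Construct a recording session
#'
#' A `Session` bundles the three things every downstream analysis consumes:
#' per-unit firing rates and pupil diameter on one common bin grid
#' (20 samples/s by default), and an epochs table marking behavior blocks,
#' trials, sound events and trial outcomes on the session clock.
#'
#' Epoch labels come from a controlled vocabulary:
#' `PASSIVE_BLOCK:k` / `ACTIVE_BLOCK:k` (ordinal k per block type, so the
#' first passive block is P1, the second P2), `TRIAL:i`, `REFERENCE:s`
#' (reference sound s, always 0.75 s), `TARGET`, `LICK`, and one outcome
#' epoch per trial spanning the trial: `HIT`, `MISS`, `FA` or `CR`.
#' All epochs are half-open `[start, end)` in seconds; a bin belongs to an
#' epoch iff its left edge lies in the interval.
#'
#' @param rate Numeric matrix, units x time bins, firing rate in spikes/s.
#' @param pupil Numeric vector of pupil diameter (arbitrary units), same
#'   bin grid and length as `ncol(rate)`.
#' @param epochs Data frame with columns `label`, `start`, `end` (seconds).
#' @param bin_rate Bins per second (default 20).
#' @param meta List with at least `session_id`; optionally `animal`, `area`
#'   (e.g. "A1", "ICC", "NCIC") and `unit_ids`.
#' @param validate Run [validate_session()] before returning?
#' @return An object of class `Session`.
#' @seealso [save_session()], [load_session()], [extract_reference_responses()]
#' @export
new_session <- function(rate, pupil, epochs, bin_rate = 20, meta = list(),
                        validate = TRUE) {
  rate <- as.matrix(rate)
  if (is.null(rownames(rate))) {
    rownames(rate) <- sprintf("u%02d", seq_len(nrow(rate)))
  }
  if (is.null(meta$unit_ids)) meta$unit_ids <- rownames(rate)
  if (is.null(meta$session_id)) meta$session_id <- "session"
  s <- structure(
    list(rate = rate, pupil = as.numeric(pupil),
         epochs = as.data.frame(epochs, stringsAsFactors = FALSE),
         bin_rate = bin_rate, meta = meta),
    class = "Session")
  if (validate) validate_session(s)
  s
}

#' @export
print.Session <- function(x, ...) {
  cat(sprintf("Session '%s': %d units x %d bins (%.1f s at %d Hz), %d epochs\n",
              x$meta$session_id, nrow(x$rate), ncol(x$rate),
              ncol(x$rate) / x$bin_rate, x$bin_rate, nrow(x$epochs)))
  invisible(x)
}

block_epochs <- function(epochs) {
  epochs[grepl("^(PASSIVE|ACTIVE)_BLOCK", epochs$label), , drop = FALSE]
}

outcome_labels <- function() c("HIT", "MISS", "FA", "CR")

#' Validate a session against its invariants
#'
#' Checks that all signals share one bin grid and length, that every epoch
#' lies within the signal extent, that block epochs tile the session without
#' overlap, and that every trial carries exactly one outcome label.
#'
#' @param session A [new_session()] object.
#' @return Invisibly `TRUE`; otherwise an error describing the violation.
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "Session"))
  n <- ncol(session$rate)
  if (length(session$pupil) != n) {
    stop("validation error: pupil length (", length(session$pupil),
         ") != rate bins (", n, ")")
  }
  dur <- n / session$bin_rate
  ep <- session$epochs
  if (!all(c("label", "start", "end") %in% names(ep))) {
    stop("validation error: epochs table must have columns label,start,end")
  }
  if (any(ep$start > ep$end)) stop("validation error: epoch with start > end")
  if (any(ep$start < -1e-9) || any(ep$end > dur + 1e-9)) {
    bad <- ep[ep$start < -1e-9 | ep$end > dur + 1e-9, ]
    stop("validation error: epoch outside signal extent: ",
         bad$label[1], " [", bad$start[1], ", ", bad$end[1], ") vs duration ", dur)
  }
  bl <- block_epochs(ep)
  if (nrow(bl) > 1) {
    bl <- bl[order(bl$start), ]
    gaps <- bl$start[-1] - bl$end[-nrow(bl)]
    if (any(abs(gaps) > 1e-6)) {
      stop("validation error: block epochs do not tile the session (gap/overlap of ",
           max(abs(gaps)), " s)")
    }
  }
  tr <- ep[grepl("^TRIAL:", ep$label), , drop = FALSE]
  out <- ep[ep$label %in% outcome_labels(), , drop = FALSE]
  if (nrow(tr) > 0) {
    for (i in seq_len(nrow(tr))) {
      hit <- sum(out$start < tr$end[i] - 1e-9 & out$end > tr$start[i] + 1e-9)
      if (hit != 1) {
        stop("validation error: trial ", tr$label[i], " carries ", hit,
             " outcome labels (expected exactly 1)")
      }
    }
  }
  invisible(TRUE)
}

fmt_full <- function(x) sprintf("%.17g", x)

#' Save a session to a directory container
#'
#' Writes the documented plain-text container: `rate.csv` (one row per unit,
#' first column the unit id, values at full double precision so the
#' save/load round trip is bitwise exact), `pupil.csv`, `epochs.csv`
#' (`label,start,end`, seconds to 6 decimal places) and `meta.json`.
#'
#' @param session A `Session`.
#' @param path Directory to create/write into.
#' @return Invisibly, `path`.
#' @export
save_session <- function(session, path) {
  stopifnot(inherits(session, "Session"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  rt <- session$rate
  lines <- c(paste(c("unit", paste0("b", seq_len(ncol(rt)))), collapse = ","),
             vapply(seq_len(nrow(rt)), function(i) {
               paste(c(rownames(rt)[i], fmt_full(rt[i, ])), collapse = ",")
             }, character(1)))
  writeLines(lines, file.path(path, "rate.csv"))
  writeLines(c("pupil", fmt_full(session$pupil)), file.path(path, "pupil.csv"))
  ep <- session$epochs
  writeLines(c("label,start,end",
               sprintf("%s,%.6f,%.6f", ep$label, ep$start, ep$end)),
             file.path(path, "epochs.csv"))
  meta <- session$meta
  meta$bin_rate <- session$bin_rate
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a session from a directory container
#'
#' Inverse of [save_session()]; validates the result.
#'
#' @param path Directory written by [save_session()].
#' @return A `Session`.
#' @export
load_session <- function(path) {
  need <- c("rate.csv", "pupil.csv", "epochs.csv", "meta.json")
  for (f in need) {
    if (!file.exists(file.path(path, f))) {
      stop("format error: session container at '", path,
           "' is missing required file '", f, "'")
    }
  }
  rt <- utils::read.csv(file.path(path, "rate.csv"), check.names = FALSE,
                        colClasses = "character")
  units <- rt[[1]]
  rate <- as.matrix(vapply(rt[-1], as.numeric, numeric(nrow(rt))))
  if (nrow(rt) == 1) rate <- matrix(rate, nrow = 1)
  dimnames(rate) <- list(units, NULL)
  pupil <- utils::read.csv(file.path(path, "pupil.csv"))$pupil
  epochs <- utils::read.csv(file.path(path, "epochs.csv"),
                            stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  bin_rate <- meta$bin_rate
  if (is.null(bin_rate)) stop("format error: meta.json is missing 'bin_rate'")
  bin_rate <- as.numeric(bin_rate)
  meta$bin_rate <- NULL
  new_session(rate, pupil, epochs, bin_rate = bin_rate, meta = as.list(meta))
}
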