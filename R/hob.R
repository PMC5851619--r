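#' Head-of-bed protocol definition
#'
#' Ordered stage timetable for the orthostatic challenge. The default is the
#' supine (0 deg, 5 min) -> 30 deg (5 min) -> supine (0 deg, 5 min) sequence
#' with 30-s transition gaps between stages and 60-s head/tail exclusions
#' inside each stage (first and last minute discarded to avoid bed-movement
#' artifacts).
#'
#' @param stages A data.frame with columns `label`, `angle` (degrees),
#'   `start` (s), `duration` (s); stages must be ordered and non-overlapping.
#' @param transition_max Maximum transition duration between stages (s).
#' @param exclude_head,exclude_tail Per-stage exclusions (s).
#' @return An object of class `hob_protocol`.
#' @export
#' @examples
#' stage_windows(hob_protocol())
hob_protocol <- function(stages = NULL, transition_max = 30,
                         exclude_head = 60, exclude_tail = 60) {
  if (is.null(stages)) {
    stages <- data.frame(
      label = c("supine_1", "hob_30", "supine_2"),
      angle = c(0, 30, 0),
      start = c(0, 330, 660),
      duration = c(300, 300, 300)
    )
  }
  stopifnot(is.data.frame(stages),
            all(c("label", "angle", "start", "duration") %in% names(stages)),
            nrow(stages) >= 1L)
  if (any(stages$duration <= 0)) stop("stage durations must be positive", call. = FALSE)
  ends <- stages$start + stages$duration
  if (nrow(stages) > 1L) {
    gaps <- stages$start[-1L] - ends[-nrow(stages)]
    if (any(gaps < 0)) stop("stages overlap", call. = FALSE)
    if (any(gaps > transition_max))
      warning("transition gap exceeds 'transition_max'", call. = FALSE)
  }
  if (any(stages$duration <= exclude_head + exclude_tail))
    stop("stage duration must exceed exclude_head + exclude_tail", call. = FALSE)
  structure(list(stages = stages, transition_max = transition_max,
                 exclude_head = exclude_head, exclude_tail = exclude_tail),
            class = "hob_protocol")
}

#' @export
print.hob_protocol <- function(x, ...) {
  cat("Head-of-bed protocol:\n")
  print(x$stages, row.names = FALSE)
  cat(sprintf("exclusions %g s head / %g s tail, transitions <= %g s\n",
              x$exclude_head, x$exclude_tail, x$transition_max))
  invisible(x)
}

#' Per-stage analysis windows
#'
#' Applies the head/tail exclusions to each stage, yielding the intervals
#' over which BFI samples contribute to the endpoints. With the defaults,
#' each 300-s stage gives a 180-s window, e.g. `[60, 240)` for a stage at
#' `[0, 300)`.
#'
#' @param protocol A [hob_protocol()].
#' @return A data.frame with columns `label`, `angle`, `win_start`,
#'   `win_end` (window is the half-open interval `[win_start, win_end)`).
#' @export
stage_windows <- function(protocol) {
  stopifnot(inherits(protocol, "hob_protocol"))
  s <- protocol$stages
  data.frame(
    label = s$label,
    angle = s$angle,
    win_start = s$start + protocol$exclude_head,
    win_end = s$start + s$duration - protocol$exclude_tail
  )
}

#' Blood-flow-index time series
#'
#' @param t Timestamps in seconds (strictly increasing; nominally 3-s
#'   spacing).
#' @param bfi Flow index values (cm^2/s).
#' @param quality Per-sample logical mask; samples with `FALSE` (e.g.
#'   non-converged fits or negative values) are excluded from endpoints,
#'   never interpolated.
#' @return An object of class `bfi_trace`.
#' @export
bfi_trace <- function(t, bfi, quality = NULL) {
  stopifnot(is.numeric(t), is.numeric(bfi), length(t) == length(bfi))
  if (length(t) > 1L && any(diff(t) <= 0))
    stop("'t' must be strictly increasing", call. = FALSE)
  if (is.null(quality)) quality <- is.finite(bfi) & bfi >= 0
  stopifnot(is.logical(quality), length(quality) == length(t))
  quality <- quality & is.finite(bfi)
  structure(list(t = as.numeric(t), bfi = as.numeric(bfi), quality = quality),
            class = "bfi_trace")
}

#' @export
print.bfi_trace <- function(x, ...) {
  cat(sprintf("BFI trace: %d samples over [%.0f, %.0f] s (%d good), median %.3g cm^2/s\n",
              length(x$t), min(x$t), max(x$t), sum(x$quality),
              stats::median(x$bfi[x$quality])))
  invisible(x)
}

#' Relative CBF endpoints of the head-of-bed challenge
#'
#' Normalises a continuous BFI trace by the mean BFI of the initial supine
#' analysis window and averages the normalised values within each stage
#' window. Endpoints are reported as signed percent change relative to the
#' initial supine baseline:
#' * `rcbf_supine_to_30`: the 30-degree stage versus baseline;
#' * `rcbf_30_to_supine`: the final supine stage versus the *initial*
#'   supine baseline (a residual offset here means failure to recover).
#'
#' @param trace A [bfi_trace()] covering all analysis windows.
#' @param protocol A [hob_protocol()].
#' @return An object of class `rcbf_result`: list with `rcbf_supine_to_30`
#'   and `rcbf_30_to_supine` (percent), `ratios` (per-stage ratios to
#'   baseline), `baseline_mean` (cm^2/s), `n_samples` (per window), `ok`
#'   and `reason`. An empty window after quality masking yields a failure
#'   record (`ok = FALSE`), not an error.
#' @export
compute_rcbf <- function(trace, protocol) {
  stopifnot(inherits(trace, "bfi_trace"), inherits(protocol, "hob_protocol"))
  win <- stage_windows(protocol)
  n_stage <- nrow(win)
  means <- rep(NA_real_, n_stage)
  nsamp <- integer(n_stage)
  for (i in seq_len(n_stage)) {
    in_win <- trace$t >= win$win_start[i] & trace$t < win$win_end[i] &
      trace$quality
    nsamp[i] <- sum(in_win)
    if (nsamp[i] >= 1L) means[i] <- mean(trace$bfi[in_win])
  }
  fail <- function(reason) structure(
    list(rcbf_supine_to_30 = NA_real_, rcbf_30_to_supine = NA_real_,
         ratios = rep(NA_real_, n_stage), baseline_mean = means[1L],
         n_samples = nsamp, ok = FALSE, reason = reason),
    class = "rcbf_result")
  if (any(nsamp == 0L))
    return(fail(paste0("empty analysis window: ",
                       paste(win$label[nsamp == 0L], collapse = ", "))))
  if (!is.finite(means[1L]) || means[1L] <= 0)
    return(fail("non-positive baseline"))
  # averaging per-sample normalised values equals the ratio of means for a
  # fixed baseline
  ratios <- means / means[1L]
  i30 <- which(win$angle != 0)[1L]
  iback <- n_stage
  structure(list(
    rcbf_supine_to_30 = (ratios[i30] - 1) * 100,
    rcbf_30_to_supine = (ratios[iback] - 1) * 100,
    ratios = ratios,
    baseline_mean = means[1L],
    n_samples = nsamp,
    ok = TRUE, reason = NA_character_
  ), class = "rcbf_result")
}

#' @export
print.rcbf_result <- function(x, ...) {
  if (!x$ok) {
    cat("rCBF endpoints: FAILED (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("rCBF supine->30: %+.1f%%; 30->supine: %+.1f%% (baseline %.3g cm^2/s)\n",
                x$rcbf_supine_to_30, x$rcbf_30_to_supine, x$baseline_mean))
  }
  invisible(x)
}

#' Per-subject endpoints for a whole cohort
#'
#' Applies [compute_rcbf()] to every subject and joins the endpoints onto
#' the subject table. Missing traces or failed windows are flagged, never
#' fatal.
#'
#' @param subjects Subject table (data.frame with at least `subject_id` and
#'   `group`).
#' @param traces Named list of [bfi_trace()] objects keyed by `subject_id`.
#' @param protocol A [hob_protocol()].
#' @return A data.frame: one row per subject with columns `subject_id`,
#'   `group`, `rcbf_supine_to_30`, `rcbf_30_to_supine`, `baseline_mean`,
#'   `ok`, `reason`.
#' @export
cohort_endpoints <- function(subjects, traces, protocol = hob_protocol()) {
  stopifnot(is.data.frame(subjects), "subject_id" %in% names(subjects))
  ids <- as.character(subjects$subject_id)
  out <- data.frame(
    subject_id = ids,
    group = if ("group" %in% names(subjects)) subjects$group else NA,
    rcbf_supine_to_30 = NA_real_,
    rcbf_30_to_supine = NA_real_,
    baseline_mean = NA_real_,
    ok = FALSE,
    reason = NA_character_,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(ids)) {
    tr <- traces[[ids[i]]]
    if (is.null(tr)) {
      out$reason[i] <- "missing trace"
      next
    }
    r <- compute_rcbf(tr, protocol)
    out$rcbf_supine_to_30[i] <- r$rcbf_supine_to_30
    out$rcbf_30_to_supine[i] <- r$rcbf_30_to_supine
    out$baseline_mean[i] <- r$baseline_mean
    out$ok[i] <- r$ok
    out$reason[i] <- r$reason
  }
  n_bad <- sum(!out$ok)
  if (n_bad > 0L)
    message(n_bad, " of ", nrow(out), " subjects flagged in endpoint computation")
  out
}
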