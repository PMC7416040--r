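#' Extract condition/phase segments from a labeled time series
#'
#' Collects every contiguous run of volumes labeled with the requested
#' condition and learning phase. Runs never span an epoch boundary. An
#' optional hemodynamic offset drops the first `offset` volumes of each run
#' (shifting the analysis window into the epoch); runs shorter than
#' `min_len` after shifting are dropped with a warning.
#'
#' @param ts A `node_timeseries`.
#' @param condition Epoch kind, e.g. "Encoding" or "Retrieval".
#' @param phase "Early", "Late", or "Both".
#' @param offset Non-negative integer volume shift (default 0).
#' @param min_len Minimum usable segment length (default 3 = model order + 2
#'   at p = 1).
#' @return A `segmented_series`: list with `condition`, `phase`, `subject`,
#'   and `segments`, a list of volumes x nodes matrices.
#' @export
#' @examples
#' sched <- make_design_schedule()
#' ts <- simulate_network_timeseries(default_coupling_specs()$HC, sched,
#'                                   seed = 1)
#' seg <- segment_series(ts, "Encoding", "Early")
#' length(seg$segments)  # 4 epochs of 9 volumes
segment_series <- function(ts, condition, phase = "Both", offset = 0,
                           min_len = 3) {
  sched <- ts$schedule
  lab <- sched$labels
  if (!condition %in% sched$epoch_order) {
    stop("unknown condition '", condition, "'; schedule has: ",
         paste(unique(sched$epoch_order), collapse = ", "), call. = FALSE)
  }
  if (!phase %in% c("Early", "Late", "Both")) {
    stop("phase must be 'Early', 'Late' or 'Both'", call. = FALSE)
  }
  if (offset < 0) stop("offset must be >= 0", call. = FALSE)

  keep <- lab$epoch == condition & (phase == "Both" | lab$phase == phase)
  if (!any(keep)) {
    stop("no epochs labeled (", condition, ", ", phase, ") in the schedule",
         call. = FALSE)
  }
  idx <- which(keep)
  # split into contiguous runs (epoch instances)
  run_id <- cumsum(c(1L, diff(idx) != 1L))
  segments <- list()
  dropped <- 0L
  for (r in unique(run_id)) {
    rows <- idx[run_id == r]
    if (offset > 0) rows <- rows[-seq_len(min(offset, length(rows)))]
    if (length(rows) >= min_len) {
      segments[[length(segments) + 1L]] <- ts$data[rows, , drop = FALSE]
    } else {
      dropped <- dropped + 1L
    }
  }
  if (dropped > 0L) {
    warning(dropped, " segment(s) shorter than ", min_len,
            " volumes after offset were dropped", call. = FALSE)
  }
  if (length(segments) == 0L) {
    stop("all segments were shorter than min_len after the offset",
         call. = FALSE)
  }
  structure(list(condition = condition, phase = phase,
                 subject = ts$subject, segments = segments),
            class = "segmented_series")
}
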