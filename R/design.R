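#' Build the block-design schedule
#'
#' Constructs the per-volume labeling of an alternating block paradigm. One
#' cycle contains the epochs in `epoch_order` (default Encoding, Rest,
#' Retrieval, Rest), each lasting `epoch_len_s` seconds sampled every `tr_s`
#' seconds. The first half of the cycles is the Early phase of learning and
#' the second half the Late phase, so `n_cycles` must be even. The defaults
#' (TR = 3 s, 27 s epochs, 8 cycles) give 9 volumes per epoch and 288 volumes
#' in total.
#'
#' @param tr_s Sampling interval (repetition time), seconds.
#' @param epoch_len_s Epoch duration, seconds; must be an integer multiple of
#'   `tr_s`.
#' @param n_cycles Number of cycles; must be even and positive.
#' @param epoch_order Character vector of epoch kinds within one cycle.
#'
#' @return A `design_schedule`: list with the design parameters,
#'   `volumes_per_epoch`, `n_volumes`, and `labels`, a data frame with one row
#'   per volume and columns `volume`, `epoch`, `cycle`, `phase`.
#' @export
#' @examples
#' sched <- make_design_schedule()
#' sched$n_volumes  # 288
#' table(sched$labels$epoch)
make_design_schedule <- function(tr_s = 3, epoch_len_s = 27, n_cycles = 8,
                                 epoch_order = c("Encoding", "Rest",
                                                 "Retrieval", "Rest")) {
  if (!is.numeric(tr_s) || length(tr_s) != 1L || tr_s <= 0) {
    stop("tr_s must be a positive scalar", call. = FALSE)
  }
  vpe <- epoch_len_s / tr_s
  if (abs(vpe - round(vpe)) > 1e-9) {
    stop("epoch_len_s (", epoch_len_s, ") must be an integer multiple of ",
         "tr_s (", tr_s, ")", call. = FALSE)
  }
  vpe <- as.integer(round(vpe))
  if (n_cycles < 2 || n_cycles %% 2 != 0) {
    stop("n_cycles must be even (>= 2): the Early/Late split takes the ",
         "first and last half of the cycles", call. = FALSE)
  }
  n_cycles <- as.integer(n_cycles)
  epoch_order <- as.character(epoch_order)

  epochs_per_cycle <- length(epoch_order)
  n_vol <- n_cycles * epochs_per_cycle * vpe
  cycle <- rep(seq_len(n_cycles), each = epochs_per_cycle * vpe)
  epoch <- rep(rep(epoch_order, each = vpe), times = n_cycles)
  phase <- ifelse(cycle <= n_cycles / 2, "Early", "Late")
  labels <- data.frame(volume = seq_len(n_vol), epoch = epoch,
                       cycle = cycle, phase = phase,
                       stringsAsFactors = FALSE)

  structure(list(tr_s = tr_s, epoch_len_s = epoch_len_s,
                 n_cycles = n_cycles, epoch_order = epoch_order,
                 volumes_per_epoch = vpe, n_volumes = n_vol,
                 labels = labels),
            class = "design_schedule")
}

#' @export
print.design_schedule <- function(x, ...) {
  cat("Block-design schedule: TR =", x$tr_s, "s;",
      x$epoch_len_s, "s epochs (", x$volumes_per_epoch, "volumes );",
      x$n_cycles, "cycles of [", paste(x$epoch_order, collapse = ", "),
      "];", x$n_volumes, "volumes total\n")
  invisible(x)
}
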