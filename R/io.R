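# Tab-delimited writers/readers. Every analysis table is written with '#'
# provenance header lines (condition, phase, mode, p, q, ...) that readers
# skip via comment.char.

.write_tsv <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) {
    for (k in names(provenance)) {
      writeLines(paste0("# ", k, "=", provenance[[k]]), con)
    }
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read a subject's node time series
#'
#' Tab-delimited text: one header row of node labels, one row per volume.
#'
#' @param ts A `node_timeseries`.
#' @param path Output path.
#' @export
write_timeseries <- function(ts, path) {
  .write_tsv(as.data.frame(ts$data), path)
}

#' @rdname write_timeseries
#' @param schedule The `design_schedule` the series was acquired under.
#' @param subject Optional `subject_record`.
#' @return `read_timeseries` returns a `node_timeseries`.
#' @export
read_timeseries <- function(path, schedule, subject = NULL) {
  d <- as.matrix(.read_tsv(path))
  if (nrow(d) != schedule$n_volumes) {
    stop("time series has ", nrow(d), " rows but the schedule expects ",
         schedule$n_volumes, call. = FALSE)
  }
  structure(list(subject = subject, schedule = schedule, data = d),
            class = "node_timeseries")
}

#' Write the schedule, subjects and behavior tables
#'
#' @param schedule A `design_schedule`.
#' @param path Output path.
#' @export
write_schedule <- function(schedule, path) {
  .write_tsv(schedule$labels, path,
             provenance = list(tr_s = schedule$tr_s,
                               epoch_len_s = schedule$epoch_len_s,
                               n_cycles = schedule$n_cycles))
}

#' @rdname write_schedule
#' @param subjects Subjects data frame (`cohort$subjects`).
#' @export
write_subjects <- function(subjects, path) {
  .write_tsv(subjects, path)
}

#' @rdname write_schedule
#' @param behavior Long behavior table.
#' @export
write_behavior <- function(behavior, path) {
  .write_tsv(behavior, path)
}

#' @rdname write_schedule
#' @return Readers return the corresponding data frame.
#' @export
read_behavior <- function(path) {
  .read_tsv(path)
}

#' @rdname write_schedule
#' @export
read_subjects <- function(path) {
  .read_tsv(path)
}

#' Write an edge statistics table with provenance header
#'
#' @param stat_table An `edge_stat_table` or `covariate_edge_table`.
#' @param path Output path.
#' @export
write_edge_stats <- function(stat_table, path) {
  prov <- list(condition = stat_table$condition[1],
               phase = stat_table$phase[1])
  if (!is.null(attr(stat_table, "mode"))) {
    prov$mode <- attr(stat_table, "mode")
    prov$p_order <- attr(stat_table, "p_order")
  }
  if (!is.null(attr(stat_table, "q_threshold"))) {
    prov$q_threshold <- attr(stat_table, "q_threshold")
  }
  .write_tsv(as.data.frame(stat_table), path, provenance = prov)
}

#' Write a connectome-ring edge list
#'
#' Machine-readable edge list for ring plots of one condition-phase cell:
#' source, target, signed group difference, significance flag. No plotting
#' dependency is required to consume it.
#'
#' @param stat_table An `edge_stat_table`.
#' @param path Output path.
#' @export
write_connectome_ring <- function(stat_table, path) {
  ring <- data.frame(source = stat_table$source, target = stat_table$target,
                     diff = stat_table$diff,
                     significant = stat_table$significant,
                     stringsAsFactors = FALSE)
  .write_tsv(ring, path,
             provenance = list(condition = stat_table$condition[1],
                               phase = stat_table$phase[1]))
}
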