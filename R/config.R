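#' Default pipeline configuration
#'
#' A single nested list holding every knob of the end-to-end pipeline:
#' design (TR, epoch length, cycle count), node labels, estimation settings
#' (pairwise vs multivariate, model order, intercept/demean, hemodynamic
#' offset), inference settings (q threshold, FDR family scope), and
#' simulation settings (group sizes, coupling parameters, behavior
#' parameters, covariate model, master seed). The structure round-trips
#' losslessly through the YAML config file ([write_config()] /
#' [read_config()]); coupling matrices are materialized from it by
#' [config_coupling_specs()].
#'
#' @param seed Master seed.
#' @param out_dir Output directory (NULL: caller supplies one at run time).
#' @return A `pipeline_config` list.
#' @export
default_pipeline_config <- function(seed = 1, out_dir = NULL) {
  structure(list(
    design = list(tr_s = 3, epoch_len_s = 27, n_cycles = 8,
                  epoch_order = c("Encoding", "Rest", "Retrieval", "Rest")),
    nodes = list(labels = default_node_set()$labels),
    estimation = list(mode = "bivariate", p = 1, intercept = TRUE,
                      demean = FALSE, hemodynamic_offset = 0),
    inference = list(q_threshold = 0.05, fdr_family = "per_cell",
                     test = "welch"),
    simulation = list(
      n_hc = 24, n_scz = 31,
      coupling = list(base_self = 0.3, base_cross = 0.05, coupled = 0.3,
                      noise_sd = 1, baseline_level = 100),
      behavior = list(n_items = 9,
                      hc = list(mean = c(0.90, 2.0, 0.80),
                                sd = c(0.06, 0.40, 0.12)),
                      scz = list(mean = c(0.60, 2.0, 0.55),
                                 sd = c(0.06, 0.40, 0.12))),
      covariates = list(links = list()),
      seed = seed),
    output = list(dir = out_dir)
  ), class = "pipeline_config")
}

#' Write / read a pipeline configuration file
#'
#' The configuration is stored as YAML; reading a written config returns an
#' identical structure (lossless round-trip).
#'
#' @param config A `pipeline_config`.
#' @param path File path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
}

#' @rdname write_config
#' @return `read_config` returns a `pipeline_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "pipeline_config")
}

#' Materialize coupling specs from a configuration
#'
#' @param config A `pipeline_config`.
#' @return Per-group coupling spec lists (see [default_coupling_specs()]).
#' @export
config_coupling_specs <- function(config) {
  cp <- config$simulation$coupling
  default_coupling_specs(
    nodes = node_set(config$nodes$labels),
    base_self = cp$base_self, base_cross = cp$base_cross,
    coupled = cp$coupled, noise_sd = cp$noise_sd,
    baseline_level = cp$baseline_level)
}

# Behavior parameter list in the format simulate_learning_curves() expects.
.config_gompertz_params <- function(config) {
  b <- config$simulation$behavior
  mk <- function(x) list(mean = stats::setNames(unlist(x$mean), c("a", "b", "c")),
                         sd = stats::setNames(unlist(x$sd), c("a", "b", "c")))
  list(HC = mk(b$hc), SCZ = mk(b$scz))
}
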