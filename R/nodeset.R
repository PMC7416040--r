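#' Define a network node set
#'
#' A node set names the network's regions and, optionally, carries MNI
#' centroid coordinates used for sphere-based ROI extraction from 4D images.
#'
#' @param labels Character vector of unique node names.
#' @param centroids Optional data frame with columns `label`, `x`, `y`, `z`
#'   (MNI mm coordinates), one row per node.
#' @param radius_mm Optional sphere radius in mm; required (and > 0) when
#'   `centroids` is given.
#'
#' @return An object of class `node_set`: a list with `labels`, `centroids`,
#'   `radius_mm`.
#' @export
#' @examples
#' ns <- node_set(c("A", "B", "C"))
#' length(ns$labels)
node_set <- function(labels, centroids = NULL, radius_mm = NULL) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) {
    stop("node labels must be unique", call. = FALSE)
  }
  if (!is.null(centroids)) {
    need <- c("label", "x", "y", "z")
    if (!is.data.frame(centroids) || !all(need %in% names(centroids))) {
      stop("centroids must be a data frame with columns label, x, y, z",
           call. = FALSE)
    }
    if (!setequal(centroids$label, labels)) {
      stop("centroid labels must match node labels", call. = FALSE)
    }
    if (is.null(radius_mm) || !is.numeric(radius_mm) || radius_mm <= 0) {
      stop("radius_mm must be > 0 when centroids are given", call. = FALSE)
    }
  }
  structure(list(labels = labels, centroids = centroids,
                 radius_mm = radius_mm),
            class = "node_set")
}

#' Default six-node memory network
#'
#' The canonical node set used throughout: dorsolateral prefrontal cortex
#' (dlPFC), dorsal anterior cingulate (dACC), hippocampus (HPC), superior
#' parietal cortex (SP), fusiform gyrus (FG), and inferior temporal gyrus
#' (ITG). With six nodes there are exactly 30 directed edges (ordered pairs,
#' diagonal excluded).
#'
#' @return A `node_set` with six labels and no centroids.
#' @export
default_node_set <- function() {
  node_set(c("dlPFC", "dACC", "HPC", "SP", "FG", "ITG"))
}

#' Enumerate directed edges of a node set
#'
#' Edge ordering is row-major by target then source: for each target node (in
#' node-set order), all source nodes except the target itself. This ordering
#' is stable and used for every edge panel and statistics table.
#'
#' @param nodes A `node_set` or character vector of labels.
#' @return Data frame with columns `source`, `target`, `edge`
#'   (label `"source->target"`), one row per ordered pair.
#' @export
directed_edges <- function(nodes) {
  labels <- if (inherits(nodes, "node_set")) nodes$labels else as.character(nodes)
  tgt <- rep(labels, each = length(labels))
  src <- rep(labels, times = length(labels))
  keep <- src != tgt
  data.frame(source = src[keep], target = tgt[keep],
             edge = paste0(src[keep], "->", tgt[keep]),
             stringsAsFactors = FALSE)
}
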