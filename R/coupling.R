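#' Spectral radius of a square matrix
#'
#' Largest eigenvalue modulus; a lag-1 coupling matrix generates a stationary
#' VAR(1) process iff its spectral radius is strictly below 1.
#'
#' @param B Square numeric matrix.
#' @return Non-negative scalar.
#' @export
spectral_radius <- function(B) {
  max(Mod(eigen(B, only.values = TRUE)$values))
}

#' Ground-truth lag-1 coupling specification
#'
#' Describes the generative VAR(1) process for one task condition and learning
#' phase: `Z_t = intercept + B Z_{t-1} + e_t`, `e_t ~ N(0, noise_sd^2 I)`.
#' Element `B[i, j]` is the influence of node `j` at the previous volume on
#' node `i` at the current volume. The process's stationary mean and
#' covariance are precomputed here so that simulation can restart each epoch
#' from the stationary distribution.
#'
#' @param condition Epoch kind this spec applies to ("Encoding", "Retrieval",
#'   "Rest", ...).
#' @param phase "Early", "Late", or "Both".
#' @param B N x N lag-1 coupling matrix with spectral radius < 1.
#' @param intercept Length-N intercept vector (signal units); scalars are
#'   recycled.
#' @param noise_sd Innovation standard deviation (>= 0).
#'
#' @return A `coupling_spec` with the inputs plus the stationary mean `mu`
#'   and a Cholesky factor of the stationary covariance.
#' @export
#' @examples
#' cs <- coupling_spec("Encoding", "Early", B = diag(0.4, 2),
#'                     intercept = c(60, 60), noise_sd = 1)
#' cs$mu  # stationary mean = (I - B)^-1 intercept
coupling_spec <- function(condition, phase = "Both", B, intercept = 0,
                          noise_sd = 1) {
  B <- as.matrix(B)
  N <- nrow(B)
  if (ncol(B) != N) stop("B must be square", call. = FALSE)
  rho <- spectral_radius(B)
  if (rho >= 1) {
    stop("unstable coupling matrix: spectral radius ", signif(rho, 4),
         " >= 1", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be >= 0", call. = FALSE)
  }
  if (!phase %in% c("Early", "Late", "Both")) {
    stop("phase must be 'Early', 'Late' or 'Both'", call. = FALSE)
  }
  intercept <- rep_len(as.numeric(intercept), N)

  mu <- solve(diag(N) - B, intercept)
  # stationary covariance: Sigma = B Sigma B' + noise_sd^2 I, solved via vec()
  if (noise_sd > 0) {
    S <- matrix(solve(diag(N * N) - kronecker(B, B),
                      as.vector(diag(noise_sd^2, N))), N, N)
    S <- (S + t(S)) / 2
    chol_S <- t(chol(S))
  } else {
    S <- matrix(0, N, N)
    chol_S <- NULL
  }

  structure(list(condition = as.character(condition), phase = phase,
                 B = B, intercept = intercept, noise_sd = noise_sd,
                 mu = mu, stationary_cov = S, chol_cov = chol_S),
            class = "coupling_spec")
}

# Raise chosen directed edges of a background coupling matrix.
# edges: data frame (source, target); B[target, source] <- value.
.raise_edges <- function(B, labels, edges, value) {
  for (k in seq_len(nrow(edges))) {
    B[match(edges$target[k], labels), match(edges$source[k], labels)] <- value
  }
  B
}

.edge_df <- function(...) {
  m <- do.call(rbind, list(...))
  data.frame(source = m[, 1], target = m[, 2], stringsAsFactors = FALSE)
}

#' Default ground-truth coupling for the two-group study
#'
#' Builds the generative coupling sets for a healthy-control (HC) and a
#' patient (SCZ) group over the four Encoding/Retrieval x Early/Late cells
#' plus Rest. All matrices share a weak background (self-coupling
#' `base_self`, cross-coupling `base_cross`); in each condition-phase cell
#' exactly six directed edges are raised to `coupled` in one group only, so
#' the groups differ on 6 of the 30 directed edges per cell and agree on the
#' remaining 24. The raised edge sets encode the qualitative group structure
#' the pipeline is meant to detect: during Encoding the patient group has
#' reduced coupling (Early: within a frontal-hippocampal-fusiform subnetwork;
#' Late: on afferents of the dlPFC), during Retrieval increased coupling
#' (Early: on afferents of the dACC; Late: toward the dlPFC but reduced from
#' the dlPFC). Rest uses weak self-coupling only, identical across groups.
#'
#' @param nodes A `node_set` (default: the six-node memory network).
#' @param base_self Background self-coupling (diagonal of every B).
#' @param base_cross Background cross-coupling (off-diagonal baseline).
#' @param coupled Raised coupling value on effect edges.
#' @param noise_sd Innovation SD shared by all specs.
#' @param baseline_level Stationary mean signal level (arbitrary BOLD-like
#'   units); intercepts are chosen as `(I - B) %*% rep(baseline_level, N)`.
#'
#' @return Named list with elements `HC` and `SCZ`, each a list of
#'   `coupling_spec` objects covering all condition-phase cells of the
#'   default schedule.
#' @export
default_coupling_specs <- function(nodes = default_node_set(),
                                   base_self = 0.3, base_cross = 0.05,
                                   coupled = 0.3, noise_sd = 1,
                                   baseline_level = 100) {
  labels <- nodes$labels
  N <- length(labels)
  base <- matrix(base_cross, N, N, dimnames = list(labels, labels))
  diag(base) <- base_self

  eff <- list(
    Encoding_Early = list(high = "HC", edges = .edge_df(
      c("dlPFC", "HPC"), c("HPC", "dlPFC"), c("dlPFC", "FG"),
      c("dACC", "HPC"), c("HPC", "FG"), c("FG", "HPC"))),
    Encoding_Late = list(high = "HC", edges = .edge_df(
      c("dACC", "dlPFC"), c("HPC", "dlPFC"), c("SP", "dlPFC"),
      c("FG", "dlPFC"), c("ITG", "dlPFC"), c("HPC", "FG"))),
    Retrieval_Early = list(high = "SCZ", edges = .edge_df(
      c("dlPFC", "dACC"), c("HPC", "dACC"), c("SP", "dACC"),
      c("FG", "dACC"), c("ITG", "dACC"), c("dACC", "FG"))),
    Retrieval_Late = NULL  # mixed-direction cell, built below
  )

  mk_spec <- function(condition, phase, B) {
    coupling_spec(condition, phase, B,
                  intercept = (diag(N) - B) %*% rep(baseline_level, N),
                  noise_sd = noise_sd)
  }

  specs <- list(HC = list(), SCZ = list())
  for (cell in c("Encoding_Early", "Encoding_Late", "Retrieval_Early")) {
    parts <- strsplit(cell, "_")[[1]]
    e <- eff[[cell]]
    for (g in c("HC", "SCZ")) {
      B <- if (g == e$high) .raise_edges(base, labels, e$edges, coupled) else base
      specs[[g]][[cell]] <- mk_spec(parts[1], parts[2], B)
    }
  }

  # Retrieval Late: patients raised toward dlPFC, controls raised from dlPFC
  to_dlpfc <- .edge_df(c("dACC", "dlPFC"), c("HPC", "dlPFC"), c("FG", "dlPFC"))
  from_dlpfc <- .edge_df(c("dlPFC", "dACC"), c("dlPFC", "HPC"), c("dlPFC", "FG"))
  specs$HC$Retrieval_Late <-
    mk_spec("Retrieval", "Late", .raise_edges(base, labels, from_dlpfc, coupled))
  specs$SCZ$Retrieval_Late <-
    mk_spec("Retrieval", "Late", .raise_edges(base, labels, to_dlpfc, coupled))

  rest <- diag(0.15, N)
  dimnames(rest) <- list(labels, labels)
  for (g in c("HC", "SCZ")) {
    specs[[g]]$Rest <- mk_spec("Rest", "Both", rest)
  }
  specs
}

#' True between-group edge differences implied by a coupling set
#'
#' Compares the generative coupling matrices of two groups for one
#' condition-phase cell and returns, per directed edge, the ground-truth
#' difference. Used to score simulation studies (which discoveries are true)
#' against the generator's own truth.
#'
#' @param group_specs Named list of per-group `coupling_spec` lists, as
#'   returned by [default_coupling_specs()].
#' @param condition,phase Cell to compare.
#' @param nodes Node set giving the edge ordering.
#' @return Data frame `source`, `target`, `edge`, `true_diff`
#'   (HC minus SCZ coupling), `nonnull` (logical).
#' @export
true_edge_differences <- function(group_specs, condition, phase,
                                  nodes = default_node_set()) {
  pick <- function(g) {
    for (sp in group_specs[[g]]) {
      if (sp$condition == condition && sp$phase %in% c(phase, "Both")) {
        return(sp$B)
      }
    }
    stop("no coupling spec for ", g, " / ", condition, " / ", phase,
         call. = FALSE)
  }
  B_hc <- pick("HC")
  B_scz <- pick("SCZ")
  ed <- directed_edges(nodes)
  d <- mapply(function(s, t) {
    i <- match(t, nodes$labels); j <- match(s, nodes$labels)
    B_hc[i, j] - B_scz[i, j]
  }, ed$source, ed$target)
  ed$true_diff <- unname(d)
  ed$nonnull <- abs(ed$true_diff) > 1e-12
  ed
}
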