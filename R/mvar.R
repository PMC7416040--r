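# Stack lagged predictor/response pairs across segments. Lagged pairs are
# formed strictly within segments: the first p volumes of each segment serve
# as predictors only, and no pair crosses a segment (epoch) boundary.
# Returns X (n_obs x N*p, lag-major: all nodes at lag 1, then lag 2, ...),
# Y (n_obs x N), n_obs = sum(len_s - p).
.stack_lagged <- function(segments, p) {
  Xs <- list(); Ys <- list()
  for (seg in segments) {
    len <- nrow(seg)
    if (len < p + 1L) next
    rows <- (p + 1L):len
    Ys[[length(Ys) + 1L]] <- seg[rows, , drop = FALSE]
    Xs[[length(Xs) + 1L]] <- do.call(cbind, lapply(seq_len(p), function(k) {
      seg[rows - k, , drop = FALSE]
    }))
  }
  if (length(Ys) == 0L) stop("no segment long enough for order ", p,
                             call. = FALSE)
  list(X = do.call(rbind, Xs), Y = do.call(rbind, Ys))
}

# Core multi-response OLS with standard errors. X: n x k design (no
# intercept column yet), Y: n x m responses. Returns coefficients (k' x m),
# sigma2 (m), se (k' x m), using an added intercept when requested.
.ols_core <- function(X, Y, intercept = TRUE) {
  n <- nrow(X)
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  k <- ncol(X)
  if (n <= k) {
    stop("insufficient observations (", n, ") for ", k, " regressors",
         call. = FALSE)
  }
  qx <- qr(X)
  if (qx$rank < k) {
    stop("rank-deficient design matrix (rank ", qx$rank, " < ", k, ")",
         call. = FALSE)
  }
  coefs <- qr.coef(qx, Y)
  resid <- Y - X %*% coefs
  sigma2 <- colSums(resid^2) / (n - k)
  XtX_inv_diag <- diag(chol2inv(qr.R(qx)))
  se <- sqrt(outer(XtX_inv_diag, sigma2))
  dimnames(se) <- dimnames(coefs)
  list(coef = coefs, sigma2 = sigma2, se = se, df = n - k)
}

#' Fit an MVAR model to segmented time series
#'
#' Ordinary least squares estimation of the lag coefficient matrices of
#' `Z_t = c + sum_k B_k Z_{t-k} + e_t` on the pooled within-segment lagged
#' pairs of the selected nodes. Each target node is regressed on all
#' selected nodes at lags 1..p (plus an intercept by default; alternatively
#' each segment is demeaned per column and the intercept dropped). Standard
#' errors come from the usual OLS covariance, and `t = estimate / se`
#' measures each coefficient's difference from zero (the Granger-style
#' directed-influence statistic).
#'
#' @param seg A `segmented_series` (or any list with a `segments` element of
#'   volumes x nodes matrices).
#' @param node_subset Node names or column indices to model (default: all
#'   columns). Order defines the coefficient matrix layout.
#' @param p Model order (number of lags, default 1).
#' @param intercept Include an intercept column (default TRUE).
#' @param demean Subtract per-segment column means instead of fitting an
#'   intercept (sets `intercept = FALSE`).
#' @return An `mvar_fit`: `B_hat`, `se`, `t_stat` as `p x N x N` arrays with
#'   `[k, i, j]` = lag-k influence of node j on node i; `intercepts`,
#'   `sigma2` (residual variance per target), `n_obs` (= sum over segments
#'   of length - p), `n_segments`, `df`, `nodes`, `p`.
#' @export
fit_mvar <- function(seg, node_subset = NULL, p = 1, intercept = TRUE,
                     demean = FALSE) {
  if (p < 1) stop("model order p must be >= 1", call. = FALSE)
  segments <- seg$segments
  all_names <- colnames(segments[[1]])
  if (is.null(node_subset)) {
    node_idx <- seq_len(ncol(segments[[1]]))
  } else if (is.character(node_subset)) {
    node_idx <- match(node_subset, all_names)
    if (anyNA(node_idx)) stop("unknown node(s): ",
                              paste(node_subset[is.na(node_idx)],
                                    collapse = ", "), call. = FALSE)
  } else {
    node_idx <- as.integer(node_subset)
  }
  if (length(node_idx) < 2L) stop("need >= 2 nodes", call. = FALSE)
  nodes <- if (!is.null(all_names)) all_names[node_idx] else
    paste0("node", node_idx)
  N <- length(node_idx)

  segments <- lapply(segments, function(s) s[, node_idx, drop = FALSE])
  segments <- Filter(function(s) nrow(s) >= p + 2L, segments)
  if (length(segments) == 0L) {
    stop("no segment of length >= p + 2", call. = FALSE)
  }
  if (demean) {
    intercept <- FALSE
    segments <- lapply(segments, function(s) scale(s, scale = FALSE))
  }
  lag <- .stack_lagged(segments, p)
  fit <- .ols_core(lag$X, lag$Y, intercept = intercept)

  off <- as.integer(intercept)
  B_hat <- array(NA_real_, c(p, N, N), dimnames = list(NULL, nodes, nodes))
  se <- B_hat; t_stat <- B_hat
  for (k in seq_len(p)) {
    rows <- off + (k - 1L) * N + seq_len(N)   # predictors: nodes at lag k
    B_hat[k, , ] <- t(fit$coef[rows, , drop = FALSE])  # [i, j]: j predicts i
    se[k, , ] <- t(fit$se[rows, , drop = FALSE])
  }
  t_stat <- ifelse(se > 0, B_hat / se, NA_real_)
  intercepts <- if (intercept) fit$coef[1, ] else rep(0, N)

  structure(list(B_hat = B_hat, se = se, t_stat = t_stat,
                 intercepts = intercepts, sigma2 = fit$sigma2,
                 n_obs = nrow(lag$X), n_segments = length(segments),
                 df = fit$df, nodes = nodes, p = p,
                 condition = seg$condition, phase = seg$phase),
            class = "mvar_fit")
}

#' @export
print.mvar_fit <- function(x, ...) {
  cat("MVAR(", x$p, ") fit over ", length(x$nodes), " nodes, ",
      x$n_obs, " lagged observations in ", x$n_segments, " segments\n",
      sep = "")
  cat("Lag-1 coefficients (row = target, column = source):\n")
  print(round(x$B_hat[1, , ], 4))
  invisible(x)
}

#' Build a subjects x directed-edges coefficient panel
#'
#' For one condition-phase cell, estimates every directed lag-1 coefficient
#' for every subject and assembles them into a panel matrix with one row per
#' subject and N(N-1) columns (30 for the default six-node set). In
#' `bivariate` mode (the default) each unordered node pair gets its own
#' 2-node MVAR fit supplying both directed coefficients; in `multivariate`
#' mode a single all-node fit supplies all off-diagonal coefficients.
#' Columns follow the stable ordering of [directed_edges()] (by target, then
#' source). Subjects whose fit fails are excluded with a warning.
#'
#' @param cohort A `cohort` (or list with `series` and `subjects`).
#' @param condition,phase Cell to analyze.
#' @param mode "bivariate" or "multivariate".
#' @param p Model order (default 1).
#' @param offset Hemodynamic offset in volumes (default 0).
#' @param intercept,demean Passed to [fit_mvar()].
#' @return An `edge_panel`: list with `coef` (subjects x edges matrix),
#'   `subjects` (data frame for the retained rows), `edges`, `condition`,
#'   `phase`, `mode`, `p`.
#' @export
build_edge_panel <- function(cohort, condition, phase,
                             mode = c("bivariate", "multivariate"),
                             p = 1, offset = 0, intercept = TRUE,
                             demean = FALSE) {
  mode <- match.arg(mode)
  series <- cohort$series
  subjects <- cohort$subjects
  nodes <- colnames(series[[1]]$data)
  ed <- directed_edges(nodes)
  n_edges <- nrow(ed)

  coef_mat <- matrix(NA_real_, length(series), n_edges,
                     dimnames = list(subjects$subject_id, ed$edge))
  failed <- character(0)
  for (s in seq_along(series)) {
    res <- tryCatch({
      seg <- segment_series(series[[s]], condition, phase, offset = offset,
                            min_len = p + 2L)
      if (mode == "multivariate") {
        fit <- fit_mvar(seg, p = p, intercept = intercept, demean = demean)
        vapply(seq_len(n_edges), function(e) {
          fit$B_hat[1, match(ed$target[e], nodes), match(ed$source[e], nodes)]
        }, numeric(1))
      } else {
        v <- numeric(n_edges)
        pairs <- utils::combn(nodes, 2, simplify = FALSE)
        for (pr in pairs) {
          fit <- fit_mvar(seg, node_subset = pr, p = p,
                          intercept = intercept, demean = demean)
          v[ed$source == pr[1] & ed$target == pr[2]] <- fit$B_hat[1, 2, 1]
          v[ed$source == pr[2] & ed$target == pr[1]] <- fit$B_hat[1, 1, 2]
        }
        v
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, subjects$subject_id[s])
    } else {
      coef_mat[s, ] <- res
    }
  }
  if (length(failed) > 0L) {
    warning("excluded ", length(failed), " subject(s) with failed fits: ",
            paste(failed, collapse = ", "), call. = FALSE)
    keep <- !subjects$subject_id %in% failed
    coef_mat <- coef_mat[keep, , drop = FALSE]
    subjects <- subjects[keep, , drop = FALSE]
  }
  structure(list(coef = coef_mat, subjects = subjects, edges = ed,
                 condition = condition, phase = phase, mode = mode, p = p),
            class = "edge_panel")
}

#' @export
print.edge_panel <- function(x, ...) {
  cat("Edge coefficient panel: ", nrow(x$coef), " subjects x ",
      ncol(x$coef), " directed edges (", x$condition, "/", x$phase,
      ", mode = ", x$mode, ", p = ", x$p, ")\n", sep = "")
  invisible(x)
}
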