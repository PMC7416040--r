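#' Mixed (split-plot) ANOVA on recall performance
#'
#' Classical two-way mixed ANOVA of fraction correct with group (HC vs SCZ)
#' as the between-subject factor and retrieval block (time) as the
#' within-subject factor, computed from the standard sums-of-squares
#' partition via [stats::aov()] with an `Error(subject)` stratum. The group
#' effect is tested against subjects-within-group; time and group x time
#' against the within-subject residual. Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)` with each effect's own error term.
#' An optional Greenhouse-Geisser correction rescales the within-subject
#' degrees of freedom by the sphericity estimate epsilon.
#'
#' @param behavior Long data frame `subject_id`, `group`, `block`,
#'   `fraction`; every subject must have every block exactly once (no
#'   imputation is attempted) and each group needs >= 2 subjects.
#' @param gg_correction Apply the Greenhouse-Geisser correction to the
#'   within-subject tests (default FALSE).
#' @return An `anova_result`: data frame with one row per effect (`group`,
#'   `time`, `group:time`) and columns `F`, `df1`, `df2`, `MSe`,
#'   `partial_eta_sq`, `p` (plus `gg_epsilon`, `p_gg` when corrected).
#' @export
mixed_anova <- function(behavior, gg_correction = FALSE) {
  d <- behavior
  need <- c("subject_id", "group", "block", "fraction")
  if (!all(need %in% names(d))) {
    stop("behavior table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  blocks <- sort(unique(d$block))
  if (length(blocks) < 2L) stop("need >= 2 blocks", call. = FALSE)
  tab <- table(d$subject_id, d$block)
  if (any(tab != 1L)) {
    stop("incomplete design: every subject must have every block exactly ",
         "once", call. = FALSE)
  }
  grp_of <- tapply(d$group, d$subject_id, function(g) g[1])
  if (any(table(grp_of) < 2L)) {
    stop("need >= 2 subjects per group", call. = FALSE)
  }

  d$subject_f <- factor(d$subject_id)
  d$group_f <- factor(d$group)
  d$block_f <- factor(d$block)
  fit <- stats::aov(fraction ~ group_f * block_f + Error(subject_f), data = d)
  sm <- summary(fit)

  between <- sm[["Error: subject_f"]][[1]]
  within <- sm[["Error: Within"]][[1]]
  rn_b <- trimws(rownames(between))
  rn_w <- trimws(rownames(within))

  ss_scale <- sum((d$fraction - mean(d$fraction))^2)
  pick <- function(tabl, rn, term) {
    i <- match(term, rn)
    err <- nrow(tabl)  # residual row is last
    ss_e <- tabl[i, "Sum Sq"]; ss_r <- tabl[err, "Sum Sq"]
    # an effect sum of squares at floating-point-noise level relative to the
    # data is no evidence even when the error term is also degenerate (0/0):
    # report F = 0, p = 1
    zero <- ss_e <= 1e-12 * max(ss_scale, .Machine$double.xmin)
    f_val <- if (zero) 0 else tabl[i, "F value"]
    p_val <- if (zero) 1 else tabl[i, "Pr(>F)"]
    data.frame(
      F = f_val, df1 = tabl[i, "Df"], df2 = tabl[err, "Df"],
      MSe = tabl[err, "Mean Sq"],
      partial_eta_sq = if (ss_e + ss_r == 0) 0 else ss_e / (ss_e + ss_r),
      p = p_val)
  }
  out <- rbind(
    cbind(effect = "group", pick(between, rn_b, "group_f")),
    cbind(effect = "time", pick(within, rn_w, "block_f")),
    cbind(effect = "group:time", pick(within, rn_w, "group_f:block_f")))
  rownames(out) <- NULL

  if (gg_correction) {
    eps <- .gg_epsilon(d)
    out$gg_epsilon <- c(NA, eps, eps)
    out$p_gg <- out$p
    for (i in 2:3) {
      out$p_gg[i] <- stats::pf(out$F[i], out$df1[i] * eps,
                               out$df2[i] * eps, lower.tail = FALSE)
    }
  }
  class(out) <- c("anova_result", "data.frame")
  out
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of the
# subject x block matrix.
.gg_epsilon <- function(d) {
  wide <- stats::reshape(
    d[, c("subject_id", "block", "fraction")],
    idvar = "subject_id", timevar = "block", direction = "wide")
  Y <- as.matrix(wide[, grep("^fraction", names(wide)), drop = FALSE])
  grp <- tapply(d$group, d$subject_id, function(g) g[1])[wide$subject_id]
  k <- ncol(Y)
  covs <- lapply(split(as.data.frame(Y), grp), function(y) {
    stats::cov(as.matrix(y)) * (nrow(y) - 1)
  })
  S <- Reduce(`+`, covs) / (nrow(Y) - length(covs))
  C <- diag(k) - 1 / k   # double-centering
  Sd <- C %*% S %*% C
  sum(diag(Sd))^2 / ((k - 1) * sum(Sd^2))
}

#' Group contrasts on fitted Gompertz parameters
#'
#' Welch two-sample t tests (HC vs SCZ) on each per-subject learning
#' parameter -- asymptote `a`, shape offset `b`, rate `c`, and the derived
#' inflection time `b/c` -- with Cohen's d from the pooled SD. Subjects whose
#' fit failed to converge or was degenerate are excluded and counted.
#'
#' @param fits Per-subject fit table from [fit_gompertz_cohort()].
#' @return Data frame with one row per parameter: group means, Welch `t`,
#'   `df`, `p`, `cohen_d`, group sizes, `n_excluded`.
#' @export
compare_gompertz_params <- function(fits) {
  ok <- fits$converged & !fits$degenerate
  n_excluded <- sum(!ok)
  f <- fits[ok, ]
  if (length(unique(f$group)) < 2L || any(table(f$group) < 2L)) {
    stop("need >= 2 converged fits per group", call. = FALSE)
  }
  params <- c("a", "b", "c", "inflection_time")
  rows <- lapply(params, function(p) {
    x <- f[[p]][f$group == "HC"]
    y <- f[[p]][f$group == "SCZ"]
    tt <- stats::t.test(x, y)
    sp <- sqrt(((length(x) - 1) * stats::var(x) +
                (length(y) - 1) * stats::var(y)) /
               (length(x) + length(y) - 2))
    data.frame(parameter = p, mean_hc = mean(x), mean_scz = mean(y),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value,
               cohen_d = if (sp > 0) (mean(x) - mean(y)) / sp else NA_real_,
               n_hc = length(x), n_scz = length(y),
               n_excluded = n_excluded, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
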