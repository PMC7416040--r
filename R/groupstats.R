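#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Adjusted q values are the standard monotone BH adjustment
#' (`p * m / rank`, cumulative-minimum from the largest p, capped at 1;
#' ties share the most favorable outcome), and the rejection mask applies
#' the step-up rule at level `q`: reject all hypotheses whose q value is at
#' most `q`.
#'
#' @param pvals Numeric vector of p values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return List with `qvals` and logical `reject`.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.04, 0.05), q = 0.05)$reject  # all TRUE
bh_fdr <- function(pvals, q = 0.05) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p values must be finite and in [0, 1]", call. = FALSE)
  }
  qvals <- stats::p.adjust(pvals, method = "BH")
  list(qvals = qvals, reject = qvals <= q)
}

#' Edge-wise group comparison with FDR control
#'
#' Welch two-sample t test (HC vs SCZ) on every directed edge of a
#' coefficient panel, with Benjamini-Hochberg adjustment across the
#' N(N-1)-edge family of this condition-phase cell. The table carries the
#' group means, their difference and absolute difference, and a direction
#' label: "reduced in SCZ" when the HC mean exceeds the SCZ mean, otherwise
#' "increased in SCZ". Edges with zero variance in both groups get p = 1 and
#' are flagged.
#'
#' @param panel An `edge_panel`.
#' @param q_threshold FDR level for the significance flag (default 0.05).
#' @return An `edge_stat_table` (data frame), one row per directed edge:
#'   `source`, `target`, `edge`, `condition`, `phase`, `mean_hc`,
#'   `mean_scz`, `diff` (HC - SCZ), `abs_diff`, `direction`, `t`, `df`, `p`,
#'   `q`, `significant`, `zero_variance`.
#' @export
compare_groups <- function(panel, q_threshold = 0.05) {
  subj <- panel$subjects
  for (g in c("HC", "SCZ")) {
    if (sum(subj$group == g) < 2L) {
      stop("need >= 2 subjects in group ", g, call. = FALSE)
    }
  }
  hc <- panel$coef[subj$group == "HC", , drop = FALSE]
  scz <- panel$coef[subj$group == "SCZ", , drop = FALSE]

  m <- ncol(panel$coef)
  mean_hc <- colMeans(hc); mean_scz <- colMeans(scz)
  t_val <- df_val <- p_val <- numeric(m)
  zero_var <- logical(m)
  for (e in seq_len(m)) {
    x <- hc[, e]; y <- scz[, e]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      zero_var[e] <- TRUE
      t_val[e] <- 0; df_val[e] <- length(x) + length(y) - 2; p_val[e] <- 1
    } else {
      tt <- stats::t.test(x, y)
      t_val[e] <- unname(tt$statistic)
      df_val[e] <- unname(tt$parameter)
      p_val[e] <- tt$p.value
    }
  }
  adj <- bh_fdr(p_val, q_threshold)

  out <- data.frame(
    panel$edges,
    condition = panel$condition, phase = panel$phase,
    mean_hc = mean_hc, mean_scz = mean_scz,
    diff = mean_hc - mean_scz, abs_diff = abs(mean_hc - mean_scz),
    direction = ifelse(mean_hc > mean_scz, "reduced in SCZ",
                       "increased in SCZ"),
    t = t_val, df = df_val, p = p_val, q = adj$qvals,
    significant = adj$reject, zero_variance = zero_var,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "q_threshold") <- q_threshold
  attr(out, "mode") <- panel$mode
  attr(out, "p_order") <- panel$p
  class(out) <- c("edge_stat_table", "data.frame")
  out
}

#' Edge-wise covariate regression
#'
#' Pearson correlation (equivalently the simple-regression slope test)
#' between a subject covariate and every directed edge coefficient, with BH
#' adjustment across the edges of this cell. Subjects with a missing
#' covariate are excluded listwise and counted.
#'
#' @param panel An `edge_panel`.
#' @param covariate Either a column name of `panel$subjects` ("age",
#'   "fsiq", "dosage_ratio") or a numeric vector aligned with the panel
#'   rows.
#' @param q_threshold FDR level (default 0.05).
#' @param group Restrict to one group first (e.g. `"SCZ"` for dosage);
#'   default: all subjects.
#' @return A `covariate_edge_table` data frame: `source`, `target`, `edge`,
#'   `condition`, `phase`, `covariate`, `n`, `r`, `p`, `q`, `significant`,
#'   `sign` ("positive"/"negative"); `attr(, "n_missing")` counts exclusions.
#' @export
covariate_regression <- function(panel, covariate, q_threshold = 0.05,
                                 group = NULL) {
  subj <- panel$subjects
  coefs <- panel$coef
  if (is.character(covariate) && length(covariate) == 1L) {
    cov_name <- covariate
    if (!cov_name %in% names(subj)) {
      stop("covariate '", cov_name, "' not found in panel subjects",
           call. = FALSE)
    }
    v <- subj[[cov_name]]
  } else {
    cov_name <- "covariate"
    v <- as.numeric(covariate)
    if (length(v) != nrow(coefs)) {
      stop("covariate vector length must match the panel rows", call. = FALSE)
    }
  }
  if (!is.null(group)) {
    keep_g <- subj$group %in% group
    v <- v[keep_g]; coefs <- coefs[keep_g, , drop = FALSE]
  }
  ok <- is.finite(v)
  n_missing <- sum(!ok)
  v <- v[ok]; coefs <- coefs[ok, , drop = FALSE]
  if (length(v) < 3L) {
    stop("need >= 3 subjects with a non-missing covariate", call. = FALSE)
  }
  if (stats::var(v) == 0) {
    stop("covariate has zero variance", call. = FALSE)
  }

  m <- ncol(coefs)
  r <- p <- numeric(m)
  for (e in seq_len(m)) {
    ct <- stats::cor.test(v, coefs[, e])
    r[e] <- unname(ct$estimate)
    p[e] <- ct$p.value
  }
  adj <- bh_fdr(p, q_threshold)
  out <- data.frame(
    panel$edges, condition = panel$condition, phase = panel$phase,
    covariate = cov_name, n = length(v), r = r, p = p, q = adj$qvals,
    significant = adj$reject,
    sign = ifelse(r >= 0, "positive", "negative"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_missing") <- n_missing
  class(out) <- c("covariate_edge_table", "data.frame")
  out
}

#' Correlations between covariates and behavioral measures
#'
#' Pearson correlations of each covariate with Early and Late mean recall
#' fractions and with the fitted learning-curve parameters (rate `c` and
#' derived inflection time `b/c`). Missing covariates are excluded listwise
#' per test.
#'
#' @param behavior Long behavior table (`subject_id`, `block`, `fraction`).
#' @param fits Per-subject Gompertz fit table from [fit_gompertz_cohort()].
#' @param covariates Data frame with `subject_id` plus one column per
#'   covariate.
#' @return Data frame `outcome`, `covariate`, `n`, `r`, `p`.
#' @export
behavior_covariate_tests <- function(behavior, fits, covariates) {
  blocks <- sort(unique(behavior$block))
  half <- blocks[seq_len(floor(length(blocks) / 2))]
  agg <- function(d) c(
    early_fraction = mean(d$fraction[d$block %in% half]),
    late_fraction = mean(d$fraction[!d$block %in% half]))
  beh <- do.call(rbind, lapply(split(behavior, behavior$subject_id), agg))
  beh <- data.frame(subject_id = rownames(beh), beh,
                    stringsAsFactors = FALSE)
  ok <- fits$converged & !fits$degenerate
  dat <- merge(beh, fits[ok, c("subject_id", "c", "inflection_time")],
               by = "subject_id")
  names(dat)[names(dat) == "c"] <- "learning_rate"
  dat <- merge(dat, covariates, by = "subject_id")

  outcomes <- c("early_fraction", "late_fraction", "learning_rate",
                "inflection_time")
  cov_names <- setdiff(names(covariates), "subject_id")
  rows <- list()
  for (oc in outcomes) {
    for (cv in cov_names) {
      keep <- is.finite(dat[[oc]]) & is.finite(dat[[cv]])
      if (sum(keep) < 3L || stats::var(dat[[cv]][keep]) == 0 ||
          stats::var(dat[[oc]][keep]) == 0) next
      ct <- stats::cor.test(dat[[cv]][keep], dat[[oc]][keep])
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = oc, covariate = cv, n = sum(keep),
        r = unname(ct$estimate), p = ct$p.value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
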