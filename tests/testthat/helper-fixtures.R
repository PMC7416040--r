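# Shared fixtures: tiny schedules, coupling sets and cohorts built in code.

tiny_schedule <- function(n_cycles = 2, epoch_len_s = 9, tr_s = 3) {
  make_design_schedule(tr_s = tr_s, epoch_len_s = epoch_len_s,
                       n_cycles = n_cycles)
}

# single-condition schedule: one epoch kind, n_cycles epochs of len volumes
long_schedule <- function(len, n_cycles = 2) {
  make_design_schedule(tr_s = 1, epoch_len_s = len, n_cycles = n_cycles,
                       epoch_order = "Encoding")
}

two_node_spec <- function(B = matrix(c(0.5, 0.3, 0, 0.4), 2, 2),
                          noise_sd = 1, condition = "Encoding",
                          phase = "Both") {
  dimnames(B) <- list(c("A", "B"), c("A", "B"))
  coupling_spec(condition, phase, B, intercept = 0, noise_sd = noise_sd)
}

# independent OLS oracle: per-target lm() on explicitly built lagged pairs
ols_oracle <- function(segments, p = 1, intercept = TRUE) {
  X <- NULL; Y <- NULL
  for (seg in segments) {
    len <- nrow(seg)
    rows <- (p + 1):len
    Y <- rbind(Y, seg[rows, , drop = FALSE])
    X <- rbind(X, do.call(cbind, lapply(seq_len(p), function(k)
      seg[rows - k, , drop = FALSE])))
  }
  N <- ncol(Y)
  B <- matrix(NA_real_, N, ncol(X))
  for (i in seq_len(N)) {
    fit <- if (intercept) stats::lm(Y[, i] ~ X) else stats::lm(Y[, i] ~ X - 1)
    cf <- stats::coef(fit)
    B[i, ] <- cf[(1 + as.integer(intercept)):length(cf)]
  }
  B   # row i = target, columns = predictors (nodes x lags)
}

# brute-force split-plot ANOVA oracle from group/subject/block means
anova_ss_oracle <- function(behavior) {
  d <- behavior
  subj <- unique(d[, c("subject_id", "group")])
  n_s <- nrow(subj)
  blocks <- sort(unique(d$block))
  k <- length(blocks)
  gm <- mean(d$fraction)

  grp_means <- tapply(d$fraction, d$group, mean)
  n_per_grp <- table(subj$group)
  ss_group <- sum(n_per_grp * k * (grp_means - gm)^2)

  subj_means <- tapply(d$fraction, d$subject_id, mean)
  subj_grp <- setNames(subj$group, subj$subject_id)
  ss_subj_within <- sum(k * (subj_means - grp_means[subj_grp[names(subj_means)]])^2)

  blk_means <- tapply(d$fraction, d$block, mean)
  ss_time <- sum(n_s * (blk_means - gm)^2)

  cell_means <- tapply(d$fraction, list(d$group, d$block), mean)
  ss_cells <- 0
  for (g in rownames(cell_means)) for (b in colnames(cell_means)) {
    ss_cells <- ss_cells + n_per_grp[[g]] *
      (cell_means[g, b] - grp_means[[g]] - blk_means[[b]] + gm)^2
  }
  ss_gxt <- ss_cells

  ss_total <- sum((d$fraction - gm)^2)
  ss_resid <- ss_total - ss_group - ss_subj_within - ss_time - ss_gxt

  df_group <- length(n_per_grp) - 1
  df_subj <- n_s - length(n_per_grp)
  df_time <- k - 1
  df_gxt <- df_group * df_time
  df_resid <- df_subj * df_time

  list(
    group = list(F = (ss_group / df_group) / (ss_subj_within / df_subj),
                 MSe = ss_subj_within / df_subj,
                 peta = ss_group / (ss_group + ss_subj_within),
                 df1 = df_group, df2 = df_subj),
    time = list(F = (ss_time / df_time) / (ss_resid / df_resid),
                MSe = ss_resid / df_resid,
                peta = ss_time / (ss_time + ss_resid),
                df1 = df_time, df2 = df_resid),
    gxt = list(F = (ss_gxt / df_gxt) / (ss_resid / df_resid),
               MSe = ss_resid / df_resid,
               peta = ss_gxt / (ss_gxt + ss_resid),
               df1 = df_gxt, df2 = df_resid))
}

# brute-force BH oracle: test every candidate cutoff
bh_oracle_reject <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  k_max <- 0
  for (i in seq_len(m)) {
    if (p[ord[i]] <= i / m * q) k_max <- i
  }
  reject <- logical(m)
  if (k_max > 0) reject[ord[seq_len(k_max)]] <- TRUE
  reject
}

# closed-form Pearson r
pearson_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

make_behavior_table <- function(Y, groups) {
  # Y: subjects x blocks matrix
  n <- nrow(Y); k <- ncol(Y)
  data.frame(subject_id = rep(sprintf("S%02d", seq_len(n)), each = k),
             group = rep(groups, each = k),
             block = rep(seq_len(k), times = n),
             fraction = as.vector(t(Y)), stringsAsFactors = FALSE)
}
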