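test_that("BH step-up matches the manual enumeration and handles edge cases", {
  res <- bh_fdr(c(0.01, 0.02, 0.04, 0.05), q = 0.05)
  expect_true(all(res$reject))  # p_(4) = 0.05 <= 4/4 * 0.05
  expect_true(all(res$qvals >= c(0.01, 0.02, 0.04, 0.05)))
  res1 <- bh_fdr(rep(1, 10))
  expect_false(any(res1$reject))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("BH rejection set equals the exhaustive-cutoff oracle", {
  set.seed(47)
  for (i in 1:200) {
    m <- sample(1:40, 1)
    p <- switch(sample(3, 1),
                runif(m),
                rbeta(m, 0.3, 1),            # enrich small p
                round(runif(m), 2))          # ties
    q <- sample(c(0.01, 0.05, 0.1, 0.2), 1)
    expect_identical(bh_fdr(p, q)$reject, bh_oracle_reject(p, q))
  }
})

make_panel <- function(coef, groups, condition = "Encoding",
                       phase = "Early") {
  nodes <- default_node_set()
  ed <- directed_edges(nodes)
  colnames(coef) <- ed$edge
  structure(list(
    coef = coef,
    subjects = data.frame(subject_id = sprintf("s%02d", seq_len(nrow(coef))),
                          group = groups, stringsAsFactors = FALSE),
    edges = ed, condition = condition, phase = phase,
    mode = "bivariate", p = 1), class = "edge_panel")
}

test_that("group comparison populates every field coherently", {
  set.seed(53)
  coef <- matrix(rnorm(20 * 30), 20, 30)
  coef[1:10, 3] <- coef[1:10, 3] + 2  # HC raised on one edge
  st <- compare_groups(make_panel(coef, rep(c("HC", "SCZ"), each = 10)))
  expect_equal(nrow(st), 30)
  expect_true(all(st$q >= st$p - 1e-15))
  expect_true(all(st$significant == (st$q <= 0.05)))
  expect_equal(st$abs_diff, abs(st$mean_hc - st$mean_scz))
  expect_equal(st$direction,
               ifelse(st$mean_hc > st$mean_scz, "reduced in SCZ",
                      "increased in SCZ"))
  expect_true(st$significant[3])
  expect_equal(st$direction[3], "reduced in SCZ")
  # Welch t cross-check on one edge
  tt <- t.test(coef[1:10, 7], coef[11:20, 7])
  expect_equal(st$t[7], unname(tt$statistic), tolerance = 1e-12)
})

test_that("duplicated groups give zero differences and no discoveries", {
  set.seed(59)
  half <- matrix(rnorm(5 * 30), 5, 30)
  st <- compare_groups(make_panel(rbind(half, half),
                                  rep(c("HC", "SCZ"), each = 5)))
  expect_true(all(st$abs_diff == 0))
  expect_false(any(st$significant))
})

test_that("flipping group labels flips directions and negates differences", {
  set.seed(61)
  coef <- matrix(rnorm(12 * 30), 12, 30)
  g <- rep(c("HC", "SCZ"), each = 6)
  st1 <- compare_groups(make_panel(coef, g))
  st2 <- compare_groups(make_panel(coef, rev(g)))
  expect_equal(st1$diff, -st2$diff)
  expect_true(all(st1$direction != st2$direction |
                  st1$diff == 0))
  expect_equal(st1$p, st2$p, tolerance = 1e-12)
})

test_that("Welch t is invariant to per-edge affine rescaling", {
  set.seed(67)
  coef <- matrix(rnorm(14 * 30), 14, 30)
  g <- rep(c("HC", "SCZ"), each = 7)
  st1 <- compare_groups(make_panel(coef, g))
  scale <- runif(30, 0.5, 3)
  shift <- rnorm(30)
  coef2 <- sweep(sweep(coef, 2, scale, "*"), 2, shift, "+")
  st2 <- compare_groups(make_panel(coef2, g))
  expect_equal(abs(st1$t), abs(st2$t), tolerance = 1e-10)
  expect_equal(st1$p, st2$p, tolerance = 1e-10)
})

test_that("zero-variance edges are flagged with p = 1", {
  set.seed(71)
  coef <- matrix(rnorm(8 * 30), 8, 30)
  coef[, 5] <- 0.7
  st <- compare_groups(make_panel(coef, rep(c("HC", "SCZ"), each = 4)))
  expect_true(st$zero_variance[5])
  expect_equal(st$p[5], 1)
  expect_error(compare_groups(make_panel(coef[1:4, ], rep("HC", 4))),
               ">= 2 subjects")
})

test_that("covariate regression equals the closed-form Pearson oracle", {
  set.seed(73)
  coef <- matrix(rnorm(15 * 30), 15, 30)
  panel <- make_panel(coef, rep(c("HC", "SCZ"), c(7, 8)))
  v <- rnorm(15)
  ct <- covariate_regression(panel, v)
  for (e in c(1, 13, 30)) {
    expect_equal(ct$r[e], pearson_oracle(v, coef[, e]), tolerance = 1e-10)
  }
  # perfect linearity
  panel2 <- make_panel(cbind(v, coef[, -1]), rep(c("HC", "SCZ"), c(7, 8)))
  ct2 <- covariate_regression(panel2, v)
  expect_equal(ct2$r[1], 1, tolerance = 1e-12)
  expect_error(covariate_regression(panel, rep(2, 15)), "zero variance")
})

test_that("missing covariates are excluded listwise and counted", {
  set.seed(79)
  coef <- matrix(rnorm(10 * 30), 10, 30)
  panel <- make_panel(coef, rep(c("HC", "SCZ"), each = 5))
  panel$subjects$dosage_ratio <- c(rep(NA, 5), runif(5))
  ct <- covariate_regression(panel, "dosage_ratio", group = "SCZ")
  expect_equal(unique(ct$n), 5)
  panel$subjects$dosage_ratio[6] <- NA
  ct2 <- covariate_regression(panel, "dosage_ratio", group = "SCZ")
  expect_equal(attr(ct2, "n_missing"), 1)
  expect_equal(unique(ct2$n), 4)
})

test_that("null covariates produce false positives at about the BH level", {
  set.seed(83)
  # with all edges null the FDP of a family is 1 iff it has any discovery,
  # so E[FDP] = P(any discovery) <= q under BH
  fdp <- vapply(1:60, function(r) {
    coef <- matrix(rnorm(20 * 30), 20, 30)
    panel <- make_panel(coef, rep(c("HC", "SCZ"), each = 10))
    ct <- covariate_regression(panel, rnorm(20))
    as.numeric(any(ct$significant))
  }, numeric(1))
  expect_lte(mean(fdp), 0.05 + 2 * sqrt(0.05 * 0.95 / 60))
})

test_that("behavior covariate tests recover constructed correlations", {
  set.seed(89)
  n <- 30
  subj <- sprintf("s%02d", 1:n)
  early <- runif(n, 0.3, 0.7)
  beh <- do.call(rbind, lapply(1:n, function(i) {
    data.frame(subject_id = subj[i], group = "HC", block = 1:8,
               fraction = c(rep(early[i], 4), rep(0.9, 4)),
               stringsAsFactors = FALSE)
  }))
  fits <- data.frame(subject_id = subj, group = "HC",
                     a = runif(n), b = rnorm(n), c = runif(n, 0.3, 1),
                     inflection_time = rnorm(n, 3),
                     sse = 0, converged = TRUE, degenerate = FALSE,
                     stringsAsFactors = FALSE)
  # covariate equal to the early fraction: r = 1
  covs <- data.frame(subject_id = subj, cv = early,
                     stringsAsFactors = FALSE)
  res <- behavior_covariate_tests(beh, fits, covs)
  expect_equal(res$r[res$outcome == "early_fraction"], 1, tolerance = 1e-12)
  # covariate orthogonalized against the outcome: r = 0
  ortho <- residuals(lm(rnorm(n) ~ early))
  covs2 <- data.frame(subject_id = subj, cv = ortho,
                      stringsAsFactors = FALSE)
  res2 <- behavior_covariate_tests(beh, fits, covs2)
  expect_lt(abs(res2$r[res2$outcome == "early_fraction"]), 1e-10)
})
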