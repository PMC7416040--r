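test_that("default schedule yields four 9-volume segments per cell", {
  sched <- make_design_schedule()
  ts <- simulate_network_timeseries(default_coupling_specs()$HC, sched,
                                    seed = 2)
  for (cond in c("Encoding", "Retrieval")) {
    for (ph in c("Early", "Late")) {
      seg <- segment_series(ts, cond, ph)
      expect_length(seg$segments, 4)
      expect_true(all(vapply(seg$segments, nrow, integer(1)) == 9))
    }
  }
  # hemodynamic offset shifts into the epoch and truncates at its end
  seg2 <- segment_series(ts, "Encoding", "Early", offset = 2)
  expect_true(all(vapply(seg2$segments, nrow, integer(1)) == 7))
})

test_that("unknown labels and empty selections are rejected", {
  sched <- tiny_schedule()
  ts <- simulate_network_timeseries(default_coupling_specs()$HC, sched,
                                    seed = 2)
  expect_error(segment_series(ts, "Sleep", "Early"), "unknown condition")
  expect_error(segment_series(ts, "Encoding", "Dusk"), "phase")
  # offset eats the whole 3-volume epochs
  expect_error(suppressWarnings(
    segment_series(ts, "Encoding", "Early", offset = 3)), "min_len")
  # uneven runs: segments falling below min_len are dropped with a warning
  sched_h <- tiny_schedule()
  sched_h$labels <- data.frame(
    volume = 1:10,
    epoch = c(rep("Encoding", 5), rep("Rest", 2), rep("Encoding", 3)),
    cycle = c(rep(1L, 7), rep(2L, 3)),
    phase = "Early", stringsAsFactors = FALSE)
  ts_h <- list(subject = NULL, schedule = sched_h,
               data = matrix(rnorm(20), 10, 2,
                             dimnames = list(NULL, c("A", "B"))))
  class(ts_h) <- "node_timeseries"
  expect_warning(seg_h <- segment_series(ts_h, "Encoding", "Early",
                                         offset = 1, min_len = 3),
                 "dropped")
  expect_length(seg_h$segments, 1)
  expect_equal(nrow(seg_h$segments[[1]]), 4)
})

test_that("fit_mvar reproduces the explicit normal-equations solution", {
  set.seed(5)
  seg_data <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("A", "B")))
  seg <- structure(list(condition = "Encoding", phase = "Both",
                        subject = NULL, segments = list(seg_data)),
                   class = "segmented_series")
  fit <- fit_mvar(seg, p = 1)
  B_orc <- ols_oracle(list(seg_data), p = 1)
  expect_lt(max(abs(fit$B_hat[1, , ] - B_orc)), 1e-10)
})

test_that("fit_mvar equals the lm oracle on random instances", {
  set.seed(23)
  for (i in 1:100) {
    N <- sample(2:4, 1)
    p <- sample(1:2, 1)
    n_seg <- sample(1:3, 1)
    segs <- lapply(seq_len(n_seg), function(s) {
      matrix(rnorm(N * sample(12:20, 1)), ncol = N,
             dimnames = list(NULL, LETTERS[1:N]))
    })
    seg <- structure(list(condition = "x", phase = "Both", subject = NULL,
                          segments = segs), class = "segmented_series")
    fit <- fit_mvar(seg, p = p)
    orc <- ols_oracle(segs, p = p)
    est <- do.call(cbind, lapply(seq_len(p), function(k) fit$B_hat[k, , ]))
    expect_lt(max(abs(est - orc)), 1e-8)
    expect_equal(fit$n_obs,
                 sum(vapply(segs, nrow, integer(1)) - p))
  }
})

test_that("coupling is recovered within tolerance at n = 2000", {
  B <- matrix(c(0.5, 0.3, 0, 0.4), 2, 2)
  ts <- simulate_network_timeseries(list(two_node_spec(B = B)),
                                    long_schedule(1000), seed = 11)
  fit <- fit_mvar(segment_series(ts, "Encoding", "Both"), p = 1)
  expect_lt(max(abs(fit$B_hat[1, , ] - B)), 0.05)
  # t statistics are estimate / se elementwise
  expect_equal(fit$t_stat, fit$B_hat / fit$se)
})

test_that("independent white-noise series show no spurious coupling", {
  set.seed(31)
  seg_data <- matrix(rnorm(10000), 5000, 2,
                     dimnames = list(NULL, c("A", "B")))
  seg <- structure(list(condition = "x", phase = "Both", subject = NULL,
                        segments = list(seg_data)),
                   class = "segmented_series")
  fit <- fit_mvar(seg, p = 1)
  expect_lt(abs(fit$B_hat[1, 1, 2]), 0.05)
  expect_lt(abs(fit$B_hat[1, 2, 1]), 0.05)
})

test_that("segment order does not change the estimate", {
  set.seed(41)
  segs <- lapply(1:4, function(s)
    matrix(rnorm(18), 9, 2, dimnames = list(NULL, c("A", "B"))))
  mk <- function(ss) structure(list(condition = "x", phase = "Both",
                                    subject = NULL, segments = ss),
                               class = "segmented_series")
  f1 <- fit_mvar(mk(segs), p = 1)
  f2 <- fit_mvar(mk(rev(segs)), p = 1)
  expect_equal(f1$B_hat, f2$B_hat, tolerance = 1e-12)
})

test_that("degenerate designs are rejected with a message", {
  x <- rnorm(20)
  seg_data <- cbind(A = x, B = x)  # perfectly collinear nodes
  seg <- structure(list(condition = "x", phase = "Both", subject = NULL,
                        segments = list(seg_data)),
                   class = "segmented_series")
  expect_error(fit_mvar(seg, p = 1), "rank-deficient")
  short <- structure(list(condition = "x", phase = "Both", subject = NULL,
                          segments = list(matrix(rnorm(8), 4, 2))),
                     class = "segmented_series")
  expect_error(fit_mvar(short, p = 3), "length >= p")
})

test_that("edge panels have N(N-1) columns in stable order", {
  coh <- simulate_cohort(default_coupling_specs(), n_hc = 2, n_scz = 2,
                         schedule = tiny_schedule(epoch_len_s = 27), seed = 3)
  pan <- build_edge_panel(coh, "Encoding", "Early")
  expect_equal(ncol(pan$coef), 30)
  expect_equal(nrow(pan$coef), 4)
  ed <- directed_edges(default_node_set())
  expect_equal(colnames(pan$coef), ed$edge)
  # ordering: by target, then source
  expect_equal(ed$target[1:5], rep("dlPFC", 5))
  expect_equal(ed$source[1:5], c("dACC", "HPC", "SP", "FG", "ITG"))

  # two-node cohort
  B <- matrix(c(0.4, 0.2, 0.1, 0.3), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  sp2 <- function(cond) coupling_spec(cond, "Both", B, noise_sd = 1)
  specs2 <- list(HC = list(sp2("Encoding"), sp2("Rest"), sp2("Retrieval")),
                 SCZ = list(sp2("Encoding"), sp2("Rest"), sp2("Retrieval")))
  coh2 <- simulate_cohort(specs2, n_hc = 2, n_scz = 2,
                          schedule = tiny_schedule(epoch_len_s = 27), seed = 4)
  pan2 <- build_edge_panel(coh2, "Encoding", "Early")
  expect_equal(ncol(pan2$coef), 2)
})

test_that("bivariate and multivariate modes agree on pairwise-sparse truth", {
  specs <- calibration_coupling_specs(coupled_hc = 0.35, coupled_scz = 0.35)
  coh <- simulate_cohort(specs, n_hc = 4, n_scz = 4,
                         schedule = make_design_schedule(), seed = 17)
  pb <- build_edge_panel(coh, "Encoding", "Early", mode = "bivariate")
  pm <- build_edge_panel(coh, "Encoding", "Early", mode = "multivariate")
  truth <- true_edge_differences(
    calibration_coupling_specs(coupled_hc = 0.35, coupled_scz = 0),
    "Encoding", "Early")
  nonnull <- truth$edge[truth$nonnull]
  mb <- colMeans(pb$coef[, nonnull])
  mm <- colMeans(pm$coef[, nonnull])
  expect_true(all(sign(mb) == sign(mm)))
  expect_true(all(mb > 0))  # all true couplings are positive
})
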