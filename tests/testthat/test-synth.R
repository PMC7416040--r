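test_that("noiseless uncoupled process sits at its stationary mean", {
  B <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  sp <- coupling_spec("Encoding", "Both", B, intercept = c(5, 5),
                      noise_sd = 0)
  sched <- long_schedule(len = 10)
  ts <- simulate_network_timeseries(list(sp), sched, seed = 1)
  expect_true(all(ts$data == 5))
})

test_that("identical seeds give bit-identical series", {
  sp <- two_node_spec()
  sched <- tiny_schedule()
  spl <- list(sp, two_node_spec(B = diag(0.1, 2), condition = "Rest"),
              two_node_spec(B = diag(0.2, 2), condition = "Retrieval"))
  t1 <- simulate_network_timeseries(spl, sched, seed = 99)
  t2 <- simulate_network_timeseries(spl, sched, seed = 99)
  expect_identical(t1$data, t2$data)
  t3 <- simulate_network_timeseries(spl, sched, seed = 100)
  expect_false(identical(t1$data, t3$data))
})

test_that("lag-1 regression on a long simulation recovers the coupling", {
  B <- matrix(c(0.5, 0.3, 0, 0.4), 2, 2)
  sp <- two_node_spec(B = B)
  sched <- long_schedule(len = 2500)  # 2 segments, 5000 volumes total
  ts <- simulate_network_timeseries(list(sp), sched, seed = 7)
  seg <- segment_series(ts, "Encoding", "Both")
  B_hat <- ols_oracle(seg$segments, p = 1)
  expect_lt(max(abs(B_hat - B)), 0.05)
})

test_that("unstable coupling matrices are refused", {
  B <- matrix(c(0.9, 0.5, 0.5, 0.9), 2, 2)
  expect_error(coupling_spec("Encoding", "Both", B), "spectral radius")
  expect_error(coupling_spec("Encoding", "Both", diag(1, 2)),
               "spectral radius")
})

test_that("schedules with uncovered cells are rejected", {
  sp <- two_node_spec(condition = "Encoding")
  sched <- tiny_schedule()  # also has Rest and Retrieval epochs
  expect_error(simulate_network_timeseries(list(sp), sched, seed = 1),
               "no coupling spec")
})

test_that("simulated variance is finite and stable across seeds", {
  sp <- two_node_spec()
  sched <- long_schedule(len = 500)
  v <- vapply(1:5, function(s) {
    ts <- simulate_network_timeseries(list(sp), sched, seed = s)
    var(ts$data[, 2])
  }, numeric(1))
  expect_true(all(is.finite(v)))
  # theoretical stationary variance of node B for this spec is ~1.35
  expect_true(all(v > 0.5 & v < 3))
})

test_that("default cohort has 24 controls and 31 patients", {
  coh <- simulate_cohort(default_coupling_specs(), schedule = tiny_schedule(),
                         seed = 5)
  expect_equal(nrow(coh$subjects), 55)
  expect_equal(sum(coh$subjects$group == "HC"), 24)
  expect_equal(sum(coh$subjects$group == "SCZ"), 31)
  expect_true(all(is.na(coh$subjects$dosage_ratio[coh$subjects$group == "HC"])))
  expect_true(all(coh$subjects$dosage_ratio[coh$subjects$group == "SCZ"] >= 0))
})

test_that("cohort members get distinct derived seeds and group sizes validate", {
  coh <- simulate_cohort(default_coupling_specs(), n_hc = 1, n_scz = 1,
                         schedule = tiny_schedule(), seed = 5)
  expect_equal(nrow(coh$subjects), 2)
  expect_false(identical(coh$series[[1]]$data, coh$series[[2]]$data))
  expect_false(subject_seed(5, 1) == subject_seed(5, 2))
  expect_error(simulate_cohort(default_coupling_specs(), n_hc = 0,
                               n_scz = 3, schedule = tiny_schedule()),
               ">= 1")
})

test_that("cohort simulation is deterministic end-to-end", {
  c1 <- simulate_cohort(default_coupling_specs(), n_hc = 3, n_scz = 3,
                        schedule = tiny_schedule(), seed = 21)
  c2 <- simulate_cohort(default_coupling_specs(), n_hc = 3, n_scz = 3,
                        schedule = tiny_schedule(), seed = 21)
  expect_identical(c1$subjects, c2$subjects)
  expect_identical(lapply(c1$series, `[[`, "data"),
                   lapply(c2$series, `[[`, "data"))
})

test_that("a configured dosage-coupling link induces a positive association", {
  cm <- default_covariate_model(links = list(list(
    covariate = "dosage_ratio", condition = "Encoding", phase = "Early",
    source = "dlPFC", target = "HPC", slope = 0.2)))
  coh <- simulate_cohort(default_coupling_specs(), n_hc = 1, n_scz = 200,
                         schedule = tiny_schedule(), covariate_model = cm,
                         seed = 31)
  scz <- coh$subjects$group == "SCZ"
  linked <- vapply(coh$true_coupling[scz], `[[`, numeric(1), "dlPFC->HPC")
  expect_gt(cor(coh$subjects$dosage_ratio[scz], linked), 0.9)
})

test_that("OLS estimate error shrinks as the series grows", {
  B <- matrix(c(0.5, 0.3, 0, 0.4), 2, 2)
  sp <- two_node_spec(B = B)
  lens <- c(100, 1000, 10000)  # per segment; two segments each
  err <- matrix(NA_real_, 50, length(lens))
  for (s in 1:50) {
    for (l in seq_along(lens)) {
      ts <- simulate_network_timeseries(list(sp), long_schedule(lens[l]),
                                        seed = 1000 + s)
      fit <- fit_mvar(segment_series(ts, "Encoding", "Both"), p = 1)
      err[s, l] <- max(abs(fit$B_hat[1, , ] - B))
    }
  }
  m <- colMeans(err)
  expect_true(all(diff(m) < 0))  # non-increasing in expectation
})

test_that("saturated learners recall everything", {
  subj <- data.frame(subject_id = c("a", "b"), group = c("HC", "HC"),
                     stringsAsFactors = FALSE)
  pars <- list(HC = list(mean = c(a = 1, b = -10, c = 0),
                         sd = c(a = 0, b = 0, c = 0)))
  beh <- simulate_learning_curves(subj, pars, n_items = 9, n_blocks = 8,
                                  seed = 1, noise = "none")
  expect_true(all(beh$fraction == 1))
  expect_equal(nrow(beh), 16)
})

test_that("noise-free curves are the Gompertz values rounded to ninths", {
  subj <- data.frame(subject_id = "a", group = "HC", stringsAsFactors = FALSE)
  pars <- list(HC = list(mean = c(a = 0.9, b = 2, c = 0.8),
                         sd = c(a = 0, b = 0, c = 0)))
  beh <- simulate_learning_curves(subj, pars, n_items = 9, n_blocks = 8,
                                  seed = 1, noise = "none")
  expected <- round(gompertz_value(0.9, 2, 0.8, 1:8) * 9) / 9
  expect_equal(beh$fraction, expected)
  # all fractions are integer counts over n_items
  expect_true(all(abs(beh$fraction * 9 - round(beh$fraction * 9)) < 1e-12))
})

test_that("defaults give eight retrieval blocks per subject", {
  subj <- data.frame(subject_id = c("a", "b"), group = c("HC", "SCZ"),
                     stringsAsFactors = FALSE)
  beh <- simulate_learning_curves(subj, seed = 2)
  expect_equal(as.vector(table(beh$subject_id)), c(8L, 8L))
  expect_true(all(beh$fraction >= 0 & beh$fraction <= 1))
})

test_that("mean curves outside the unit interval are rejected", {
  subj <- data.frame(subject_id = "a", group = "HC", stringsAsFactors = FALSE)
  pars <- list(HC = list(mean = c(a = 1.2, b = -5, c = 1),
                         sd = c(a = 0, b = 0, c = 0)))
  expect_error(simulate_learning_curves(subj, pars, seed = 1), "\\[0, 1\\]")
})
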