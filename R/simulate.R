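#' Create a subject record
#'
#' @param subject_id Character id.
#' @param group "HC" (control) or "SCZ" (patient).
#' @param age Age in years (may be NA).
#' @param fsiq Full-scale IQ (may be NA).
#' @param dosage_ratio Antipsychotic PDD/DDD dosage ratio; NA for controls
#'   and missing values, otherwise >= 0.
#' @return A `subject_record` list.
#' @export
subject_record <- function(subject_id, group, age = NA_real_,
                           fsiq = NA_real_, dosage_ratio = NA_real_) {
  if (!group %in% c("HC", "SCZ")) {
    stop("group must be 'HC' or 'SCZ'", call. = FALSE)
  }
  if (!is.na(dosage_ratio) && dosage_ratio < 0) {
    stop("dosage_ratio must be >= 0 or NA", call. = FALSE)
  }
  structure(list(subject_id = as.character(subject_id), group = group,
                 age = age, fsiq = fsiq, dosage_ratio = dosage_ratio),
            class = "subject_record")
}

#' Derive a per-subject seed from a master seed
#'
#' Deterministic multiplicative hash kept below 2^31 so results are
#' reproducible from a single master seed. Index 0 is reserved for
#' cohort-level draws (covariates); behavioral simulation salts the index to
#' keep its stream distinct from the time-series stream.
#'
#' @param master Master seed (integer-valued scalar).
#' @param index Subject index (>= 0).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
subject_seed <- function(master, index) {
  p <- 2147483647
  as.integer((as.numeric(master) %% p * 48271 + as.numeric(index) * 16807) %% p)
}

# Match the unique coupling_spec covering (condition, phase); error when
# missing or ambiguous.
.match_spec <- function(specs, condition, phase) {
  hit <- Filter(function(sp) {
    sp$condition == condition && sp$phase %in% c(phase, "Both")
  }, specs)
  if (length(hit) == 0L) {
    stop("no coupling spec covers condition '", condition, "', phase '",
         phase, "'", call. = FALSE)
  }
  if (length(hit) > 1L) {
    stop("multiple coupling specs cover condition '", condition,
         "', phase '", phase, "'", call. = FALSE)
  }
  hit[[1]]
}

#' Simulate one subject's network time series
#'
#' Generates a VAR(1) recursion `Z_t = intercept + B Z_{t-1} + e_t` within
#' each epoch of the schedule, using the `coupling_spec` matching the epoch's
#' condition and phase. Each epoch restarts from an independent draw of the
#' process's stationary distribution, so no dependence crosses an epoch
#' boundary (the downstream estimators never form lagged pairs across
#' boundaries either).
#'
#' @param specs List of `coupling_spec` objects; together they must cover
#'   every (condition, phase) pair occurring in the schedule, each exactly
#'   once.
#' @param schedule A `design_schedule`.
#' @param subject Optional `subject_record` carried through to the output.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A `node_timeseries`: list with `subject`, `schedule`, and `data`,
#'   a volumes x nodes matrix.
#' @export
simulate_network_timeseries <- function(specs, schedule, subject = NULL,
                                        seed = 1) {
  if (inherits(specs, "coupling_spec")) specs <- list(specs)
  lab <- schedule$labels
  cells <- unique(lab[, c("epoch", "phase")])
  for (r in seq_len(nrow(cells))) {
    .match_spec(specs, cells$epoch[r], cells$phase[r])  # validates coverage
  }
  N <- nrow(specs[[1]]$B)
  node_names <- rownames(specs[[1]]$B)
  if (is.null(node_names)) node_names <- paste0("node", seq_len(N))

  set.seed(seed)
  Z <- matrix(NA_real_, schedule$n_volumes, N)
  # epoch instances = runs of identical (epoch, cycle, phase)
  epoch_id <- cumsum(c(TRUE, lab$epoch[-1] != lab$epoch[-nrow(lab)] |
                             lab$cycle[-1] != lab$cycle[-nrow(lab)]))
  for (id in unique(epoch_id)) {
    rows <- which(epoch_id == id)
    sp <- .match_spec(specs, lab$epoch[rows[1]], lab$phase[rows[1]])
    len <- length(rows)
    z <- if (is.null(sp$chol_cov)) sp$mu else
      sp$mu + sp$chol_cov %*% rnorm(N)
    Z[rows[1], ] <- z
    if (len > 1L) {
      eps <- if (sp$noise_sd > 0)
        matrix(rnorm((len - 1L) * N, sd = sp$noise_sd), N, len - 1L)
      else matrix(0, N, len - 1L)
      for (t in 2:len) {
        z <- sp$intercept + sp$B %*% z + eps[, t - 1L]
        Z[rows[t], ] <- z
      }
    }
  }
  colnames(Z) <- node_names
  structure(list(subject = subject, schedule = schedule, data = Z),
            class = "node_timeseries")
}

#' Default covariate model for cohort simulation
#'
#' Age and FSIQ are Gaussian with group-specific means matching the study
#' demographics (HC: age 28, FSIQ 101.3 +/- 10.6; SCZ: age 29, FSIQ 87.7 +/-
#' 6.1); the PDD/DDD dosage ratio is log-normal and drawn for patients only.
#' `links` optionally ties a covariate to a generative coupling edge by a
#' linear effect, for recovery tests: each link is a list with `covariate`
#' ("age", "fsiq" or "dosage_ratio"), `condition`, `phase`, `source`,
#' `target`, and `slope` (coupling units per SD of the covariate).
#'
#' @param links List of link specifications (default none: covariates
#'   independent of coupling).
#' @return A covariate model list.
#' @export
default_covariate_model <- function(links = list()) {
  list(
    age = list(mean_hc = 28, sd_hc = 7, mean_scz = 29, sd_scz = 8),
    fsiq = list(mean_hc = 101.29, sd_hc = 10.55,
                mean_scz = 87.74, sd_scz = 6.06),
    dosage = list(meanlog = 0, sdlog = 0.5),
    links = links
  )
}

# Apply covariate-coupling links for one subject: returns a (possibly
# modified) spec list plus the subject's true coupling values on linked edges.
.apply_links <- function(specs, links, covars, labels) {
  linked <- list()
  for (lk in links) {
    v <- covars[[lk$covariate]]
    if (is.na(v)) next
    z <- (v - lk$center) / lk$scale
    for (s in seq_along(specs)) {
      sp <- specs[[s]]
      if (sp$condition == lk$condition && sp$phase %in% c(lk$phase, "Both")) {
        B <- sp$B
        i <- match(lk$target, labels); j <- match(lk$source, labels)
        B[i, j] <- B[i, j] + lk$slope * z
        specs[[s]] <- coupling_spec(sp$condition, sp$phase, B,
                                    sp$intercept, sp$noise_sd)
        linked[[paste0(lk$source, "->", lk$target)]] <- B[i, j]
      }
    }
  }
  list(specs = specs, linked = linked)
}

#' Simulate a two-group cohort of network time series
#'
#' Draws covariates for `n_hc + n_scz` subjects, then simulates each
#' subject's series from the group's coupling specs with a per-subject seed
#' derived from the master seed (see [subject_seed()]). When the covariate
#' model contains links, the linked edge coupling is shifted by
#' `slope * standardized covariate` before simulation (the per-subject
#' generative value is recorded for recovery tests).
#'
#' @param group_specs Named list `HC`/`SCZ` of `coupling_spec` lists.
#' @param n_hc,n_scz Group sizes (>= 1); defaults 24 and 31.
#' @param schedule A `design_schedule`.
#' @param covariate_model See [default_covariate_model()].
#' @param seed Master seed.
#' @return A `cohort`: list with `series` (list of `node_timeseries`),
#'   `subjects` (data frame: subject_id, group, age, fsiq, dosage_ratio),
#'   `true_coupling` (per-subject linked-edge values, if any), `schedule`,
#'   `seed`.
#' @export
#' @examples
#' sched <- make_design_schedule(tr_s = 3, epoch_len_s = 9, n_cycles = 2)
#' coh <- simulate_cohort(default_coupling_specs(), n_hc = 2, n_scz = 2,
#'                        schedule = sched, seed = 7)
#' coh$subjects
simulate_cohort <- function(group_specs, n_hc = 24, n_scz = 31,
                            schedule = make_design_schedule(),
                            covariate_model = default_covariate_model(),
                            seed = 1) {
  if (n_hc < 1 || n_scz < 1) {
    stop("group sizes must be >= 1", call. = FALSE)
  }
  groups <- c(rep("HC", n_hc), rep("SCZ", n_scz))
  n <- length(groups)
  ids <- sprintf("S%03d", seq_len(n))

  cm <- covariate_model
  set.seed(subject_seed(seed, 0L))
  age <- ifelse(groups == "HC",
                rnorm(n, cm$age$mean_hc, cm$age$sd_hc),
                rnorm(n, cm$age$mean_scz, cm$age$sd_scz))
  fsiq <- ifelse(groups == "HC",
                 rnorm(n, cm$fsiq$mean_hc, cm$fsiq$sd_hc),
                 rnorm(n, cm$fsiq$mean_scz, cm$fsiq$sd_scz))
  dosage <- ifelse(groups == "SCZ",
                   rlnorm(n, cm$dosage$meanlog, cm$dosage$sdlog),
                   NA_real_)
  subjects <- data.frame(subject_id = ids, group = groups, age = age,
                         fsiq = fsiq, dosage_ratio = dosage,
                         stringsAsFactors = FALSE)

  # links: standardize against the model-implied moments
  links <- lapply(cm$links, function(lk) {
    lk$center <- switch(lk$covariate,
      age = mean(c(cm$age$mean_hc, cm$age$mean_scz)),
      fsiq = mean(c(cm$fsiq$mean_hc, cm$fsiq$mean_scz)),
      dosage_ratio = exp(cm$dosage$meanlog + cm$dosage$sdlog^2 / 2))
    lk$scale <- switch(lk$covariate,
      age = mean(c(cm$age$sd_hc, cm$age$sd_scz)),
      fsiq = mean(c(cm$fsiq$sd_hc, cm$fsiq$sd_scz)),
      dosage_ratio = sqrt((exp(cm$dosage$sdlog^2) - 1) *
                          exp(2 * cm$dosage$meanlog + cm$dosage$sdlog^2)))
    lk
  })

  labels <- rownames(group_specs[[1]][[1]]$B)
  series <- vector("list", n)
  true_coupling <- vector("list", n)
  for (i in seq_len(n)) {
    covars <- list(age = age[i], fsiq = fsiq[i], dosage_ratio = dosage[i])
    adj <- .apply_links(group_specs[[groups[i]]], links, covars, labels)
    subj <- subject_record(ids[i], groups[i], age[i], fsiq[i], dosage[i])
    series[[i]] <- simulate_network_timeseries(
      adj$specs, schedule, subject = subj, seed = subject_seed(seed, i))
    true_coupling[[i]] <- adj$linked
  }
  names(series) <- ids
  names(true_coupling) <- ids
  structure(list(series = series, subjects = subjects,
                 true_coupling = true_coupling, schedule = schedule,
                 seed = seed),
            class = "cohort")
}

#' Default group-level Gompertz learning parameters
#'
#' Group means and between-subject SDs of the Gompertz triple (a, b, c) used
#' by the behavioral simulator. Controls approach a higher asymptote
#' (a = 0.9 vs 0.6), learn faster (c = 0.8 vs 0.55 per block) and reach the
#' inflection earlier (b/c = 2.5 vs ~3.6 blocks) than patients.
#'
#' @return Named list `HC`/`SCZ`, each with `mean` and `sd` vectors named
#'   a, b, c.
#' @export
default_gompertz_params <- function() {
  list(
    HC = list(mean = c(a = 0.90, b = 2.0, c = 0.80),
              sd = c(a = 0.06, b = 0.40, c = 0.12)),
    SCZ = list(mean = c(a = 0.60, b = 2.0, c = 0.55),
               sd = c(a = 0.06, b = 0.40, c = 0.12))
  )
}

#' Simulate Gompertz-governed recall behavior
#'
#' For each subject, draws (a, b, c) around the group means, evaluates the
#' Gompertz recall probability `a exp(-exp(b - c t))` at retrieval blocks
#' `t = 1..n_blocks`, and draws the number of recalled items as
#' Binomial(`n_items`, p) (or deterministic rounding of `p * n_items` in
#' noise-free mode). Fractions are therefore always multiples of
#' `1/n_items`.
#'
#' @param subjects Data frame with `subject_id` and `group` columns (for
#'   example `cohort$subjects`), or a `cohort`.
#' @param params Per-group parameter means/SDs; see
#'   [default_gompertz_params()].
#' @param n_items Items per retrieval block (default 9).
#' @param n_blocks Retrieval blocks (default 8).
#' @param seed Master seed; per-subject streams are derived from it.
#' @param noise "binomial" (default) or "none".
#' @return Long data frame `subject_id`, `group`, `block`, `n_items`,
#'   `fraction`, with the drawn per-subject true parameters in
#'   `attr(, "true_params")`.
#' @export
simulate_learning_curves <- function(subjects,
                                     params = default_gompertz_params(),
                                     n_items = 9, n_blocks = 8, seed = 1,
                                     noise = c("binomial", "none")) {
  noise <- match.arg(noise)
  if (inherits(subjects, "cohort")) subjects <- subjects$subjects
  if (n_items < 1) stop("n_items must be >= 1", call. = FALSE)
  if (n_blocks < 2) stop("n_blocks must be >= 2", call. = FALSE)
  for (g in names(params)) {
    m <- params[[g]]$mean
    pm <- gompertz_value(m["a"], m["b"], m["c"], seq_len(n_blocks))
    if (any(pm < 0 | pm > 1)) {
      stop("group '", g, "' mean curve leaves [0, 1]", call. = FALSE)
    }
  }

  n <- nrow(subjects)
  out <- vector("list", n)
  true_params <- data.frame(subject_id = subjects$subject_id,
                            group = subjects$group,
                            a = NA_real_, b = NA_real_, c = NA_real_,
                            stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    g <- subjects$group[i]
    set.seed(subject_seed(seed, i + 500000L))  # salt: distinct from fMRI stream
    p <- params[[g]]
    abc <- p$mean + p$sd * rnorm(3)
    abc["a"] <- min(max(abc["a"], 0), 1)
    abc["c"] <- max(abc["c"], 0)
    prob <- gompertz_value(abc["a"], abc["b"], abc["c"], seq_len(n_blocks))
    k <- if (noise == "binomial") rbinom(n_blocks, n_items, prob)
         else round(prob * n_items)
    out[[i]] <- data.frame(subject_id = subjects$subject_id[i], group = g,
                           block = seq_len(n_blocks), n_items = n_items,
                           fraction = k / n_items, stringsAsFactors = FALSE)
    true_params[i, c("a", "b", "c")] <- abc
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "true_params") <- true_params
  res
}
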