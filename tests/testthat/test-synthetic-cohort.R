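test_that("config validation names the offending field", {
  expect_error(cohort_config(n_modules = 1), "n_modules")
  expect_error(cohort_config(n_timepoints = 10, window_length_trs = 22),
               "n_timepoints")
  expect_error(cohort_config(motion_spike_prob = 2), "motion_spike_prob")
  expect_error(cohort_config(n_nodes = 5, n_modules = 4), "n_nodes")
})

test_that("noise-free degenerate cohort reproduces the base coupling", {
  cfg <- cohort_config(n_control = 3, n_assaulted = 3, n_nodes = 12,
                       n_modules = 3, n_timepoints = 2000, noise_sd = 0,
                       coupling_volatility = 0, trauma_effect_fc = 0,
                       trauma_effect_mod = 0, trauma_effect_tracking = 0,
                       motion_spike_prob = 0, seed = 7)
  co <- generate_cohort(cfg)
  for (s in seq_along(co$subjects)) {
    ts <- co$subjects[[s]]
    r <- cor(ts$mat[, ts$roles$amygdala], ts$mat[, ts$roles$mpfc])
    expect_lt(abs(r - cfg$coupling_base), 0.05)
  }
})

test_that("a fixed seed reproduces the cohort exactly", {
  cfg <- tiny_cohort_config(seed = 5)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$subjects[[1]]$mat, b$subjects[[1]]$mat)
  expect_identical(a$motion, b$motion)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$truth, b$truth)
})

test_that("cohort dimensions, roles, and ground truth are coherent", {
  cfg <- tiny_cohort_config(seed = 2)
  co <- generate_cohort(cfg)
  expect_length(co$subjects, 8)
  expect_equal(dim(co$subjects[[1]]$mat), c(80, 24))
  lab <- co$truth$module_labels
  expect_equal(length(lab), 24)
  expect_setequal(unique(lab), 1:4)
  roles <- co$subjects[[1]]$roles
  expect_equal(lab[roles$mpfc], 1)           # DMN
  expect_equal(lab[roles$amygdala], 2)       # limbic
  expect_true(all(lab[roles$caudate] == 2))
  expect_true(lab[roles$amygdala] != lab[roles$mpfc])
  n_win <- nrow(make_windows(80, window_spec(22, 5)))
  expect_equal(ncol(co$truth$latent_coupling), n_win)
  # assaulted group drawn with higher emotional abuse
  ab <- tapply(co$covariates$ctq_emotional_abuse, co$covariates$group, mean)
  expect_gt(ab["assaulted"], ab["control"])
})

test_that("planted abuse effect shows in empirical static bi-nodal FC", {
  cfg <- cohort_config(n_control = 100, n_assaulted = 100, n_nodes = 12,
                       n_modules = 3, n_timepoints = 225,
                       trauma_effect_fc = -0.3, seed = 2)
  co <- generate_cohort(cfg)
  fc <- vapply(co$subjects, function(ts) {
    cor(ts$mat[, ts$roles$amygdala], ts$mat[, ts$roles$mpfc])
  }, numeric(1))
  r <- cor(co$covariates$ctq_emotional_abuse, fc)
  expect_lt(r, 0)
  expect_gt(abs(r), 0.2)
})

test_that("true injected bi-nodal effect is recovered by regression at n=500", {
  cfg <- cohort_config(n_control = 250, n_assaulted = 250, n_nodes = 12,
                       n_modules = 3, n_timepoints = 30,
                       trauma_effect_fc = -0.2, trauma_effect_tracking = 0,
                       seed = 3)
  co <- generate_cohort(cfg)
  eff <- co$truth$subject_effects
  slope <- coef(lm(true_binodal_mean ~ abuse_z, data = eff))[2]
  expect_lt(abs(slope - cfg$trauma_effect_fc), 0.1 * abs(cfg$trauma_effect_fc))
})

test_that("motion traces honor the spike probability", {
  tr0 <- generate_motion_trace(225, spike_prob = 0, seed = 5)
  expect_true(all(framewise_displacement(tr0) < 0.5))
  tr1 <- generate_motion_trace(60, spike_prob = 1, seed = 5)
  expect_true(all(framewise_displacement(tr1)[-1] > 0.5))
  frac <- vapply(1:500, function(s) {
    tr <- generate_motion_trace(225, spike_prob = 0.1, seed = s)
    mean(framewise_displacement(tr) > 0.5)
  }, numeric(1))
  expect_lt(abs(mean(frac) - 0.1), 0.02)
})

test_that("cohort round-trips to plain-text files", {
  cfg <- cohort_config(n_control = 2, n_assaulted = 2, n_nodes = 9,
                       n_modules = 3, n_timepoints = 25, seed = 4)
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  mat <- as.matrix(read.table(file.path(dir, "sub001_ts.txt"), header = TRUE))
  expect_equal(unname(mat), unname(co$subjects[[1]]$mat), tolerance = 1e-12)
  cov <- read.table(file.path(dir, "covariates.tsv"), header = TRUE,
                    sep = "\t")
  expect_equal(cov$ctq_emotional_abuse, co$covariates$ctq_emotional_abuse)
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$module_labels, co$truth$module_labels)
})
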