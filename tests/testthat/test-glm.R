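test_that("canonical HRF has the expected shape", {
  expect_equal(canonical_hrf(0), 0)
  fine <- seq(0, 32, by = 0.01)
  h <- canonical_hrf(fine)
  peak_t <- fine[which.max(h)]
  expect_gte(peak_t, 4)
  expect_lte(peak_t, 7)
  expect_lt(abs(canonical_hrf(30)), 0.01 * max(h))
  k <- hrf_kernel(3.36)
  expect_equal(k[1], 0)
  expect_gt(sum(k), 0)
  expect_identical(k, hrf_kernel(3.36))
})

test_that("design matrices carry one regressor per condition-stimulus cell plus nuisance", {
  d <- make_design(1, 8, 48, seed = 1)[[1]]
  run1 <- d[d$run == 1, ]
  X <- build_design_matrix(run1, n_scans = 160, TR_s = 3.36)
  expect_equal(sum(X$columns$type == "event"), 6)
  expect_setequal(
    X$columns$label[X$columns$type == "event"],
    as.vector(outer(c("congruent", "incongruent", "no_move"),
                    c("index", "little"), paste, sep = ":")))
  expect_true(all(c("drift", "constant") %in% X$columns$label))

  nm <- run1[run1$condition == "no_move", ]
  Xnm <- build_design_matrix(nm, n_scans = 160, TR_s = 3.36)
  expect_equal(sum(Xnm$columns$type == "event"), 2)

  expect_error(build_design_matrix(d, 160, 3.36), "exactly one run")
  expect_error(build_design_matrix(run1, 10, 3.36), "past the end")
})

test_that("an event regressor is the sum of onset-shifted kernels", {
  ev <- data.frame(subject_id = "s", run = 1, trial_index = 1:2,
                   onset_s = c(8, 20), task = "finger_judgement",
                   executed = NA, observed = "index", condition = "no_move")
  X <- build_design_matrix(ev, n_scans = 30, TR_s = 2)
  t_scan <- (0:29) * 2
  expect_equal(X$X[, "no_move:index"],
               canonical_hrf(t_scan - 8) + canonical_hrf(t_scan - 20),
               ignore_attr = TRUE)
})

noiseless_fit <- function(hypothesis = "sharpening") {
  grid <- tiny_grid(4)
  spec <- population_spec(as.matrix(expand.grid(2:3, 2, 2)),
                          c("index", "little"), baseline = 50,
                          amp_preferred = 2, amp_nonpreferred = 1,
                          gain = 0.5, hypothesis = hypothesis,
                          noise_sd = 0)
  d <- make_design(1, 2, 12, seed = 4)[[1]]
  ts <- simulate_timeseries(d, grid, spec, TR_s = 2, seed = 1)
  designs <- lapply(1:2, function(r)
    build_design_matrix(d[d$run == r, ], n_scans = nrow(ts$runs[[r]]),
                        TR_s = 2))
  list(betas = fit_glm(ts, designs), spec = spec, grid = grid, d = d,
       ts = ts, designs = designs)
}

test_that("GLM recovers generating amplitudes exactly on noiseless series", {
  f <- noiseless_fit()
  pref <- popcode:::preference_vector(f$grid, f$spec)
  mask <- as.vector(f$grid$mask)
  for (cond in c("congruent", "incongruent", "no_move"))
    for (s in c("index", "little")) {
      expected <- mean_response(pref[mask], s, cond, f$spec) -
        f$spec$baseline
      fitted <- f$betas$beta[mask, 1, cond, s]
      expect_lt(max(abs(fitted - expected)), 1e-6)
    }
})

test_that("doubling the preferred amplitude doubles the recovered evoked beta", {
  f1 <- noiseless_fit()
  grid <- f1$grid
  spec2 <- population_spec(f1$spec$informative_region, f1$spec$preference,
                           baseline = 50, amp_preferred = 4,
                           amp_nonpreferred = 1, gain = 0.5,
                           hypothesis = "sharpening", noise_sd = 0)
  ts2 <- simulate_timeseries(f1$d, grid, spec2, TR_s = 2, seed = 1)
  b2 <- fit_glm(ts2, f1$designs)
  vox <- popcode:::coords_to_index(cbind(2, 2, 2), grid$shape) # index-pref
  expect_equal(b2$beta[vox, 1, "incongruent", "index"],
               2 * f1$betas$beta[vox, 1, "incongruent", "index"],
               tolerance = 1e-8)
})

test_that("OLS residuals are orthogonal to the design and intercepts absorb constants", {
  f <- noiseless_fit()
  spec_n <- population_spec(f$spec$informative_region, f$spec$preference,
                            baseline = 50, amp_preferred = 2,
                            amp_nonpreferred = 1, gain = 0.5,
                            hypothesis = "sharpening", noise_sd = 2)
  ts <- simulate_timeseries(f$d, f$grid, spec_n, TR_s = 2, seed = 3)
  X <- f$designs[[1]]$X
  Y <- ts$runs[[1]]
  resid <- Y - X %*% qr.coef(qr(X), Y)
  expect_lt(max(abs(crossprod(X, resid))), 1e-7)

  ts_shift <- ts
  ts_shift$runs[[1]] <- ts$runs[[1]] + 10
  attr(ts_shift$runs[[1]], "voxel_index") <- attr(ts$runs[[1]], "voxel_index")
  b0 <- fit_glm(ts, f$designs)
  b1 <- fit_glm(ts_shift, f$designs)
  expect_equal(b0$beta, b1$beta, tolerance = 1e-8)
})

test_that("GLM betas are unbiased: recovery within Monte-Carlo error over replicates", {
  grid <- volume_grid(c(3, 3, 3), 3)
  spec <- population_spec(cbind(2, 2, 2), "index", baseline = 10,
                          amp_preferred = 2, amp_nonpreferred = 1,
                          gain = 0.5, hypothesis = "null", noise_sd = 2)
  d <- make_design(1, 2, 12, seed = 6)[[1]]
  designs <- NULL
  vox <- popcode:::coords_to_index(cbind(2, 2, 2), grid$shape)
  est <- vapply(1:40, function(s) {
    ts <- simulate_timeseries(d, grid, spec, TR_s = 2, seed = s)
    if (is.null(designs))
      designs <<- lapply(1:2, function(r)
        build_design_matrix(d[d$run == r, ], n_scans = nrow(ts$runs[[r]]),
                            TR_s = 2))
    b <- fit_glm(ts, designs)
    mean(b$beta[vox, , "congruent", "index"])
  }, numeric(1))
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 2), 2 * mc_se + 1e-12)
})

test_that("rank-deficient designs are rejected with the collinear columns named", {
  ev <- data.frame(subject_id = "s", run = 1, trial_index = 1,
                   onset_s = 8, task = "finger_judgement",
                   executed = NA, observed = "index", condition = "no_move")
  X <- build_design_matrix(ev, n_scans = 20, TR_s = 2,
                           nuisance = cbind(dup_constant = rep(1, 20)))
  grid <- volume_grid(c(2, 2, 2), 3)
  y <- matrix(rnorm(20 * 8), 20, 8)
  attr(y, "voxel_index") <- 1:8
  ts <- structure(list(runs = list(`1` = y), TR_s = 2, grid = grid,
                       events = ev),
                  class = "timeseries_set")
  expect_error(fit_glm(ts, list(X)), "rank deficient")
})
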