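spec_fig <- function(hypothesis)
  population_spec(informative_region = cbind(2, 2, 2), preference = "index",
                  baseline = 0, amp_preferred = 2, amp_nonpreferred = 1,
                  gain = 0.5, hypothesis = hypothesis, noise_sd = 1)

test_that("mean_response implements the gain rules of both hypotheses", {
  sh <- spec_fig("sharpening")
  ca <- spec_fig("cancellation")
  # sharpening leaves tuned-toward voxels alone, halves tuned-away
  expect_equal(mean_response("index", "index", "congruent", sh), 2)
  expect_equal(mean_response("index", "little", "congruent", sh), 0.5)
  # cancellation halves tuned-toward
  expect_equal(mean_response("index", "index", "congruent", ca), 1)
  expect_equal(mean_response("index", "little", "congruent", ca), 1)
  # no modulation off congruent trials, for either hypothesis
  for (s in list(sh, ca)) for (cond in c("incongruent", "no_move")) {
    expect_equal(mean_response("index", "index", cond, s), 2)
    expect_equal(mean_response("index", "little", cond, s), 1)
  }
  # non-informative voxels sit at baseline
  expect_equal(mean_response(NA, "index", "congruent", sh), 0)
  # null hypothesis ignores the gain
  nu <- population_spec(cbind(2, 2, 2), "index", baseline = 0,
                        amp_preferred = 2, amp_nonpreferred = 1,
                        gain = 0.5, hypothesis = "null", noise_sd = 1)
  expect_equal(mean_response("index", "index", "congruent", nu), 2)
  expect_equal(mean_response("index", "little", "congruent", nu), 1)
})

pattern_distance <- function(spec, condition) {
  pref <- spec$preference
  di <- mean_response(pref, "index", condition, spec)
  dl <- mean_response(pref, "little", condition, spec)
  sqrt(sum((di - dl)^2))
}

test_that("population separability orders congruent vs incongruent as the hypotheses claim", {
  for (g in c(0.3, 0.7, 0.95)) {
    sh <- tiny_spec("sharpening", gain = g)
    ca <- tiny_spec("cancellation", gain = g)
    nu <- tiny_spec("null", gain = g)
    expect_gt(pattern_distance(sh, "congruent"),
              pattern_distance(sh, "incongruent"))
    expect_lt(pattern_distance(ca, "congruent"),
              pattern_distance(ca, "incongruent"))
    expect_equal(pattern_distance(nu, "congruent"),
                 pattern_distance(nu, "incongruent"))
  }
})

test_that("univariate signature: suppression is confined to the hypothesis's target voxels", {
  for (h in c("sharpening", "cancellation")) {
    spec <- tiny_spec(h, noise_sd = 0)
    d <- tiny_design(trials = 12, n_runs = 2)[[1]]
    b <- simulate_betas(d, tiny_grid(), spec, seed = 1)
    pref <- popcode:::preference_vector(tiny_grid(), spec)
    info <- which(!is.na(pref))
    # mean over tuned-away voxels: (voxel, stimulus) pairs where pref != stim
    away <- function(cond) mean(sapply(c("index", "little"), function(s)
      mean(b$beta[info[pref[info] != s], 1, cond, s])))
    toward <- function(cond) mean(sapply(c("index", "little"), function(s)
      mean(b$beta[info[pref[info] == s], 1, cond, s])))
    if (h == "sharpening") {
      expect_lt(away("congruent"), away("incongruent"))
      expect_equal(toward("congruent"), toward("incongruent"))
    } else {
      expect_equal(away("congruent"), away("incongruent"))
      expect_lt(toward("congruent"), toward("incongruent"))
    }
  }
})

test_that("simulated betas equal mean responses exactly in the noiseless limit", {
  spec <- tiny_spec("sharpening", noise_sd = 0)
  grid <- tiny_grid()
  d <- tiny_design(trials = 12, n_runs = 2)[[1]]
  b <- simulate_betas(d, grid, spec, seed = 1)
  pref <- popcode:::preference_vector(grid, spec)
  for (cond in c("congruent", "incongruent", "no_move"))
    for (s in c("index", "little"))
      expect_equal(b$beta[as.vector(grid$mask), 1, cond, s],
                   mean_response(pref[as.vector(grid$mask)], s, cond, spec))
})

test_that("beta simulation is seed-deterministic and fails on empty cells", {
  spec <- tiny_spec()
  d <- tiny_design(trials = 12, n_runs = 2)[[1]]
  b1 <- simulate_betas(d, tiny_grid(), spec, seed = 9)
  b2 <- simulate_betas(d, tiny_grid(), spec, seed = 9)
  expect_identical(b1, b2)
  b3 <- simulate_betas(d, tiny_grid(), spec, seed = 10)
  expect_false(identical(b1$beta, b3$beta))

  d_missing <- d[!(d$run == 2 & d$condition == "no_move" &
                     d$observed == "little"), ]
  expect_error(simulate_betas(d_missing, tiny_grid(), spec, seed = 1),
               "no trials .* run 2, condition no_move, stimulus little")
})

test_that("beta noise scales as noise_sd over the square root of trials per cell", {
  spec <- tiny_spec("null", noise_sd = 3)
  grid <- tiny_grid(4)
  d <- tiny_design(trials = 48, n_runs = 2)[[1]]   # m = 8 per cell
  draws <- vapply(1:60, function(s)
    simulate_betas(d, grid, spec, seed = s)$beta[, 1, "congruent", "index"],
    numeric(prod(grid$shape)))
  emp_sd <- mean(apply(draws, 1, sd))
  expect_equal(emp_sd, 3 / sqrt(8), tolerance = 0.05)
})

test_that("empty informative region produces pure-baseline betas", {
  spec <- population_spec(NULL, baseline = 5, hypothesis = "null",
                          noise_sd = 0)
  d <- tiny_design(trials = 6, n_runs = 2)[[1]]
  b <- simulate_betas(d, tiny_grid(4), spec, seed = 1)
  expect_true(all(b$beta[!is.na(b$beta)] == 5))
})

test_that("single-trial noiseless time series is the scaled, shifted HRF", {
  grid <- volume_grid(c(3, 3, 3), 3)
  spec <- population_spec(cbind(2, 2, 2), "index", baseline = 0,
                          amp_preferred = 2, amp_nonpreferred = 1,
                          gain = 0.5, hypothesis = "sharpening",
                          noise_sd = 0)
  ev <- data.frame(subject_id = "sub-01", run = 1, trial_index = 1,
                   onset_s = 10, task = "finger_judgement",
                   executed = NA, observed = "index", condition = "no_move")
  ts <- simulate_timeseries(ev, grid, spec, TR_s = 2, seed = 1)
  vox <- which(attr(ts$runs[[1]], "voxel_index") ==
                 popcode:::coords_to_index(cbind(2, 2, 2), grid$shape))
  t_scan <- (seq_len(nrow(ts$runs[[1]])) - 1) * 2
  expect_equal(ts$runs[[1]][, vox], 2 * canonical_hrf(t_scan - 10),
               tolerance = 1e-12)
})

test_that("time-series simulation rejects runs shorter than their last onset", {
  grid <- tiny_grid(3)
  spec <- tiny_spec(n = 3)
  d <- tiny_design(trials = 6, n_runs = 2)[[1]]
  expect_error(simulate_timeseries(d, grid, spec, TR_s = 3.36, n_scans = 5),
               "shorter than its last onset")
})
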