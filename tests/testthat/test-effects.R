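test_that("cluster means are plain voxel averages in a fully crossed table", {
  grid_shape <- c(4, 4, 4)
  mk <- function(vals) { a <- array(0.05, grid_shape); a[cbind(2:3, 2, 2)] <- vals; a }
  maps <- list(
    `sub-01` = list(congruent = mk(c(0.10, 0.20)), incongruent = mk(c(0, 0))),
    `sub-02` = list(congruent = mk(c(0.30, 0.10)), incongruent = mk(c(0.1, 0.1))))
  rois <- fake_cluster_set(cbind(2:3, 2, 2), cbind(4, 4, 4))
  tab <- extract_cluster_means(maps, rois)
  expect_equal(nrow(tab), 2 * 2 * 2)  # subjects x clusters x conditions
  expect_equal(tab$value[tab$subject_id == "sub-01" & tab$cluster == "C1" &
                           tab$condition == "congruent"], 0.15)
  # single-voxel cluster equals the voxel value
  expect_equal(tab$value[tab$subject_id == "sub-01" & tab$cluster == "C2" &
                           tab$condition == "congruent"], 0.05)

  bad <- maps
  bad[["sub-01"]]$congruent[2, 2, 2] <- NA
  expect_error(extract_cluster_means(bad, rois), "outside the volume mask")
})

test_that("rm_anova matches the brute-force SS decomposition on toy tables", {
  cases <- list(
    list(n = 4, lv = list(condition = c("congruent", "incongruent"),
                          preference = c("preferred", "nonpreferred"))),
    list(n = 5, lv = list(cluster = c("C1", "C2", "C3"),
                          condition = c("congruent", "incongruent"))),
    list(n = 6, lv = list(cluster = c("C1", "C2"),
                          condition = c("congruent", "incongruent"),
                          task = c("finger", "colour"))))
  for (k in seq_along(cases)) {
    d <- random_cell_table(cases[[k]]$n, cases[[k]]$lv, seed = 50 + k)
    got <- rm_anova(d, names(cases[[k]]$lv))
    want <- bf_rm_anova(d, names(cases[[k]]$lv))
    got <- got[match(want$effect, got$effect), ]
    expect_equal(got$F, want$F, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
    expect_equal(got$df_num, want$df_num)
    expect_equal(got$df_den, want$df_den)
    expect_equal(got$partial_eta_sq, want$partial_eta_sq, tolerance = 1e-10)
  }
})

test_that("for a two-level factor the ANOVA F equals the squared paired t", {
  d <- random_cell_table(8, list(condition = c("congruent", "incongruent")),
                         seed = 60)
  a <- rm_anova(d, "condition")
  x <- d$value[d$condition == "congruent"]
  y <- d$value[d$condition == "incongruent"]
  tt <- paired_t(x, y)
  expect_equal(a$F[a$effect == "condition"], tt$t^2, tolerance = 1e-10)
  expect_equal(a$p[a$effect == "condition"], tt$p, tolerance = 1e-10)
})

test_that("the within-subject SS decomposition is exhaustive", {
  d <- random_cell_table(5, list(A = c("a1", "a2"), B = c("b1", "b2", "b3")),
                         seed = 61)
  want <- bf_rm_anova(d, c("A", "B"))
  ss_subject <- bf_ss(d, "subject_id", "value")
  total <- sum((d$value - mean(d$value))^2)
  expect_equal(sum(want$ss_effect) + sum(want$ss_error) + ss_subject, total,
               tolerance = 1e-10)
})

test_that("identical condition values give zero F, and missing cells error", {
  d <- random_cell_table(6, list(condition = c("congruent", "incongruent")),
                         seed = 62)
  # subject effects plus within-subject noise whose condition means are
  # exactly equal: the condition effect SS is zero, the error SS is not
  d$value <- rep(rnorm(6), 2) + c(1, -1, 2, -2, 3, -3,
                                  -1, 1, -2, 2, -3, 3)
  a <- rm_anova(d, "condition")
  expect_lt(a$F[a$effect == "condition"], 1e-10)

  d2 <- random_cell_table(4, list(condition = c("congruent", "incongruent")),
                          seed = 63)
  expect_error(rm_anova(d2[-1, ], "condition"), "not fully crossed")
})

test_that("paired_t matches hand computation and its symmetries", {
  x <- c(2, 3, 4)
  y <- c(1, 1, 1)
  r <- paired_t(x, y)
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$p, 2 * pt(-abs(r$t), 2), tolerance = 1e-12)
  expect_equal(paired_t(y, x)$t, -r$t)

  same <- paired_t(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  shifted <- paired_t(x, x - 1)   # constant difference: zero variance
  expect_true(shifted$flagged)
  expect_true(is.infinite(shifted$t))
})

test_that("within-participant CI half-width follows the difference-SD formula", {
  set.seed(64)
  n <- 20
  base <- rnorm(n)
  diffs <- rnorm(n, 0, 0.1)
  d <- data.frame(
    subject_id = rep(sprintf("s%02d", 1:n), 2),
    condition = rep(c("congruent", "incongruent"), each = n),
    value = c(base + diffs, base))
  ci <- within_subject_ci(d, "condition")
  expect_equal(ci$half_width,
               qt(0.975, n - 1) * sd(diffs) / sqrt(n) / sqrt(2),
               tolerance = 1e-12)
  # closed-form spot value: SD 0.1 with n = 20 gives about 0.0331
  expect_equal(qt(0.975, 19) * 0.1 / sqrt(20) / sqrt(2), 0.0331,
               tolerance = 1e-3)

  # identical conditions give zero width; scaling is homogeneous
  d0 <- d
  d0$value <- rep(base, 2)
  expect_equal(within_subject_ci(d0, "condition")$half_width, 0)
  d3 <- d
  d3$value <- 3 * d$value
  expect_equal(within_subject_ci(d3, "condition")$half_width,
               3 * ci$half_width, tolerance = 1e-12)

  d$value2 <- d$value
  dd <- rbind(d, d)
  dd$condition <- rep(c("a", "b", "c", "d"), each = n)
  expect_error(within_subject_ci(dd, "condition"), "exactly 2")
})

test_that("the congruency ANOVA rejects at the nominal rate under the null", {
  set.seed(65)
  n_rep <- 250
  hits <- replicate(n_rep, {
    d <- data.frame(
      subject_id = rep(sprintf("s%02d", 1:8), times = 4),
      cluster = rep(c("C1", "C2"), each = 16),
      condition = rep(rep(c("congruent", "incongruent"), each = 8), 2),
      value = rnorm(32))
    a <- rm_anova(d, c("cluster", "condition"))
    a$p[a$effect == "condition"] < 0.05
  })
  expect_gte(sum(hits), qbinom(0.025, n_rep, 0.05))
  expect_lte(sum(hits), qbinom(0.975, n_rep, 0.05))
})
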