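test_that("planted correlations are recovered at large frame counts", {
  part <- default_partition()
  pl <- planted_component(part, n_a = 2, n_b = 2, r = 0.3)
  cfg <- sim_config(n_patients = 3, n_controls = 3, n_frames = 2000,
                    planted_edges = pl, seed = 81)
  study <- generate_study(cfg, keep_timeseries = FALSE)$study
  pat <- study$group == "patient"
  for (k in seq_len(nrow(pl))) {
    ia <- pl$region_a[k]; ib <- pl$region_b[k]
    r_pat <- tanh(mean(vapply(study$matrices[pat],
                              function(m) m[ia, ib], 0)))
    r_ctl <- tanh(mean(vapply(study$matrices[!pat],
                              function(m) m[ia, ib], 0)))
    expect_lt(abs(r_pat - 0.3), 0.05)
    expect_lt(abs(r_ctl + 0.3), 0.05)
  }
})

test_that("identity baseline with no planted edges gives near-zero mean z", {
  cfg <- sim_config(n_patients = 6, n_controls = 6, n_frames = 200,
                    baseline_within_r = 0, baseline_between_r = list(),
                    seed = 82)
  study <- generate_study(cfg, keep_timeseries = FALSE)$study
  zbar <- mean(vapply(study$matrices, function(m) mean(m[upper.tri(m)]), 0))
  expect_lt(abs(zbar), 0.005)
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_patients = 3, n_controls = 3, n_frames = 50, seed = 83)
  a <- generate_study(cfg)
  b <- generate_study(cfg)
  expect_identical(a$study$matrices, b$study$matrices)
  expect_identical(a$timeseries[[1]]$data, b$timeseries[[1]]$data)
  expect_identical(a$study$covariates, b$study$covariates)
  cfg2 <- cfg; cfg2$seed <- 84
  expect_false(identical(generate_study(cfg2)$study$matrices,
                         a$study$matrices))
})

test_that("infeasible target correlations are repaired to a valid matrix", {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.9
  R[1, 3] <- R[3, 1] <- 0.9
  R[2, 3] <- R[3, 2] <- -0.9   # impossible triple
  expect_lt(min(eigen(R, symmetric = TRUE)$values), 0)
  R2 <- repair_correlation(R)
  expect_gte(min(eigen(R2, symmetric = TRUE)$values), 0)
  expect_equal(diag(R2), rep(1, 3))
  expect_identical(R2, t(R2))
  # already-valid matrices pass through untouched
  R3 <- diag(2); R3[1, 2] <- R3[2, 1] <- 0.5
  expect_identical(repair_correlation(R3), R3)
})

test_that("the control group of a study carries the negative between-network baseline", {
  part <- default_partition()
  cfg <- sim_config(n_patients = 4, n_controls = 4, n_frames = 800, seed = 85)
  study <- generate_study(cfg, keep_timeseries = FALSE)$study
  ctl <- study$matrices[study$group == "control"]
  w <- mean(vapply(ctl, function(m)
    between_strength(m, part, "sensory-motor", "auditory"), 0))
  expect_lt(w, -0.08)
  within <- mean(vapply(ctl, function(m)
    within_strength(m, part, "visual"), 0))
  expect_gt(within, 0.2)
})

test_that("null edges pass the sign-test mask at the exact binomial rate", {
  # independent-edge null: inclusion probability per edge is the exact
  # union rate of the two per-group majority-tail binomial tests
  rate_for <- function(n) {
    k <- 0:n
    tailp <- vapply(pmax(k, n - k), function(kk)
      pbinom(kk - 1, n, 0.5, lower.tail = FALSE), 0)
    sum(dbinom(k, n, 0.5) * (tailp <= 0.05))
  }
  n1 <- 33; n2 <- 24
  expected <- 1 - (1 - rate_for(n1)) * (1 - rate_for(n2))
  cfg <- sim_config(baseline_within_r = 0, baseline_between_r = list(),
                    n_frames = 100, seed = 86)
  study <- generate_null_study(cfg)
  mask <- nonzero_mask(study)
  observed <- mean(mask[upper.tri(mask)])
  expect_equal(observed, expected, tolerance = 0.015)
})

test_that("clinical coupling links the planted edge to the covariate", {
  part <- default_partition()
  pl <- planted_component(part, n_a = 2, n_b = 2, r = 0.15)
  cfg <- sim_config(n_patients = 30, n_controls = 4, n_frames = 500,
                    planted_edges = pl, clinical_variable = "FPG",
                    clinical_effect = 0.15, seed = 87)
  study <- generate_study(cfg, keep_timeseries = FALSE)$study
  pat <- study$group == "patient"
  ev <- vapply(study$matrices[pat],
               function(m) m[pl$region_a[1], pl$region_b[1]], 0)
  fpg <- study$covariates$FPG[pat]
  expect_gt(cor(ev, fpg), 0.3)
})
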