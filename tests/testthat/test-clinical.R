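test_that("summary t-test equals a raw-data t-test on reconstructed samples", {
  # reconstruct samples with exactly the requested mean and sd, then
  # compare against stats::t.test as the oracle
  remake <- function(m, s, n) {
    x <- seq_len(n)
    m + s * (x - mean(x)) / sd(x)
  }
  set.seed(71)
  for (rep in 1:20) {
    m1 <- rnorm(1, 50, 10); m2 <- rnorm(1, 50, 10)
    s1 <- runif(1, 0.5, 15); s2 <- runif(1, 0.5, 15)
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    got <- ttest_from_summary(m1, s1, n1, m2, s2, n2)
    ref <- t.test(remake(m1, s1, n1), remake(m2, s2, n2), var.equal = TRUE)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$p, ref$p.value, tolerance = 1e-9)
    expect_equal(got$df, unname(ref$parameter))
  }
})

test_that("degenerate zero-variance summaries are handled explicitly", {
  same <- ttest_from_summary(5, 0, 10, 5, 0, 10)
  expect_equal(same$p, 1)
  expect_equal(same$t, 0)
  diff <- ttest_from_summary(5, 0, 10, 6, 0, 10)
  expect_equal(diff$p, 0)
  expect_true(diff$degenerate)
})

test_that("chi-square matches the hand Pearson formula and is transpose-invariant", {
  flat <- chisq_2x2(10, 10, 10, 10)
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p, 1)
  got <- chisq_2x2(20, 10, 10, 20)
  # hand Pearson: sum (O - E)^2 / E with all E = 15
  expect_equal(got$chi2, 4 * 25 / 15, tolerance = 1e-10)
  expect_equal(got$chi2, 6.667, tolerance = 1e-3)
  expect_equal(chisq_2x2(20, 10, 10, 20)$chi2,
               chisq_2x2(20, 10, 10, 20)$chi2)
  expect_equal(chisq_2x2(3, 7, 5, 9)$chi2, chisq_2x2(3, 5, 7, 9)$chi2)
  expect_error(chisq_2x2(0, 0, 3, 4), "marginal")
})

test_that("bundled demographics table reproduces its printed p-values", {
  tab <- summary_table_tests(read_summary_table())
  p_of <- function(v) tab$p[tab$variable == v]
  expect_lt(abs(p_of("HOMA_IR") - 0.012), 0.002)
  expect_lt(abs(p_of("HOMA_beta_pct") - 0.001), 0.002)
  expect_lt(abs(p_of("Systolic_BP_mmHg") - 0.969), 0.002)
  expect_lt(abs(p_of("Diastolic_BP_mmHg") - 0.513), 0.002)
  expect_lt(abs(p_of("Age_years") - 0.194), 0.003)
})

test_that("adjusted association recovers an exact linear relationship", {
  set.seed(72)
  n <- 33
  v <- rnorm(n, 8, 3)
  res <- suppressWarnings(  # lm flags the intentionally perfect fit
    adjusted_association(v, v, rnorm(n, 50, 10), rbinom(n, 1, 0.5),
                         rnorm(n, 13, 3)))
  expect_equal(res$coefficient, 1, tolerance = 1e-10)
  expect_lt(res$p, 1e-20)
})

test_that("adjusted association errors on collinear designs", {
  set.seed(73)
  n <- 20
  age <- rnorm(n, 50, 10)
  expect_error(
    adjusted_association(rnorm(n), 2 * age + 1, age, rbinom(n, 1, 0.5),
                         rnorm(n, 13, 3)),
    "collinear")
})

test_that("zero-variance covariates reduce the model to a plain correlation test", {
  set.seed(74)
  n <- 30
  edge <- rnorm(n); v <- 0.3 * edge + rnorm(n)
  res <- adjusted_association(edge, v, rep(50, n), rep(1, n), rep(12, n))
  ref <- cor.test(edge, v)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-10)
})

test_that("type-I error and slope coverage behave nominally", {
  null <- slope_recovery(n_sims = 400, slope = 0, seed = 75)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 400)
  expect_gte(null$type1, ci[1])
  expect_lte(null$type1, ci[2])
  rec <- slope_recovery(n_sims = 400, slope = 0.05, seed = 76)
  expect_gte(rec$coverage, 0.93)
  expect_lt(abs(mean(rec$estimates) - 0.05), 0.005)
})

test_that("edge-wise clinical associations run over a study's covariates", {
  set.seed(77)
  cfg <- sim_config(n_patients = 20, n_controls = 10, n_frames = 60,
                    clinical_effect = 0, seed = 78)
  study <- generate_study(cfg, keep_timeseries = FALSE)$study
  edges <- data.frame(region_a = study$regions[1],
                      region_b = study$regions[2])
  out <- edge_clinical_associations(study, edges, c("FPG", "MoCA"))
  expect_equal(nrow(out), 2)
  expect_true(all(out$p > 0 & out$p <= 1))
  out2 <- edge_clinical_associations(study, edges, c("FPG", "MoCA"),
                                     p_adjust = "BH")
  expect_true(all(out2$p_adj >= out2$p))
})
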