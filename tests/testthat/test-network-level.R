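make_named_matrix <- function(part, fill) {
  regions <- names(part$assignment)
  n <- length(regions)
  m <- matrix(0, n, n, dimnames = list(regions, regions))
  m[upper.tri(m)] <- fill
  m <- m + t(m)
  m
}

test_that("within-network strength averages the distinct pairs", {
  part <- tiny_partition()
  m <- make_named_matrix(part, 0)
  m["A1", "A2"] <- m["A2", "A1"] <- 0.1
  m["A1", "A3"] <- m["A3", "A1"] <- 0.2
  m["A2", "A3"] <- m["A3", "A2"] <- 0.6
  expect_equal(within_strength(m, part, "alpha"), 0.3)
  m["B1", "B2"] <- m["B2", "B1"] <- 0.7
  expect_equal(within_strength(m, part, "beta"), 0.7)
  # constant block averages to the constant
  m2 <- make_named_matrix(part, 0.42)
  expect_equal(within_strength(m2, part, "alpha"), 0.42)
  expect_error(within_strength(m, part, "gamma"), "fewer than 2")
})

test_that("between-network strength averages the cross block symmetrically", {
  part <- tiny_partition()
  m <- make_named_matrix(part, 0)
  m["A1", "B1"] <- m["B1", "A1"] <- 0.1
  m["A1", "B2"] <- m["B2", "A1"] <- 0.3
  m["A2", "B1"] <- m["B1", "A2"] <- 0.5
  m["A2", "B2"] <- m["B2", "A2"] <- 0.7
  part2 <- network_partition(c(A1 = "alpha", A2 = "alpha",
                               B1 = "beta", B2 = "beta"))
  m4 <- m[c("A1", "A2", "B1", "B2"), c("A1", "A2", "B1", "B2")]
  expect_equal(between_strength(m4, part2, "alpha", "beta"), 0.4)
  expect_equal(between_strength(m4, part2, "alpha", "beta"),
               between_strength(m4, part2, "beta", "alpha"))
  # singleton networks reduce to the single entry
  expect_equal(between_strength(m, part, "gamma", "beta"),
               mean(m["C1", c("B1", "B2")]))
  expect_error(between_strength(m, part, "alpha", "alpha"),
               "within_strength")
})

test_that("the 28 strengths decompose the global off-diagonal mean exactly", {
  part <- default_partition()
  set.seed(61)
  for (rep in 1:10) {
    m <- make_named_matrix(part, rnorm(116 * 115 / 2))
    s <- network_strengths(m, part)
    sizes <- table(factor(part$assignment, levels = part$networks))
    w_within <- sizes * (sizes - 1) / 2
    pairs <- combn(part$networks, 2)
    w_between <- sizes[pairs[1, ]] * sizes[pairs[2, ]]
    wts <- c(w_within, w_between)
    expect_equal(sum(s * wts) / sum(wts), mean(m[upper.tri(m)]),
                 tolerance = 1e-13)
  }
})

test_that("strengths are invariant to region ordering", {
  part <- default_partition()
  set.seed(62)
  m <- make_named_matrix(part, rnorm(116 * 115 / 2))
  perm <- sample(116)
  expect_equal(network_strengths(m, part),
               network_strengths(m[perm, perm], part))
})

test_that("group comparison applies BH across the 28-measure family", {
  part <- default_partition()
  set.seed(63)
  study <- generate_block_shift_study(1.2, part)
  tab <- compare_network_strengths(study, part)
  expect_equal(nrow(tab), 28)
  expect_equal(sum(tab$scope == "within"), 7)
  expect_equal(sum(tab$scope == "between"), 21)
  expect_equal(tab$p_fdr, p.adjust(tab$p, "BH"))
  # hand BH step-up oracle on a small p set
  p <- c(0.001, 0.02, 0.9)
  m <- length(p)
  thresh <- 0.05 * seq_len(m) / m
  k <- max(which(sort(p) <= thresh))
  expect_equal(sort(p)[seq_len(k)], c(0.001, 0.02))
  expect_equal(which(p.adjust(p, "BH") < 0.05), c(1, 2))
})

test_that("a planted between-network shift is flagged at the oracle rate", {
  # power at d = 1.2 checked against the noncentral-t prediction band:
  # BH's data-dependent threshold lies between q/28 and q per measure
  res <- network_level_power(n_sims = 60, d = 1.2, seed = 64)
  se <- sqrt(res$power_analytic_hi * (1 - res$power_analytic_lo) / 60)
  expect_gte(res$power, res$power_analytic_lo - 2.5 * se)
  expect_lte(res$power, 1)
  expect_gt(res$power, 0.7)
  # false flags behave like an FDR-controlled family
  expect_lte(res$fdr_observed,
             0.05 + 2 * sqrt(0.05 * 0.95 / 60))
})

test_that("identical groups yield no significant network differences", {
  part <- network_partition(c(A1 = "alpha", A2 = "alpha", A3 = "alpha",
                              B1 = "beta", B2 = "beta", C1 = "gamma",
                              C2 = "gamma"))
  set.seed(65)
  mats <- lapply(1:8, function(i) make_named_matrix(part, rnorm(21, 0, 0.1)))
  # duplicate the same matrices in both groups: every t is exactly 0
  study <- group_study(c(mats, mats), rep(c("control", "patient"), each = 8))
  tab <- compare_network_strengths(study, part)
  expect_true(all(abs(tab$t) < 1e-12))
  expect_true(all(tab$p > 0.999))
  expect_false(any(tab$significant))
})
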