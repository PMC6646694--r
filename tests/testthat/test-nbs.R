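test_that("sign test matches exact binomial tails", {
  expect_equal(sign_test_p(rep(1, 30)), 0.5^30)
  x <- c(rep(1, 15), rep(-1, 15))
  expect_equal(sign_test_p(x),
               sum(dbinom(15:30, 30, 0.5)))
  expect_gt(sign_test_p(x), 0.05)
  expect_equal(sign_test_p(c(0, 0, 0)), 1)
  # zeros are dropped before counting
  expect_equal(sign_test_p(c(0, 1, 1, 1)), 0.5^3)
})

test_that("connection mask takes the union of per-group sign tests", {
  set.seed(41)
  n1 <- 16; n2 <- 16
  # edge 1: consistent positive in group 2 (controls) only
  # edge 2: consistent in both; edge 3: balanced in both
  g1 <- cbind(rnorm(n1, 0, 1), abs(rnorm(n1)) + 0.1,
              rep(c(1, -1), n1 / 2))
  g2 <- cbind(abs(rnorm(n2)) + 0.1, abs(rnorm(n2)) + 0.1,
              rep(c(1, -1), n2 / 2))
  study <- study_from_edges(rbind(g2, g1),
                            rep(c("control", "patient"), c(n2, n1)))
  mask <- nonzero_mask(study, alpha = 0.05)
  em <- mask[upper.tri(mask)][1:3]
  expect_true(em[1])   # union rule: one group suffices
  expect_true(em[2])
  expect_false(em[3])  # 8/16 positive is far from significant
  expect_false(any(diag(mask)))
  expect_identical(mask[lower.tri(mask)][1], mask[upper.tri(mask)][1])
})

test_that("edge t tests reproduce the pooled two-sample statistic", {
  study <- study_from_edges(matrix(c(1, 2, 3, 4, 5, 6), 6, 1),
                            rep(c("patient", "control"), each = 3))
  st <- edge_t_tests(study)
  expect_equal(st$t[1, 2], -3.674, tolerance = 1e-3)
  expect_equal(st$df, 4)
  # swapping the labels negates t
  study2 <- study_from_edges(matrix(c(1, 2, 3, 4, 5, 6), 6, 1),
                             rep(c("control", "patient"), each = 3))
  expect_equal(edge_t_tests(study2)$t[1, 2], -st$t[1, 2])
  # identical groups: t = 0, one-tailed p = 0.5
  study3 <- study_from_edges(matrix(c(1, 2, 3, 1, 2, 3), 6, 1),
                             rep(c("patient", "control"), each = 3))
  st3 <- edge_t_tests(study3)
  expect_equal(st3$t[1, 2], 0)
  expect_equal(st3$p_patient_gt[1, 2], 0.5)
  # agreement with stats::t.test on random data
  set.seed(42)
  vals <- matrix(rnorm(40), 20, 2)
  grp <- rep(c("control", "patient"), 10)
  # the helper pads to 3 regions, so one all-zero edge is excluded
  expect_warning(st4 <- edge_t_tests(study_from_edges(vals, grp)),
                 "zero pooled variance")
  ref <- t.test(vals[grp == "patient", 1], vals[grp == "control", 1],
                var.equal = TRUE)
  expect_equal(st4$t[1, 2], unname(ref$statistic), tolerance = 1e-12)
})

test_that("suprathreshold components match hand-built graphs", {
  # edges (1,2), (2,3), (4,5): components of size 2 and 1
  tm <- matrix(0, 6, 6, dimnames = list(paste0("R", 1:6), paste0("R", 1:6)))
  tm[1, 2] <- tm[2, 3] <- tm[4, 5] <- 5
  st <- stats_from_t(tm)
  comps <- suprathreshold_components(st, t_threshold = 3)
  expect_length(comps, 2)
  expect_equal(unname(vapply(comps, `[[`, 0L, "size")), c(2L, 1L))
  expect_setequal(unlist(comps[[1]]$edges[, c("region_a", "region_b")]),
                  c("R1", "R2", "R2", "R3"))
  # a chain over k nodes is one component of k - 1 edges
  k <- 7
  tm2 <- matrix(0, k, k, dimnames = list(paste0("N", 1:k), paste0("N", 1:k)))
  for (i in 1:(k - 1)) tm2[i, i + 1] <- 4
  comps2 <- suprathreshold_components(stats_from_t(tm2), t_threshold = 3)
  expect_length(comps2, 1)
  expect_equal(comps2[[1]]$size, k - 1L)
  # no suprathreshold edges: empty list, not an error
  expect_length(suprathreshold_components(st, t_threshold = 10), 0)
  # p-threshold form must agree with the equivalent t cut
  pcomp <- suprathreshold_components(st, p_threshold = 0.05)
  tcomp <- suprathreshold_components(st, t_threshold = qt(0.95, st$df))
  expect_equal(pcomp, tcomp)
  expect_error(suprathreshold_components(st), "exactly one")
})

test_that("component sizes agree with a breadth-first-search oracle", {
  set.seed(43)
  n <- 20
  for (rep in 1:60) {
    tm <- matrix(0, n, n, dimnames = list(paste0("R", 1:n), paste0("R", 1:n)))
    tm[upper.tri(tm)] <- ifelse(runif(n * (n - 1) / 2) < 0.08, 5, 0)
    comps <- suprathreshold_components(stats_from_t(tm), t_threshold = 3)
    got <- unname(sort(vapply(comps, `[[`, 0L, "size"), decreasing = TRUE))
    edges <- which(upper.tri(tm) & tm > 3, arr.ind = TRUE)
    expect_identical(got, bfs_component_edge_sizes(edges, n))
  }
})

test_that("permutation p-values hit the +1 estimator boundaries", {
  set.seed(44)
  # large planted difference on a 3-edge triangle: observed max beats
  # every permutation
  n1 <- 10; n2 <- 10
  base <- matrix(rnorm((n1 + n2) * 6, 0, 0.1), n1 + n2, 6)
  base[1:n1, 1:3] <- base[1:n1, 1:3] + 3
  study <- study_from_edges(base, rep(c("patient", "control"), c(n1, n2)))
  res <- nbs_permutation(study, t_threshold = 3, n_perm = 199, seed = 1)
  expect_gte(length(res$components), 1)
  expect_equal(res$components[[1]]$p_fwe, 1 / 200)
  expect_length(res$null_max_sizes, 199)
  # threshold below every t with a fixed all-edge mask: the observed graph
  # equals every permutation's graph, so p = 1
  n <- length(study$regions)
  allmask <- matrix(TRUE, n, n, dimnames = list(study$regions, study$regions))
  diag(allmask) <- FALSE
  res2 <- nbs_permutation(study, mask = allmask, t_threshold = -100,
                          n_perm = 199, seed = 1)
  expect_equal(res2$components[[1]]$p_fwe, 1)
  expect_warning(nbs_permutation(study, t_threshold = 3, n_perm = 50,
                                 seed = 1),
                 "coarse")
})

test_that("nbs runs are seed-reproducible and relabel-invariant", {
  set.seed(45)
  vals <- matrix(rnorm(20 * 10), 20, 10)
  grp <- rep(c("patient", "control"), 10)
  study <- study_from_edges(vals, grp)
  r1 <- nbs_permutation(study, t_threshold = 1.5, n_perm = 120, seed = 9)
  r2 <- nbs_permutation(study, t_threshold = 1.5, n_perm = 120, seed = 9)
  expect_identical(r1, r2)
  # permuting region order permutes components but not sizes or p-values
  perm <- c(3, 1, 5, 2, 4)
  mats2 <- lapply(study$matrices, function(m) m[perm, perm])
  study2 <- group_study(mats2, study$group)
  r3 <- nbs_permutation(study2, t_threshold = 1.5, n_perm = 120, seed = 9)
  sizes <- function(r) sort(vapply(r$components, `[[`, 0L, "size"))
  pf <- function(r) sort(vapply(r$components, `[[`, 0, "p_fwe"))
  expect_identical(sizes(r1), sizes(r3))
  expect_equal(pf(r1), pf(r3))
  expect_identical(r1$null_max_sizes, r3$null_max_sizes)
})

test_that("raising the primary threshold never grows a component", {
  set.seed(46)
  vals <- matrix(rnorm(24 * 15), 24, 15) +
    matrix(rep(c(0.5, 0), c(12, 12)), 24, 15)
  study <- study_from_edges(vals, rep(c("patient", "control"), each = 12))
  st <- edge_t_tests(study)
  cuts <- c(0.5, 1, 1.5, 2, 2.5, 3)
  maxes <- vapply(cuts, function(cc) {
    comps <- suprathreshold_components(st, t_threshold = cc)
    if (length(comps) == 0) 0L else comps[[1]]$size
  }, 0L)
  expect_true(all(diff(maxes) <= 0))
})
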