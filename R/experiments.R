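# Calibration and power experiments over the synthetic-study generator.
# These drive the analysis scripts, the test suite's statistical checks,
# and the acceptance report, from one code path.

derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Familywise-error calibration of the NBS pass
#'
#' Generates `n_studies` null studies (both groups share the baseline
#' correlation structure), runs the full NBS pass on each (sign-test mask,
#' pooled-t edges, permutation max-component null), and reports how often
#' any component reaches `p_fwe < alpha`. Under correct FWE control this
#' familywise false-positive rate should not exceed `alpha` up to binomial
#' noise.
#'
#' @param n_studies Number of simulated null studies (default 200).
#' @param n_perm Permutations per study (default 500).
#' @param t_threshold Primary threshold (default 3).
#' @param alpha Component significance level (default 0.05).
#' @param tail Direction of the one-tailed NBS pass (default patient_gt;
#'   FWE is controlled per pass).
#' @param config Base [sim_config()] (default study conditions).
#' @param seed Master seed; per-study seeds derive from it.
#' @return List: `any_significant` (logical per study), `rate`, and the
#'   95% upper binomial bound `bound` for `alpha` at this `n_studies`.
#' @export
fwe_calibration <- function(n_studies = 200, n_perm = 500, t_threshold = 3,
                            alpha = 0.05, tail = "patient_gt",
                            config = sim_config(), seed = 1) {
  seeds <- derive_seeds(seed, 2 * n_studies)
  any_sig <- logical(n_studies)
  for (i in seq_len(n_studies)) {
    config$seed <- seeds[i]
    study <- generate_null_study(config)
    res <- nbs_permutation(study, t_threshold = t_threshold, tail = tail,
                           n_perm = n_perm, seed = seeds[n_studies + i])
    any_sig[i] <- any(vapply(res$components, `[[`, 0, "p_fwe") < alpha)
  }
  list(any_significant = any_sig, rate = mean(any_sig),
       bound = stats::qbinom(0.95, n_studies, alpha) / n_studies)
}

#' Detection power for a planted edge component
#'
#' Plants a connected between-network component of `n_a * n_b` sign-flipped
#' edges at per-edge effect size `d` (Fisher-z gap `d / sqrt(frames - 3)`),
#' runs the full pipeline per simulation, and counts a detection when a
#' component with `p_fwe < alpha` consists mostly (> 50%) of planted edges.
#' Also classifies the planted edges recovered in significant components
#' by their change pattern, to measure how often the planted sign flip is
#' labelled pathological-positive.
#'
#' @param n_sims Number of simulated studies (default 100).
#' @param d Per-edge Cohen's d (default 1).
#' @param n_perm Permutations per study (default 1000).
#' @param t_threshold Primary threshold (default 3).
#' @param alpha Component significance level (default 0.05).
#' @param n_a,n_b Planted bipartite hub sizes (default 6 x 5 = 30 edges).
#' @param config Base [sim_config()].
#' @param seed Master seed.
#' @return List: `detected` (logical per sim), `power`, `n_planted_found`,
#'   `n_pathological` (per sim), and the pooled fraction
#'   `pattern_recovery` of recovered planted edges labelled
#'   pathological-positive.
#' @export
planted_power <- function(n_sims = 100, d = 1, n_perm = 1000,
                          t_threshold = 3, alpha = 0.05, n_a = 6, n_b = 5,
                          config = sim_config(), seed = 1) {
  dz <- planted_z_offset(d, config$n_frames)
  planted <- planted_component(config$partition, n_a = n_a, n_b = n_b,
                               r = tanh(dz / 2))
  config$planted_edges <- planted
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  planted_keys <- key(planted$region_a, planted$region_b)
  seeds <- derive_seeds(seed, 2 * n_sims)
  detected <- logical(n_sims)
  n_found <- n_path <- integer(n_sims)
  for (i in seq_len(n_sims)) {
    config$seed <- seeds[i]
    study <- generate_study(config, keep_timeseries = FALSE)$study
    res <- nbs_permutation(study, t_threshold = t_threshold,
                           tail = "patient_gt", n_perm = n_perm,
                           seed = seeds[n_sims + i])
    stats <- edge_t_tests(study, res$mask)
    for (cp in res$components) {
      if (cp$p_fwe >= alpha) next
      hit <- key(cp$edges$region_a, cp$edges$region_b) %in% planted_keys
      if (mean(hit) > 0.5) detected[i] <- TRUE
      if (!any(hit)) next
      e <- cp$edges[hit, ]
      ia <- match(e$region_a, study$regions)
      ib <- match(e$region_b, study$regions)
      pat <- classify_edge(stats$mean_patient[cbind(ia, ib)],
                           stats$mean_control[cbind(ia, ib)])
      n_found[i] <- n_found[i] + nrow(e)
      n_path[i] <- n_path[i] + sum(pat == "pathological_positive")
    }
  }
  list(detected = detected, power = mean(detected),
       n_planted_found = n_found, n_pathological = n_path,
       pattern_recovery = sum(n_path) / max(1, sum(n_found)))
}

#' Matrix-level two-group study with a shifted network block
#'
#' Generates subject Fisher-z matrices directly (iid Gaussian edge noise
#' around a zero baseline) with the patient group's `network_a` x
#' `network_b` between-network block shifted so that the block-mean
#' strength W differs by `d` standard deviations between groups. Used for
#' network-level power checks where the effect size on W must be exact.
#'
#' @param d Effect size on the block-mean strength (Cohen's d).
#' @param partition A [network_partition()].
#' @param n_patients,n_controls Group sizes.
#' @param edge_sd Per-edge noise sd (default 0.0645, the sampling sd of a
#'   single-subject Fisher z at 243 frames).
#' @param network_a,network_b The shifted block.
#' @return A [group_study()].
#' @export
generate_block_shift_study <- function(d, partition = default_partition(),
                                       n_patients = 33, n_controls = 24,
                                       edge_sd = 1 / sqrt(240),
                                       network_a = "sensory-motor",
                                       network_b = "auditory") {
  regions <- names(partition$assignment)
  n <- length(regions)
  ia <- which(partition$assignment == network_a)
  ib <- which(partition$assignment == network_b)
  # W is the mean of the n_a*n_b iid block entries, so its sd is
  # edge_sd / sqrt(n_a * n_b); a d-sd shift of W needs delta = d * that
  delta <- d * edge_sd / sqrt(length(ia) * length(ib))
  make <- function(shift) {
    m <- matrix(0, n, n, dimnames = list(regions, regions))
    z <- stats::rnorm(n * (n - 1) / 2, 0, edge_sd)
    m[upper.tri(m)] <- z
    m <- m + t(m)
    if (shift != 0) {
      m[ia, ib] <- m[ia, ib] + shift
      m[ib, ia] <- t(m[ia, ib])
    }
    m
  }
  mats <- c(lapply(seq_len(n_controls), function(i) make(0)),
            lapply(seq_len(n_patients), function(i) make(delta)))
  group_study(mats, factor(rep(c("control", "patient"),
                               c(n_controls, n_patients)),
                           levels = c("control", "patient")))
}

#' Network-level planted-effect power
#'
#' Repeatedly generates [generate_block_shift_study()] data, compares all
#' 28 network strengths with [compare_network_strengths()], and reports
#' how often the shifted block is flagged after FDR correction, the
#' false-flag count on the other 27 measures, and the analytic power
#' predicted by the noncentral-t distribution at the single-measure
#' Benjamini-Hochberg threshold `q/m` (a lower bound on BH power).
#'
#' @param n_sims Number of simulations (default 100).
#' @param d Effect size on the planted block-mean strength (default 1.2).
#' @param q FDR level (default 0.05).
#' @param partition A [network_partition()].
#' @param seed Master seed.
#' @return List: `hit` (planted row significant, per sim), `power`,
#'   `false_flags` (per sim count), `fdr_observed`, `power_analytic_lo`
#'   and `power_analytic_hi` (noncentral-t power at thresholds q/m and q).
#' @export
network_level_power <- function(n_sims = 100, d = 1.2, q = 0.05,
                                partition = default_partition(), seed = 1) {
  seeds <- derive_seeds(seed, n_sims)
  target <- "between:sensory-motor|auditory"
  hit <- logical(n_sims)
  fp <- integer(n_sims)
  for (i in seq_len(n_sims)) {
    set.seed(seeds[i])
    study <- generate_block_shift_study(d, partition)
    tab <- compare_network_strengths(study, partition, q = q)
    hit[i] <- tab$significant[tab$measure == target]
    fp[i] <- sum(tab$significant[tab$measure != target])
  }
  n1 <- 33; n2 <- 24; df <- n1 + n2 - 2
  ncp <- d / sqrt(1 / n1 + 1 / n2)
  pow <- function(alpha) {
    cut <- stats::qt(1 - alpha / 2, df)
    stats::pt(cut, df, ncp, lower.tail = FALSE) +
      stats::pt(-cut, df, ncp)
  }
  fdp <- fp / pmax(1, fp + hit)
  list(hit = hit, power = mean(hit), false_flags = fp,
       fdr_observed = mean(fdp),
       power_analytic_lo = pow(q / 28), power_analytic_hi = pow(q))
}

#' Adjusted-association slope recovery and type-I error
#'
#' Simulates patient cohorts where an edge strength depends on a clinical
#' variable (`edge = slope * variable + confounded age effect + noise`),
#' fits [adjusted_association()], and reports how often the 95% CI covers
#' the true slope; under `slope = 0` the rejection rate at `alpha`
#' estimates the type-I error.
#'
#' @param n_sims Simulations (default 1000).
#' @param slope True slope (default 0.05); 0 gives the null experiment.
#' @param n Cohort size (default 33).
#' @param alpha Test level for the rejection count (default 0.05).
#' @param seed Master seed.
#' @return List: `covered` (logical per sim), `coverage`, `rejected`,
#'   `type1` (rejection rate), `estimates`.
#' @export
slope_recovery <- function(n_sims = 1000, slope = 0.05, n = 33,
                           alpha = 0.05, seed = 1) {
  set.seed(seed)
  covered <- rejected <- logical(n_sims)
  est <- numeric(n_sims)
  for (i in seq_len(n_sims)) {
    age <- stats::rnorm(n, 49, 10)
    sex <- stats::rbinom(n, 1, 0.6)
    edu <- stats::rnorm(n, 13, 3.5)
    # FPG partly driven by age so the confound adjustment matters
    fpg <- 8.5 + 0.08 * (age - 49) + stats::rnorm(n, 0, 3)
    edge <- slope * fpg + 0.004 * (age - 49) + stats::rnorm(n, 0, 0.15)
    res <- adjusted_association(edge, fpg, age, sex, edu)
    covered[i] <- res$ci[1] <= slope && slope <= res$ci[2]
    rejected[i] <- res$p < alpha
    est[i] <- res$coefficient
  }
  list(covered = covered, coverage = mean(covered), rejected = rejected,
       type1 = mean(rejected), estimates = est)
}
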