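# Synthetic two-group connectome studies: multivariate Gaussian ROI time
# series with a block-structured target correlation matrix, optional
# planted edge effects, and Table-1-style clinical covariates.

#' Simulation configuration
#'
#' Defines the study conditions a synthetic two-group connectome study is
#' generated under. Defaults mirror the design this pipeline targets:
#' 33 patients vs 24 controls, 116 regions, 243 retained frames at a 2 s
#' sampling interval, a mean within-network correlation of 0.3, and a
#' negative sensory-motor/auditory between-network baseline (r = -0.15) —
#' the normally antagonistic relation whose sign flip in patients the
#' pipeline is designed to detect.
#'
#' @param n_patients,n_controls Group sizes (defaults 33, 24).
#' @param n_frames Frames per subject after discard (default 243).
#' @param sampling_interval Seconds per frame (default 2).
#' @param partition A [network_partition()]; defaults to the packaged
#'   116-region table, which also fixes `n_regions`.
#' @param baseline_within_r Common within-network target correlation
#'   (default 0.3).
#' @param baseline_between_r Named list of between-network target
#'   correlations, names as `"X|Y"`; unlisted pairs default to 0. Default:
#'   `list("sensory-motor|auditory" = -0.15)` in both groups.
#' @param planted_edges NULL or a data.frame with columns region_a,
#'   region_b, r_patient, r_control: per-edge target correlations that
#'   override the baseline per group.
#' @param noise_sd White measurement noise added on top of the correlated
#'   signal (default 0; the unit-variance Gaussian frames already carry
#'   sampling noise).
#' @param clinical_variable,clinical_effect Clinical covariate coupled to
#'   the planted edges: each patient's planted-edge target (Fisher-z scale)
#'   is shifted by `clinical_effect` times the standardised covariate
#'   (default effect 0 = no coupling).
#' @param seed Integer seed; the whole study is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 33, n_controls = 24, n_frames = 243,
                       sampling_interval = 2,
                       partition = default_partition(),
                       baseline_within_r = 0.3,
                       baseline_between_r = list("sensory-motor|auditory" = -0.15),
                       planted_edges = NULL, noise_sd = 0,
                       clinical_variable = "FPG", clinical_effect = 0,
                       seed = 1) {
  cfg <- list(n_patients = n_patients, n_controls = n_controls,
              n_frames = n_frames, sampling_interval = sampling_interval,
              partition = partition, baseline_within_r = baseline_within_r,
              baseline_between_r = baseline_between_r,
              planted_edges = planted_edges, noise_sd = noise_sd,
              clinical_variable = clinical_variable,
              clinical_effect = clinical_effect, seed = seed)
  stopifnot(n_patients >= 2, n_controls >= 2, n_frames >= 10,
            abs(baseline_within_r) < 1)
  if (!is.null(planted_edges)) {
    stopifnot(all(c("region_a", "region_b", "r_patient", "r_control") %in%
                    names(planted_edges)),
              all(abs(planted_edges$r_patient) < 1),
              all(abs(planted_edges$r_control) < 1))
  }
  class(cfg) <- "sim_config"
  cfg
}

# Table-1-style covariate generating values (patient mean/sd, control
# mean/sd); invented only in the sense of being read off a typical early
# type-2-diabetes cohort description.
COVARIATE_DEFAULTS <- data.frame(
  variable = c("age", "education", "FPG", "PG2h", "HbA1c", "HOMA_IR", "MoCA"),
  mean_p = c(49.11, 13.03, 8.48, 12.31, 7.30, 2.02, 26.32),
  sd_p = c(9.68, 3.53, 3.22, 5.37, 1.97, 1.30, 2.42),
  mean_c = c(52.50, 11.88, 5.20, 5.71, 5.60, 1.25, 24.38),
  sd_c = c(9.66, 3.30, 0.40, 1.06, 0.25, 0.76, 3.99),
  stringsAsFactors = FALSE
)
P_FEMALE <- c(patient = 20 / 33, control = 14 / 24)

#' Repair a target correlation matrix to positive semi-definite
#'
#' Eigen-decomposes, floors eigenvalues at `floor`, reconstructs, and
#' rescales to a unit diagonal. Needed because arbitrary per-edge target
#' overrides can break positive semi-definiteness.
#'
#' @param R Symmetric matrix with unit diagonal.
#' @param floor Eigenvalue floor (default 1e-6).
#' @return A valid correlation matrix.
#' @export
repair_correlation <- function(R, floor = 1e-6) {
  eig <- eigen(R, symmetric = TRUE)
  if (min(eig$values) >= floor) return(R)
  vals <- pmax(eig$values, floor)
  R2 <- eig$vectors %*% (vals * t(eig$vectors))
  d <- diag(R2)
  if (any(d <= 0)) stop("correlation repair failed: non-positive diagonal")
  R2 <- R2 / sqrt(outer(d, d))
  dimnames(R2) <- dimnames(R)
  (R2 + t(R2)) / 2
}

# Baseline target correlation matrix from the partition block structure.
baseline_correlation <- function(partition, within_r, between_r) {
  regions <- names(partition$assignment)
  net <- partition$assignment
  n <- length(regions)
  R <- matrix(0, n, n, dimnames = list(regions, regions))
  same <- outer(net, net, `==`)
  R[same] <- within_r
  for (key in names(between_r)) {
    xy <- strsplit(key, "|", fixed = TRUE)[[1]]
    ix <- net == xy[1]; iy <- net == xy[2]
    R[ix, iy] <- between_r[[key]]
    R[iy, ix] <- between_r[[key]]
  }
  diag(R) <- 1
  R
}

apply_planted <- function(R, planted, col) {
  if (is.null(planted)) return(R)
  for (k in seq_len(nrow(planted))) {
    a <- planted$region_a[k]; b <- planted$region_b[k]
    if (!(a %in% rownames(R)) || !(b %in% rownames(R))) {
      stop("planted edge region not in partition: ", a, " -- ", b)
    }
    R[a, b] <- R[b, a] <- planted[[col]][k]
  }
  R
}

#' Default planted edge component
#'
#' A connected set of between-network edges: the complete bipartite graph
#' between `n_a` sensory-motor and `n_b` auditory regions (first members of
#' each network in the partition), giving `n_a * n_b` edges — by default
#' 30, sign-flipped from `-r` in controls to `+r` in patients, echoing a
#' pathological positive between-network pattern.
#'
#' @param partition A [network_partition()].
#' @param n_a,n_b Number of hub regions per side (defaults 6 and 5).
#' @param r Target correlation magnitude (default 0.15).
#' @param network_a,network_b The two networks bridged.
#' @return Data.frame usable as `planted_edges` in [sim_config()].
#' @export
planted_component <- function(partition, n_a = 6, n_b = 5, r = 0.15,
                              network_a = "sensory-motor",
                              network_b = "auditory") {
  ra <- names(partition$assignment)[partition$assignment == network_a][seq_len(n_a)]
  rb <- names(partition$assignment)[partition$assignment == network_b][seq_len(n_b)]
  grid <- expand.grid(region_a = ra, region_b = rb,
                      stringsAsFactors = FALSE)
  data.frame(grid, r_patient = r, r_control = -r)
}

#' Planted z offset for a target per-edge effect size
#'
#' For series of `n_frames` approximately independent frames, a subject's
#' edge Fisher-z has standard deviation about `1 / sqrt(n_frames - 3)`, so
#' a per-edge group difference of Cohen's d corresponds to a Fisher-z gap
#' of `d / sqrt(n_frames - 3)`.
#'
#' @param d Per-edge standardised effect size.
#' @param n_frames Frames per subject.
#' @return The Fisher-z group difference giving that d.
#' @export
planted_z_offset <- function(d, n_frames) d / sqrt(n_frames - 3)

simulate_covariates <- function(cfg) {
  n <- cfg$n_patients + cfg$n_controls
  grp <- rep(c("patient", "control"), c(cfg$n_patients, cfg$n_controls))
  cov <- data.frame(subject_id = sprintf("sub%03d", seq_len(n)), group = grp)
  cov$sex <- stats::rbinom(n, 1, P_FEMALE[grp])  # 0 = male, 1 = female
  for (k in seq_len(nrow(COVARIATE_DEFAULTS))) {
    v <- COVARIATE_DEFAULTS[k, ]
    mu <- ifelse(grp == "patient", v$mean_p, v$mean_c)
    sdv <- ifelse(grp == "patient", v$sd_p, v$sd_c)
    cov[[v$variable]] <- stats::rnorm(n, mu, sdv)
  }
  cov
}

#' Generate a synthetic two-group connectome study
#'
#' Draws, per subject, `n_frames` multivariate Gaussian frames with the
#' group's target correlation matrix (baseline block structure plus any
#' planted edge overrides, repaired to positive semi-definite), adds
#' optional white noise, simulates clinical covariates, and assembles the
#' per-subject Fisher-z connectivity matrices into a [group_study()].
#' Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @param keep_timeseries Keep the per-subject `roi_ts` objects in the
#'   result (default TRUE; set FALSE to save memory in large batches).
#' @return List with `timeseries` (list of `roi_ts`, or NULL) and `study`
#'   (a [group_study()] with covariates).
#' @export
generate_study <- function(config, keep_timeseries = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  regions <- names(config$partition$assignment)
  n_reg <- length(regions)
  base <- baseline_correlation(config$partition, config$baseline_within_r,
                               config$baseline_between_r)
  R_pat <- repair_correlation(apply_planted(base, config$planted_edges,
                                            "r_patient"))
  R_ctl <- repair_correlation(apply_planted(base, config$planted_edges,
                                            "r_control"))
  cov <- simulate_covariates(config)
  grp <- cov$group
  chol_pat <- chol(R_pat)
  chol_ctl <- chol(R_ctl)

  # clinical coupling: shift each patient's planted-edge target (z scale)
  # by effect * standardised covariate, requiring a per-subject factor
  use_coupling <- config$clinical_effect != 0 && !is.null(config$planted_edges)
  if (use_coupling) {
    v <- cov[[config$clinical_variable]][grp == "patient"]
    vstd <- (v - mean(v)) / stats::sd(v)
  }

  n <- nrow(cov)
  ts_list <- if (keep_timeseries) vector("list", n) else NULL
  mats <- vector("list", n)
  pat_counter <- 0L
  for (s in seq_len(n)) {
    if (grp[s] == "patient" && use_coupling) {
      pat_counter <- pat_counter + 1L
      Rs <- apply_planted(base, config$planted_edges, "r_patient")
      pl <- config$planted_edges
      shift <- tanh(fisher_z(pl$r_patient) +
                      config$clinical_effect * vstd[pat_counter])
      for (k in seq_len(nrow(pl))) {
        Rs[pl$region_a[k], pl$region_b[k]] <- shift[k]
        Rs[pl$region_b[k], pl$region_a[k]] <- shift[k]
      }
      ch <- chol(repair_correlation(Rs))
    } else {
      ch <- if (grp[s] == "patient") chol_pat else chol_ctl
    }
    frames <- matrix(stats::rnorm(config$n_frames * n_reg),
                     config$n_frames, n_reg) %*% ch
    if (config$noise_sd > 0) {
      frames <- frames + matrix(stats::rnorm(length(frames), 0,
                                             config$noise_sd),
                                nrow(frames), ncol(frames))
    }
    colnames(frames) <- regions
    ts <- roi_timeseries(frames, cov$subject_id[s],
                         config$sampling_interval)
    if (keep_timeseries) ts_list[[s]] <- ts
    mats[[s]] <- pearson_connectivity(ts)
  }
  study <- group_study(mats,
                       factor(grp, levels = c("control", "patient")),
                       covariates = cov)
  list(timeseries = ts_list, study = study, config = config)
}

#' Generate a null study (no group difference)
#'
#' Both groups share one correlation structure (the baseline, ignoring any
#' planted edges); used for type-I-error and FWE calibration.
#'
#' @param config A [sim_config()].
#' @return A [group_study()].
#' @export
generate_null_study <- function(config) {
  config$planted_edges <- NULL
  config$clinical_effect <- 0
  generate_study(config, keep_timeseries = FALSE)$study
}
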