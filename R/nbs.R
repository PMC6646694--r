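# Network-based statistics: sign-test connection mask, edge-wise pooled-t
# tests, suprathreshold connected components, and permutation FWE control
# on the maximal component size.

#' Non-zero connection mask (sign test, union over groups)
#'
#' Tests each edge, within each group separately, for a non-zero median
#' Fisher-z value with an exact binomial sign test (zeros dropped, one
#' tailed toward the observed majority sign). An edge enters the mask if
#' the test rejects in *either* group at level `alpha`.
#'
#' @param study A [group_study()].
#' @param alpha Per-edge significance level (default 0.05).
#' @return A symmetric logical regions x regions matrix (class `edge_mask`)
#'   with a FALSE diagonal.
#' @export
nonzero_mask <- function(study, alpha = 0.05) {
  stopifnot(inherits(study, "group_study"))
  X <- edge_values(study)
  sig <- rep(FALSE, ncol(X))
  for (g in levels(study$group)) {
    Xi <- X[study$group == g, , drop = FALSE]
    npos <- colSums(Xi > 0)
    nn <- colSums(Xi != 0)
    k <- pmax(npos, nn - npos)
    # P(Bin(nn, 1/2) >= k), the majority tail; edges with nn = 0 never pass
    p <- stats::pbinom(k - 1, nn, 0.5, lower.tail = FALSE)
    p[nn == 0] <- 1
    sig <- sig | (p <= alpha)
  }
  n <- length(study$regions)
  mask <- matrix(FALSE, n, n, dimnames = list(study$regions, study$regions))
  mask[upper.tri(mask)] <- sig
  mask <- mask | t(mask)
  class(mask) <- c("edge_mask", class(mask))
  mask
}

#' Exact binomial sign test
#'
#' One-tailed p-value that a sample's median is zero, counting positive
#' against negative values (zeros dropped) and evaluating the tail of the
#' observed majority sign.
#'
#' @param x Numeric vector.
#' @return One-tailed p-value; 1 when every value is zero.
#' @export
sign_test_p <- function(x) {
  x <- x[x != 0]
  if (length(x) == 0) return(1)
  k <- max(sum(x > 0), sum(x < 0))
  stats::pbinom(k - 1, length(x), 0.5, lower.tail = FALSE)
}

# Pooled-variance two-sample t statistics for all columns of X at once.
# grp1 is a logical index of the non-reference (patient) group; the sign of
# t is patient minus control.
pooled_t_cols <- function(X, grp1) {
  n1 <- sum(grp1); n2 <- sum(!grp1)
  s1 <- colSums(X[grp1, , drop = FALSE])
  s2 <- colSums(X[!grp1, , drop = FALSE])
  q1 <- colSums(X[grp1, , drop = FALSE]^2)
  q2 <- colSums(X[!grp1, , drop = FALSE]^2)
  m1 <- s1 / n1; m2 <- s2 / n2
  sp2 <- (q1 - n1 * m1^2 + q2 - n2 * m2^2) / (n1 + n2 - 2)
  tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tt, df = n1 + n2 - 2, mean_patient = m1, mean_control = m2,
       sp2 = sp2)
}

#' Edge-wise two-sample t tests within a mask
#'
#' Pooled-variance (Student) two-sample t statistic per masked edge,
#' signed patient minus control, with one-tailed p-values for both
#' directions. Edges with zero pooled variance are dropped from the map
#' with a warning.
#'
#' @param study A [group_study()].
#' @param mask Optional logical mask from [nonzero_mask()]; NULL tests all
#'   edges.
#' @return An object of class `edge_stats`: matrices `t`, `p_patient_gt`,
#'   `p_control_gt` (NA outside the mask), the degrees of freedom, and the
#'   per-group edge means.
#' @export
edge_t_tests <- function(study, mask = NULL) {
  stopifnot(inherits(study, "group_study"))
  n <- length(study$regions)
  if (is.null(mask)) {
    mask <- matrix(TRUE, n, n); diag(mask) <- FALSE
    dimnames(mask) <- list(study$regions, study$regions)
  }
  keep <- mask[upper.tri(mask)]
  X <- edge_values(study)
  grp1 <- study$group == levels(study$group)[2]
  res <- pooled_t_cols(X[, keep, drop = FALSE], grp1)
  bad <- !is.finite(res$t)
  if (any(bad)) {
    warning(sum(bad), " masked edge(s) with zero pooled variance excluded")
  }
  fill <- function(v) {
    full <- rep(NA_real_, length(keep))
    full[keep] <- v
    m <- matrix(NA_real_, n, n, dimnames = list(study$regions, study$regions))
    m[upper.tri(m)] <- full
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }
  tmat <- fill(ifelse(bad, NA_real_, res$t))
  structure(
    list(t = tmat,
         p_patient_gt = fill(stats::pt(res$t, res$df, lower.tail = FALSE)),
         p_control_gt = fill(stats::pt(res$t, res$df)),
         df = res$df,
         mean_patient = fill(res$mean_patient),
         mean_control = fill(res$mean_control),
         groups = levels(study$group)),
    class = "edge_stats"
  )
}

# Resolve a primary threshold given either t= or p= form into a t cut for
# a one-tailed test at `df` degrees of freedom.
resolve_threshold <- function(t_threshold, p_threshold, df) {
  if (is.null(t_threshold) == is.null(p_threshold)) {
    stop("give exactly one of t_threshold or p_threshold")
  }
  if (!is.null(t_threshold)) t_threshold
  else stats::qt(p_threshold, df, lower.tail = FALSE)
}

#' Connected components of suprathreshold edges
#'
#' Thresholds the one-tailed edge statistics and returns the connected
#' components of the resulting graph, largest first. Component size is its
#' number of edges (links).
#'
#' @param stats An `edge_stats` object from [edge_t_tests()].
#' @param t_threshold,p_threshold The primary threshold, as a t value or a
#'   one-tailed p value; give exactly one.
#' @param tail `"patient_gt"` tests patient > control (t >= cut),
#'   `"control_gt"` the reverse (-t >= cut).
#' @return List of components, each a list with `edges` (data.frame:
#'   region_a, region_b, t, p), `size`, and `p_fwe` (NA until assessed by
#'   [nbs_permutation()]). Empty list when no edge passes.
#' @export
suprathreshold_components <- function(stats, t_threshold = NULL,
                                      p_threshold = NULL,
                                      tail = c("patient_gt", "control_gt")) {
  stopifnot(inherits(stats, "edge_stats"))
  tail <- match.arg(tail)
  cut <- resolve_threshold(t_threshold, p_threshold, stats$df)
  tt <- stats$t
  signed <- if (tail == "patient_gt") tt else -tt
  pmat <- if (tail == "patient_gt") stats$p_patient_gt else stats$p_control_gt
  sel <- which(upper.tri(signed) & !is.na(signed) & signed >= cut,
               arr.ind = TRUE)
  if (nrow(sel) == 0) return(list())
  regions <- rownames(tt)
  g <- igraph::graph_from_data_frame(
    data.frame(from = regions[sel[, 1]], to = regions[sel[, 2]]),
    directed = FALSE
  )
  memb <- igraph::components(g)$membership
  edge_comp <- memb[regions[sel[, 1]]]
  comps <- lapply(split(seq_len(nrow(sel)), edge_comp), function(rows) {
    edges <- data.frame(
      region_a = regions[sel[rows, 1]],
      region_b = regions[sel[rows, 2]],
      t = tt[sel[rows, , drop = FALSE]],
      p = pmat[sel[rows, , drop = FALSE]],
      stringsAsFactors = FALSE
    )
    list(edges = edges, size = nrow(edges), p_fwe = NA_real_, tail = tail)
  })
  comps[order(-vapply(comps, `[[`, 0L, "size"))]
}

# Max suprathreshold component size for one permutation's t vector.
# ei/ej are edge endpoints (integer node ids) aligned with tvec; union-find.
max_component_size <- function(tvec, cut, ei, ej, n_nodes) {
  hit <- which(is.finite(tvec) & tvec >= cut)
  m <- length(hit)
  if (m <= 1) return(m)
  parent <- seq_len(n_nodes)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (k in hit) {
    ra <- find(ei[k]); rb <- find(ej[k])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(ei[hit], find, 0L)
  max(tabulate(roots))
}

#' Permutation FWE assessment of component sizes
#'
#' Runs the full network-based statistics pass for one tail: sign-test
#' connection mask, edge-wise pooled-t tests within it, suprathreshold
#' components, and a permutation null distribution of the maximal
#' component size obtained by wholesale relabelling of subjects. The
#' whole pipeline — including the sign-test mask — is re-derived from each
#' permutation's relabelled groups, so the null reflects the mask's
#' data-dependence (a fixed observed mask selects null edges for sign
#' consistency and anti-conservatively inflates the observed statistics
#' relative to permuted ones). Each component's familywise-error corrected
#' p-value is
#' `(1 + #permutations with max size >= observed size) / (1 + n_perm)`.
#'
#' @param study A [group_study()].
#' @param mask Optional fixed logical edge mask. When supplied it is used
#'   verbatim for the observed pass *and* every permutation (no per-
#'   permutation recomputation); when NULL (default) the sign-test mask at
#'   `mask_alpha` is derived from the observed labels and re-derived per
#'   permutation.
#' @param mask_alpha Sign-test level for the connection mask
#'   (default 0.05); ignored when `mask` is given. `NA` disables masking
#'   entirely (all edges eligible).
#' @param t_threshold,p_threshold Primary threshold (exactly one).
#' @param tail Direction tested, as in [suprathreshold_components()].
#' @param n_perm Number of permutations (reference analyses use 5000).
#' @param seed Integer seed fixing the permutation stream.
#' @return List with `components` (as in [suprathreshold_components()], with
#'   `p_fwe` filled in), `null_max_sizes` (integer vector, one per
#'   permutation), `n_perm`, the mask used for the observed pass, and the
#'   threshold.
#' @export
nbs_permutation <- function(study, mask = NULL, mask_alpha = 0.05,
                            t_threshold = NULL, p_threshold = NULL,
                            tail = c("patient_gt", "control_gt"),
                            n_perm = 5000, seed = 42) {
  stopifnot(inherits(study, "group_study"))
  tail <- match.arg(tail)
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (n_perm < 100) warning("n_perm < 100: permutation p resolution is coarse")
  n <- length(study$regions)
  fixed_mask <- !is.null(mask)
  if (!fixed_mask) {
    mask <- if (is.na(mask_alpha)) NULL else nonzero_mask(study, mask_alpha)
  }
  stats <- edge_t_tests(study, mask)
  comps <- suprathreshold_components(stats, t_threshold, p_threshold, tail)
  cut <- resolve_threshold(t_threshold, p_threshold, stats$df)

  # permutations run over the fixed mask's edges, or over all edges with
  # the sign-test mask re-derived per permutation
  remask <- !fixed_mask && !is.na(mask_alpha)
  keep_mat <- if (fixed_mask) mask else matrix(TRUE, n, n)
  diag(keep_mat) <- FALSE
  keep <- which(keep_mat[upper.tri(keep_mat)])
  idx <- edge_index(n)
  ei <- idx$i[keep]; ej <- idx$j[keep]
  X <- edge_values(study)[, keep, drop = FALSE]
  X2 <- X^2
  nsub <- nrow(X)
  n1 <- sum(study$group == levels(study$group)[2])
  n2 <- nsub - n1
  stot <- colSums(X); qtot <- colSums(X2)
  sgn <- if (tail == "patient_gt") 1 else -1
  if (remask) {
    POS <- (X > 0) * 1
    NZ <- (X != 0) * 1
    pos_tot <- colSums(POS); nz_tot <- colSums(NZ)
    # critical majority count per non-zero sample size: the sign test
    # rejects at mask_alpha iff max(n+, n-) >= kcrit[nz + 1]
    kcrit <- vapply(0:nsub, function(m) {
      p <- stats::pbinom((0:m) - 1, m, 0.5, lower.tail = FALSE)
      k <- which(p <= mask_alpha)
      if (length(k)) k[1] - 1 else m + 1
    }, 0)
  }

  set.seed(seed)
  null_max <- integer(n_perm)
  chunk <- 250L
  done <- 0L
  while (done < n_perm) {
    nb <- min(chunk, n_perm - done)
    # rows of P indicate which subjects land in the (pseudo-)patient group
    P <- matrix(0, nb, nsub)
    for (b in seq_len(nb)) P[b, sample.int(nsub, n1)] <- 1
    S1 <- P %*% X
    Q1 <- P %*% X2
    M1 <- S1 / n1
    M2 <- sweep(-S1, 2, stot, `+`) / n2
    SP2 <- (Q1 - n1 * M1^2 + sweep(-Q1, 2, qtot, `+`) -
              n2 * M2^2) / (nsub - 2)
    Tm <- sgn * (M1 - M2) / sqrt(SP2 * (1 / n1 + 1 / n2))
    if (remask) {
      NP1 <- P %*% POS
      NZ1 <- P %*% NZ
      NP2 <- sweep(-NP1, 2, pos_tot, `+`)
      NZ2 <- sweep(-NZ1, 2, nz_tot, `+`)
      in_mask <- (pmax(NP1, NZ1 - NP1) >= kcrit[NZ1 + 1]) |
        (pmax(NP2, NZ2 - NP2) >= kcrit[NZ2 + 1])
      Tm[!in_mask] <- -Inf
    }
    for (b in seq_len(nb)) {
      null_max[done + b] <- max_component_size(Tm[b, ], cut, ei, ej, n)
    }
    done <- done + nb
  }
  for (k in seq_along(comps)) {
    comps[[k]]$p_fwe <-
      (1 + sum(null_max >= comps[[k]]$size)) / (1 + n_perm)
  }
  list(components = comps, null_max_sizes = null_max, n_perm = n_perm,
       t_threshold = cut, tail = tail, df = stats$df, seed = seed,
       mask = mask, remasked = remask)
}

#' Full NBS run (both tails)
#'
#' Convenience wrapper: builds the sign-test connection mask, then runs
#' [nbs_permutation()] for the requested tail(s) and returns all components
#' together with the per-tail null distributions. With `tails = "both"`
#' each direction is assessed as its own one-tailed pass and the union of
#' components is reported.
#'
#' @param study A [group_study()].
#' @param mask_alpha Sign-test level for the connection mask (default 0.05).
#' @param t_threshold,p_threshold Primary threshold (exactly one; default
#'   t = 3, the reference configuration).
#' @param tails `"both"`, `"patient_gt"` or `"control_gt"`.
#' @param n_perm,seed As in [nbs_permutation()]. Each tail uses its own
#'   permutation stream derived from `seed`.
#' @return List with `components` (all tails, sorted by size), `runs`
#'   (per-tail [nbs_permutation()] results), and the mask.
#' @export
nbs_run <- function(study, mask_alpha = 0.05, t_threshold = 3,
                    p_threshold = NULL, tails = "both", n_perm = 5000,
                    seed = 42) {
  if (!is.null(p_threshold)) t_threshold <- NULL
  which_tails <- if (tails == "both") c("patient_gt", "control_gt") else tails
  runs <- list()
  for (k in seq_along(which_tails)) {
    runs[[which_tails[k]]] <- nbs_permutation(
      study, mask_alpha = mask_alpha, t_threshold = t_threshold,
      p_threshold = p_threshold, tail = which_tails[k],
      n_perm = n_perm, seed = seed + (k - 1L)
    )
  }
  comps <- do.call(c, lapply(runs, `[[`, "components"))
  comps <- comps[order(-vapply(comps, `[[`, 0L, "size"))]
  list(components = comps, runs = runs, mask = runs[[1]]$mask,
       config = list(mask_alpha = mask_alpha, t_threshold = t_threshold,
                     p_threshold = p_threshold, tails = tails,
                     n_perm = n_perm, seed = seed))
}
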