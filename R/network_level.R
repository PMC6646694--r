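# Within- and between-network connectivity strengths and their group
# comparison with Benjamini-Hochberg FDR control.

#' Region-to-network partition
#'
#' Assigns every region to exactly one resting-state network. The default
#' 116-region table bundled with the package groups the 90 cerebral regions
#' into six networks (default mode, attention, visual, auditory,
#' sensory-motor, subcortical) and the 26 cerebellar regions into a
#' cerebellum network. That table is a reconstruction of a conventional
#' AAL-based grouping — analyses tied to a specific published partition
#' should supply their own file via [read_partition()].
#'
#' @param assignment Named character vector: names are region labels,
#'   values network names.
#' @param networks Optional ordered vector of network names; defaults to
#'   order of first appearance.
#' @return Object of class `network_partition` with fields `assignment`
#'   and `networks`.
#' @export
network_partition <- function(assignment,
                              networks = unique(unname(assignment))) {
  assignment <- stats::setNames(as.character(assignment), names(assignment))
  if (is.null(names(assignment)) || any(names(assignment) == "")) {
    stop("assignment must be named by region")
  }
  if (anyDuplicated(names(assignment))) {
    stop("region(s) assigned more than once: ",
         paste(unique(names(assignment)[duplicated(names(assignment))]),
               collapse = ", "))
  }
  extra <- setdiff(unique(assignment), networks)
  if (length(extra) > 0) stop("unknown network(s): ", paste(extra, collapse = ", "))
  structure(list(assignment = assignment, networks = networks),
            class = "network_partition")
}

#' @export
print.network_partition <- function(x, ...) {
  cat("<network_partition>", length(x$assignment), "regions in",
      length(x$networks), "networks\n")
  print(table(factor(x$assignment, levels = x$networks)))
  invisible(x)
}

#' Read a partition table
#'
#' @param path Two-column delimited file (region, network) with a header.
#' @return A [network_partition()].
#' @export
read_partition <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  network_partition(stats::setNames(df[[2]], df[[1]]))
}

#' Default 116-region, 7-network partition
#'
#' @return The packaged reconstruction (see [network_partition()]).
#' @export
default_partition <- function() {
  read_partition(system.file("extdata", "partition_aal116.tsv",
                             package = "fcnbs"))
}

region_indices <- function(matrix, partition, network) {
  regions <- rownames(matrix)
  if (is.null(regions)) stop("matrix must have region names")
  idx <- which(partition$assignment[regions] == network)
  idx
}

#' Within-network connectivity strength
#'
#' Mean Fisher-z over the `n_X (n_X - 1) / 2` distinct region pairs inside
#' one network:
#' `W_X = 1 / (n_X (n_X - 1) / 2) * sum_{i<j in X} z_ij`.
#'
#' @param matrix A `conn_matrix` (region names required).
#' @param partition A [network_partition()].
#' @param network Network name with at least two member regions.
#' @return Scalar strength in Fisher-z units.
#' @export
within_strength <- function(matrix, partition, network) {
  idx <- region_indices(matrix, partition, network)
  if (length(idx) < 2) {
    stop("network '", network, "' has fewer than 2 regions in the matrix")
  }
  block <- matrix[idx, idx]
  mean(block[upper.tri(block)])
}

#' Between-network connectivity strength
#'
#' Mean Fisher-z over the `n_X * n_Y` cross pairs of two distinct
#' networks: `W_{X,Y} = 1 / (n_X n_Y) * sum_{i in X, j in Y} z_ij`.
#' Symmetric in its two network arguments.
#'
#' @inheritParams within_strength
#' @param network_x,network_y Distinct network names, each nonempty.
#' @return Scalar strength in Fisher-z units.
#' @export
between_strength <- function(matrix, partition, network_x, network_y) {
  if (identical(network_x, network_y)) {
    stop("networks are identical; use within_strength() for '",
         network_x, "'")
  }
  ix <- region_indices(matrix, partition, network_x)
  iy <- region_indices(matrix, partition, network_y)
  if (length(ix) == 0 || length(iy) == 0) stop("empty network")
  mean(matrix[ix, iy])
}

#' All 28 network-level strengths of one subject
#'
#' @inheritParams within_strength
#' @return Named numeric vector: 7 `within:<X>` followed by 21
#'   `between:<X>|<Y>` values (network order as in the partition).
#' @export
network_strengths <- function(matrix, partition) {
  nets <- partition$networks
  w <- vapply(nets, function(x) within_strength(matrix, partition, x), 0)
  names(w) <- paste0("within:", nets)
  pairs <- utils::combn(nets, 2)
  b <- apply(pairs, 2, function(xy) {
    between_strength(matrix, partition, xy[1], xy[2])
  })
  names(b) <- paste0("between:", pairs[1, ], "|", pairs[2, ])
  c(w, b)
}

#' Group comparison of network strengths with FDR control
#'
#' Computes the 7 within-network and 21 between-network strengths per
#' subject, compares groups per measure with a two-sided pooled-variance t
#' test, and applies Benjamini-Hochberg correction across all 28 measures
#' jointly. Measures with zero pooled variance are flagged and excluded
#' from the FDR family with a warning.
#'
#' @param study A [group_study()].
#' @param partition A [network_partition()].
#' @param q FDR level for the `significant` flag (default 0.05).
#' @return Data.frame with one row per measure: measure, scope, mean per
#'   group, t, df, p, p_fdr, significant.
#' @export
compare_network_strengths <- function(study, partition, q = 0.05) {
  stopifnot(inherits(study, "group_study"))
  S <- t(vapply(study$matrices,
                function(m) network_strengths(m, partition),
                network_strengths(study$matrices[[1]], partition)))
  grp1 <- study$group == levels(study$group)[2]
  res <- pooled_t_cols(S, grp1)
  p <- 2 * stats::pt(-abs(res$t), res$df)
  degenerate <- !is.finite(res$t)
  if (any(degenerate)) {
    warning("measure(s) with zero pooled variance excluded from FDR: ",
            paste(colnames(S)[degenerate], collapse = ", "))
  }
  p_fdr <- rep(NA_real_, length(p))
  p_fdr[!degenerate] <- stats::p.adjust(p[!degenerate], method = "BH")
  data.frame(
    measure = colnames(S),
    scope = ifelse(startsWith(colnames(S), "within"), "within", "between"),
    mean_patient = res$mean_patient,
    mean_control = res$mean_control,
    t = res$t, df = res$df, p = p, p_fdr = p_fdr,
    significant = !is.na(p_fdr) & p_fdr < q,
    row.names = NULL, stringsAsFactors = FALSE
  )
}
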