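# Correlations are clipped just inside (-1, 1) before atanh so duplicate or
# perfectly anti-correlated series map to a large finite z, not +/-Inf.
R_CLIP <- 1 - 1e-7

#' Fisher r-to-z transform
#'
#' `z = atanh(r)`, the variance-stabilising map applied to correlation
#' coefficients before parametric group tests. `r` is clipped to
#' +/-(1 - 1e-7) so the result is always finite.
#'
#' @param r Numeric vector or matrix of correlations in `[-1, 1]`.
#' @return Fisher-z values of the same shape.
#' @export
fisher_z <- function(r) {
  atanh(pmin(pmax(r, -R_CLIP), R_CLIP))
}

#' Per-subject Fisher-z connectivity matrix
#'
#' Pearson-correlates every pair of region series and applies the Fisher
#' r-to-z transform. The diagonal (self-connectivity) is set to 0 and is
#' excluded from all downstream statistics. Regions with zero temporal
#' variance get a zeroed row/column, a warning, and are recorded in the
#' `flagged_regions` attribute.
#'
#' @param ts A `roi_ts` object with at least 10 frames.
#' @return A symmetric regions x regions matrix of Fisher-z values
#'   (class `conn_matrix`), with `subject_id` and `flagged_regions`
#'   attributes.
#' @export
pearson_connectivity <- function(ts) {
  stopifnot(inherits(ts, "roi_ts"))
  if (n_frames(ts) < 10) {
    stop("need at least 10 frames to estimate correlations, got ",
         n_frames(ts))
  }
  sds <- apply(ts$data, 2, stats::sd)
  degenerate <- which(sds == 0 | !is.finite(sds))
  x <- ts$data
  if (length(degenerate) > 0) {
    warning("zero-variance region(s) zeroed out: ",
            paste(colnames(x)[degenerate], collapse = ", "))
    # give them unit noise-free placeholders so cor() stays finite, then zero
    x[, degenerate] <- seq_len(nrow(x))
  }
  r <- stats::cor(x)
  z <- fisher_z(r)
  diag(z) <- 0
  if (length(degenerate) > 0) {
    z[degenerate, ] <- 0
    z[, degenerate] <- 0
  }
  z <- (z + t(z)) / 2  # enforce exact symmetry
  structure(z, class = c("conn_matrix", class(z)),
            subject_id = ts$subject_id,
            flagged_regions = colnames(ts$data)[degenerate])
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat("<conn_matrix> subject:", attr(x, "subject_id") %||% "?",
      "|", nrow(x), "x", ncol(x), "Fisher-z\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Grouped connectivity study
#'
#' Collects the per-subject connectivity matrices of a two-group study with
#' its group labels and (optionally) per-subject covariates.
#'
#' @param matrices List of `conn_matrix` (or plain symmetric matrices), all
#'   with identical region names and ordering.
#' @param group Vector of group labels, coerced to a factor whose first
#'   level is the reference (control) group. Use
#'   `factor(..., levels = c("control", "patient"))` to fix the roles:
#'   group tests are reported as patient minus control, i.e. second level
#'   minus first level.
#' @param covariates Optional data.frame of per-subject covariates
#'   (age, sex, education, clinical variables), one row per subject.
#' @return An object of class `group_study`.
#' @export
group_study <- function(matrices, group, covariates = NULL) {
  stopifnot(is.list(matrices), length(matrices) == length(group))
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("exactly two groups are required")
  if (any(table(group) < 2)) stop("need at least 2 subjects per group")
  ref <- dimnames(matrices[[1]])
  for (i in seq_along(matrices)) {
    m <- matrices[[i]]
    if (!isTRUE(all.equal(dim(m), dim(matrices[[1]])))) {
      stop("matrix ", i, " has mismatched dimensions")
    }
    if (!identical(dimnames(m)[[1]], ref[[1]])) {
      stop("matrix ", i, " has mismatched region ordering")
    }
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(group)) {
      stop("covariates must have one row per subject")
    }
  }
  structure(
    list(matrices = matrices, group = group, covariates = covariates,
         regions = ref[[1]] %||% sprintf("R%03d", seq_len(nrow(matrices[[1]])))),
    class = "group_study"
  )
}

#' @export
print.group_study <- function(x, ...) {
  tb <- table(x$group)
  cat("<group_study>", length(x$matrices), "subjects (",
      paste(sprintf("%s: %d", names(tb), tb), collapse = ", "),
      ") |", length(x$regions), "regions\n")
  invisible(x)
}

# Upper-triangle edge indexing shared by the NBS internals: a study's edge
# data as a subjects x n_edges matrix plus the (i, j) endpoints per edge.
edge_index <- function(n) {
  ut <- which(upper.tri(diag(n)), arr.ind = TRUE)
  list(i = ut[, 1], j = ut[, 2], n_edges = nrow(ut))
}

edge_values <- function(study) {
  n <- length(study$regions)
  keep <- upper.tri(diag(n))
  vals <- vapply(study$matrices, function(m) m[keep], numeric(sum(keep)))
  if (is.null(dim(vals))) matrix(vals, ncol = 1) else t(vals)
}

edge_names <- function(study) {
  idx <- edge_index(length(study$regions))
  paste(study$regions[idx$i], study$regions[idx$j], sep = "--")
}
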