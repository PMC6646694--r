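# Shared fixtures and independent oracles used across the test files.

# Independent connected-components oracle: plain breadth-first search over
# an adjacency list, counting edges per reachable set. Used to cross-check
# the graph-library-based component extraction.
bfs_component_edge_sizes <- function(edges, n_nodes) {
  if (nrow(edges) == 0) return(integer())
  adj <- vector("list", n_nodes)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(n_nodes)
  sizes <- integer()
  for (s in unique(c(edges[, 1], edges[, 2]))) {
    if (seen[s]) next
    comp <- integer()
    queue <- s
    seen[s] <- TRUE
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      for (w in adj[[v]]) {
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    in_comp <- logical(n_nodes); in_comp[comp] <- TRUE
    sizes <- c(sizes, sum(in_comp[edges[, 1]] & in_comp[edges[, 2]]))
  }
  sort(sizes, decreasing = TRUE)
}

# Build a tiny group study directly from per-subject upper-triangle edge
# values: `edge_rows` is a subjects x n_edges matrix, regions labelled
# R1..Rk for the smallest k that holds the edges.
study_from_edges <- function(edge_rows, group) {
  n_edges <- ncol(edge_rows)
  n <- ceiling((1 + sqrt(1 + 8 * n_edges)) / 2)
  regions <- paste0("R", seq_len(n))
  mats <- lapply(seq_len(nrow(edge_rows)), function(s) {
    m <- matrix(0, n, n, dimnames = list(regions, regions))
    m[upper.tri(m)][seq_len(n_edges)] <- edge_rows[s, ]
    m + t(m)
  })
  group_study(mats, group)
}

# An edge_stats object with prescribed t values (upper-triangle order) so
# component extraction can be tested on hand-built graphs.
stats_from_t <- function(tmat, df = 10) {
  tmat[lower.tri(tmat)] <- t(tmat)[lower.tri(tmat)]
  diag(tmat) <- NA
  structure(list(t = tmat,
                 p_patient_gt = stats::pt(tmat, df, lower.tail = FALSE),
                 p_control_gt = stats::pt(tmat, df),
                 df = df,
                 mean_patient = tmat * NA, mean_control = tmat * NA,
                 groups = c("control", "patient")),
            class = "edge_stats")
}

# Two series with an exact target Pearson correlation, built from an
# orthonormalised pair of fixed vectors.
series_with_correlation <- function(r, n = 24) {
  x <- seq_len(n)
  e <- rep(c(1, -1), length.out = n)
  xs <- (x - mean(x)) / stats::sd(x)
  e <- e - mean(e) - sum((e - mean(e)) * xs) / sum(xs^2) * xs
  es <- (e - mean(e)) / stats::sd(e)
  cbind(x = xs, y = r * xs + sqrt(1 - r^2) * es)
}

tiny_partition <- function() {
  network_partition(c(A1 = "alpha", A2 = "alpha", A3 = "alpha",
                      B1 = "beta", B2 = "beta", C1 = "gamma"))
}
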