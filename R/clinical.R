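# Group comparisons reproducible from printed summary statistics, and
# covariate-adjusted edge-clinical association models.

#' Two-sample t test from summary statistics
#'
#' Pooled-variance (Student) two-sample t test computed from per-group
#' mean, standard deviation and sample size — the form needed to reproduce
#' a demographics table that prints only summaries. Degrees of freedom are
#' `n_a + n_b - 2`; the p-value is two-sided.
#'
#' @param mean_a,sd_a,n_a First group summary.
#' @param mean_b,sd_b,n_b Second group summary.
#' @return List with `t`, `df`, `p` (two-sided). Degenerate case of both
#'   sds zero: p = 1 if the means agree, p = 0 (flagged `degenerate`)
#'   otherwise.
#' @export
ttest_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  stopifnot(sd_a >= 0, sd_b >= 0, n_a >= 2, n_b >= 2)
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  if (sp2 == 0) {
    same <- mean_a == mean_b
    return(list(t = if (same) 0 else sign(mean_a - mean_b) * Inf, df = df,
                p = if (same) 1 else 0, degenerate = !same))
  }
  tt <- (mean_a - mean_b) / sqrt(sp2 * (1 / n_a + 1 / n_b))
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df), degenerate = FALSE)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Pearson chi-square without continuity correction, df = 1 — the form
#' conventionally used for a sex-by-group cross table.
#'
#' @param a,b,c,d Cell counts, row-wise: `rbind(c(a, b), c(c, d))`.
#' @return List with `chi2` and `p`.
#' @export
chisq_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0), sum(counts) >= 1)
  tab <- matrix(counts, 2, 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero marginal in 2x2 table")
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(res$statistic), p = unname(res$p.value))
}

#' Reproduce a summary-statistics comparison table
#'
#' Applies [ttest_from_summary()] to every row of a table of printed group
#' summaries (and [chisq_2x2()] to count rows, identified by NA sds).
#'
#' @param summaries Data.frame with columns variable, mean_a, sd_a, n_a,
#'   mean_b, sd_b, n_b. For a count row (e.g. sex), mean columns carry the
#'   two cell counts per group and sd columns are NA.
#' @return Input with `t_or_chi2`, `df`, `p` columns appended.
#' @export
summary_table_tests <- function(summaries) {
  out <- summaries
  out$t_or_chi2 <- out$df <- out$p <- NA_real_
  for (i in seq_len(nrow(summaries))) {
    s <- summaries[i, ]
    if (is.na(s$sd_a)) {
      res <- chisq_2x2(s$mean_a, s$n_a - s$mean_a, s$mean_b, s$n_b - s$mean_b)
      out$t_or_chi2[i] <- res$chi2; out$df[i] <- 1; out$p[i] <- res$p
    } else {
      res <- ttest_from_summary(s$mean_a, s$sd_a, s$n_a,
                                s$mean_b, s$sd_b, s$n_b)
      out$t_or_chi2[i] <- res$t; out$df[i] <- res$df; out$p[i] <- res$p
    }
  }
  out
}

#' Read the bundled demographics summary table
#'
#' @param path TSV of per-variable group summaries; defaults to the
#'   packaged fixture (patient group = a, control group = b).
#' @return Data.frame suitable for [summary_table_tests()].
#' @export
read_summary_table <- function(path = system.file("extdata",
                                                  "table1_summaries.tsv",
                                                  package = "fcnbs")) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Covariate-adjusted edge-clinical association
#'
#' Ordinary-least-squares general linear model
#' `edge ~ variable + age + sex + education`, giving the slope of the
#' clinical variable with age, sex and education simultaneously adjusted
#' for. Sex is coded 0/1 (any consistent coding leaves the other slopes'
#' tests unchanged).
#'
#' @param edge_values Per-subject edge Fisher-z values.
#' @param variable Per-subject clinical variable (same length).
#' @param age,sex,education Per-subject covariates; sex may be a factor or
#'   0/1 numeric.
#' @return List with `coefficient`, `se`, `t`, `df`, `p` (two-sided),
#'   `ci` (95% interval for the slope), and the fitted `model`.
#' @export
adjusted_association <- function(edge_values, variable, age, sex, education) {
  sex <- if (is.factor(sex) || is.character(sex)) {
    as.numeric(as.factor(sex)) - 1
  } else as.numeric(sex)
  df <- data.frame(edge = edge_values, variable = variable, age = age,
                   sex = sex, education = education)
  df <- stats::na.omit(df)
  # covariates without variance carry no information; drop rather than fail
  keep <- vapply(df[, c("variable", "age", "sex", "education")],
                 function(x) stats::var(x) > 0, TRUE)
  if (!keep[["variable"]]) stop("clinical variable has zero variance")
  form <- stats::reformulate(names(keep)[keep], response = "edge")
  fit <- stats::lm(form, data = df)
  if (any(is.na(stats::coef(fit)))) {
    stop("collinear design; aliased column(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit)["variable", ]
  list(coefficient = sm["variable", "Estimate"],
       se = sm["variable", "Std. Error"],
       t = sm["variable", "t value"],
       df = fit$df.residual,
       p = sm["variable", "Pr(>|t|)"],
       ci = unname(ci),
       model = fit)
}

#' Associations for every significant edge and clinical variable
#'
#' Runs [adjusted_association()] for each edge in a component against each
#' requested clinical variable, within the patient group only.
#'
#' @param study A [group_study()] whose `covariates` include age, sex,
#'   education and the clinical variables.
#' @param edges Data.frame with `region_a`, `region_b` rows to test.
#' @param variables Character vector of covariate column names.
#' @param p_adjust `"none"` (default, matching an uncorrected P < 0.05
#'   convention) or any [stats::p.adjust()] method, applied across all
#'   edge-variable pairs.
#' @return Data.frame: region_a, region_b, variable, coefficient, t, p
#'   (and p_adj unless `p_adjust = "none"`).
#' @export
edge_clinical_associations <- function(study, edges, variables,
                                       p_adjust = "none") {
  stopifnot(inherits(study, "group_study"), !is.null(study$covariates))
  pat <- study$group == levels(study$group)[2]
  cov <- study$covariates[pat, , drop = FALSE]
  regions <- study$regions
  rows <- list()
  for (i in seq_len(nrow(edges))) {
    ia <- match(edges$region_a[i], regions)
    ib <- match(edges$region_b[i], regions)
    if (is.na(ia) || is.na(ib)) {
      stop("edge region not in study: ", edges$region_a[i], " -- ",
           edges$region_b[i])
    }
    ev <- vapply(study$matrices[pat], function(m) m[ia, ib], 0)
    for (v in variables) {
      res <- adjusted_association(ev, cov[[v]], cov$age, cov$sex,
                                  cov$education)
      rows[[length(rows) + 1]] <- data.frame(
        region_a = edges$region_a[i], region_b = edges$region_b[i],
        variable = v, coefficient = res$coefficient, t = res$t, p = res$p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (p_adjust != "none") out$p_adj <- stats::p.adjust(out$p, p_adjust)
  out
}
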