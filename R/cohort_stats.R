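#' Continuity-corrected chi-squared test on a 2x2 table
#'
#' Yates-corrected chi-squared statistic
#' `N * (max(0, |ad - bc| - N/2))^2 / ((a+b)(c+d)(a+c)(b+d))` with 1 df,
#' for a table laid out as rows = groups, columns = yes/no counts.
#' Matches [stats::chisq.test()] with `correct = TRUE`.
#'
#' @param a,b first group's yes/no counts.
#' @param c,d second group's yes/no counts.
#' @return `CohortTestResult`: list with `test`, `statistic`, `df`, `p`,
#'   `degenerate` (TRUE with `p = 1` when a margin is zero).
#' @export
yates_chisq_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be non-negative")
  N <- sum(counts)
  if (N == 0) stop("empty table")
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  if (denom == 0) {
    return(structure(list(test = "yates_chisq_2x2", statistic = 0, df = 1,
                          p = 1, degenerate = TRUE), class = "CohortTestResult"))
  }
  chi <- N * max(0, abs(a * d - b * c) - N / 2)^2 / denom
  structure(list(test = "yates_chisq_2x2", statistic = chi, df = 1,
                 p = stats::pchisq(chi, 1, lower.tail = FALSE), degenerate = FALSE),
            class = "CohortTestResult")
}

#' Pooled-variance two-sample t-test from summary statistics
#'
#' Student's t from means, standard deviations and sample sizes:
#' `sp^2 = ((n1-1) sd1^2 + (n2-1) sd2^2)/(n1+n2-2)`,
#' `t = (m1 - m2)/(sp sqrt(1/n1 + 1/n2))`, `df = n1 + n2 - 2`, two-sided p.
#'
#' @param m1,sd1,n1 first group's mean, sd, size.
#' @param m2,sd2,n2 second group's mean, sd, size.
#' @return `CohortTestResult`: list with `test`, `statistic`, `df`, `p`.
#' @export
pooled_t_from_summary <- function(m1, sd1, n1, m2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  if (sd1 < 0 || sd2 < 0) stop("negative standard deviation")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  df <- n1 + n2 - 2
  if (sp2 == 0) {
    if (m1 == m2) {
      return(structure(list(test = "pooled_t", statistic = 0, df = df, p = 1),
                       class = "CohortTestResult"))
    }
    stop("zero pooled variance with unequal means")
  }
  t <- (m1 - m2) / (sqrt(sp2) * sqrt(1 / n1 + 1 / n2))
  structure(list(test = "pooled_t", statistic = t, df = df,
                 p = 2 * stats::pt(-abs(t), df)), class = "CohortTestResult")
}

#' Fisher's exact test on a 2x2 table
#'
#' Companion output to [yates_chisq_2x2()] for small counts.
#'
#' @param a,b,c,d the table counts, rows = groups.
#' @return `CohortTestResult` with the two-sided exact p.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  ht <- stats::fisher.test(matrix(c(a, c, b, d), nrow = 2))
  structure(list(test = "fisher_exact", statistic = unname(ht$estimate),
                 df = NA_real_, p = ht$p.value), class = "CohortTestResult")
}

#' @export
print.CohortTestResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n", x$test,
              x$statistic, format(x$df), x$p))
  invisible(x)
}

#' Compute a cohort comparison table from printed summaries
#'
#' Reproduces a demographics/clinical comparison table from its printed
#' counts and summary statistics: categorical rows (counts per group, with
#' the complement inferred from group sizes) get the continuity-corrected
#' chi-squared test, continuous rows (mean +/- sd) the pooled-variance
#' Student's t-test. Fisher's exact p is reported alongside for
#' categorical rows.
#'
#' @param summary_df data.frame with columns `variable`, `type`
#'   (`"count"`/`"continuous"`), and either `hd_count`, `hc_count` or
#'   `hd_mean`, `hd_sd`, `hc_mean`, `hc_sd`.
#' @param n_hd,n_hc group sizes.
#' @return data.frame: variable, test, statistic, df, p, fisher_p.
#' @export
cohort_table <- function(summary_df, n_hd, n_hc) {
  rows <- lapply(seq_len(nrow(summary_df)), function(i) {
    r <- summary_df[i, ]
    if (r$type == "count") {
      res <- yates_chisq_2x2(r$hd_count, n_hd - r$hd_count,
                             r$hc_count, n_hc - r$hc_count)
      fp <- fisher_exact_2x2(r$hd_count, n_hd - r$hd_count,
                             r$hc_count, n_hc - r$hc_count)$p
    } else {
      res <- pooled_t_from_summary(r$hd_mean, r$hd_sd, n_hd,
                                   r$hc_mean, r$hc_sd, n_hc)
      fp <- NA_real_
    }
    data.frame(variable = r$variable, test = res$test,
               statistic = res$statistic, df = res$df, p = res$p, fisher_p = fp)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a cohort summary TSV
#'
#' @param path TSV with the columns described in [cohort_table()]. A small
#'   example modeled on a 12-vs-19 dialysis/control cohort ships with the
#'   package: `system.file("extdata", "cohort_summary.tsv", package =
#'   "btmdcnet")`.
#' @return data.frame ready for [cohort_table()].
#' @export
read_cohort_summary <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
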