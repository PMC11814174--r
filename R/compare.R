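comparison_report <- function(test, groups, statistic, p_value,
                              alternative, n, details = list()) {
  structure(list(test = test, groups = groups, statistic = statistic,
                 p_value = p_value, alternative = alternative, n = n,
                 details = details),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> ", x$test, ": ", paste(x$groups, collapse = " vs "),
      "\n  statistic = ", signif(x$statistic, 5), ", p = ",
      signif(x$p_value, 4), " (", x$alternative, "), n = ",
      paste(x$n, collapse = "/"), "\n", sep = "")
  if (isTRUE(x$details$degenerate))
    cat("  [degenerate: zero-variance differences, p set to 1]\n")
  invisible(x)
}

#' Paired t-test between two decoding time courses
#'
#' Pairs the two accuracy curves by window start (the only index the two
#' curves share) and applies a paired t-test to the per-window differences
#' `b - a`. One-sided alternatives refer to that difference:
#' `"greater"` tests whether `b` decodes better than `a`. Zero-variance
#' differences (e.g. identical curves) cannot be tested and return p = 1,
#' flagged as degenerate.
#'
#' @param a,b `decoding_timecourse` objects on identical window grids.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @param labels optional character(2) naming the two curves in the report.
#' @return a `comparison_report`
#' @export
paired_t_timecourses <- function(a, b,
                                 alternative = c("two.sided", "greater",
                                                 "less"),
                                 labels = c("a", "b")) {
  alternative <- match.arg(alternative)
  if (!identical(a$window_start, b$window_start))
    stop("alignment error: time courses have different window grids")
  d <- b$accuracy - a$accuracy
  n <- length(d)
  if (n < 2) stop("need >= 2 windows for a paired test")
  if (sd(d) == 0) {
    return(comparison_report("paired t-test (windows paired by start)",
                             rev(labels), statistic = NA_real_, p_value = 1,
                             alternative = alternative, n = c(n, n),
                             details = list(degenerate = TRUE)))
  }
  ht <- t.test(b$accuracy, a$accuracy, paired = TRUE,
               alternative = alternative)
  comparison_report("paired t-test (windows paired by start)",
                    rev(labels), statistic = unname(ht$statistic),
                    p_value = ht$p.value, alternative = alternative,
                    n = c(n, n),
                    details = list(mean_difference = mean(d),
                                   df = unname(ht$parameter)))
}

#' Mann-Whitney U-test between two window ranges of a separation curve
#'
#' Compares the Mahalanobis distances whose window *starts* fall in
#' `range_a` against those in `range_b` (both inclusive, and required to
#' be disjoint). Small samples (combined n <= 20, no ties) use the exact
#' null distribution; otherwise the normal approximation with tie
#' correction. One-sided alternatives refer to range_b relative to
#' range_a: `"greater"` tests whether separation in `range_b` exceeds
#' that in `range_a`. Note that with a 1-ms slide the D samples are
#' autocorrelated (overlapping windows); `thin` subsamples every
#' `thin`-th window as a robustness option.
#'
#' @param tc a `separation_timecourse`
#' @param range_a,range_b numeric `c(lo, hi)` window-start ranges (ms).
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @param thin keep every `thin`-th window start in each range (default 1:
#'   use all, as in the original procedure).
#' @return a `comparison_report`
#' @export
mannwhitney_windows <- function(tc, range_a, range_b,
                                alternative = c("two.sided", "greater",
                                                "less"),
                                thin = 1) {
  alternative <- match.arg(alternative)
  if (max(range_a[1], range_b[1]) <= min(range_a[2], range_b[2]))
    stop("window ranges [", range_a[1], ", ", range_a[2], "] and [",
         range_b[1], ", ", range_b[2], "] overlap; they must be disjoint")
  pick <- function(rng) {
    s <- tc$window_start >= rng[1] & tc$window_start <= rng[2]
    x <- tc$D[s]
    x[seq(1, length(x), by = thin)]
  }
  x <- pick(range_a)
  y <- pick(range_b)
  if (!length(x) || !length(y))
    stop("a window range selects no samples from the time course")
  exact <- (length(x) + length(y)) <= 20 &&
    !anyDuplicated(c(x, y))
  ht <- suppressWarnings(
    wilcox.test(y, x, alternative = alternative, exact = exact,
                correct = TRUE))
  comparison_report("Mann-Whitney U-test (window-start ranges)",
                    c(paste0("[", range_b[1], ",", range_b[2], "]"),
                      paste0("[", range_a[1], ",", range_a[2], "]")),
                    statistic = unname(ht$statistic), p_value = ht$p.value,
                    alternative = alternative,
                    n = c(length(y), length(x)),
                    details = list(exact = exact, thin = thin))
}

#' Two-proportion z-test
#'
#' Pooled two-proportion z-test (two-sided), as used to compare the
#' fraction of visually responsive neurons before and after category
#' training.
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @return a `comparison_report` (statistic = z).
#' @export
proportion_z_test <- function(k1, n1, k2, n2) {
  if (n1 < 1 || n2 < 1) stop("group sizes must be >= 1")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2)
    stop("successes must lie in [0, n]")
  p1 <- k1 / n1
  p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  comparison_report("two-proportion z-test (pooled)",
                    c(sprintf("%d/%d", k1, n1), sprintf("%d/%d", k2, n2)),
                    statistic = z, p_value = 2 * pnorm(-abs(z)),
                    alternative = "two.sided", n = c(n1, n2),
                    details = list(p1 = p1, p2 = p2, pooled = pp))
}

# serializable form of a comparison report
.report_to_list <- function(x) {
  list(test = x$test, groups = as.list(x$groups),
       statistic = x$statistic, p_value = x$p_value,
       alternative = x$alternative, n = as.list(x$n),
       details = x$details)
}
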