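#' Sample summary in mean / SEM / SD / n form
#'
#' @param x Numeric sample (n >= 1).
#' @return List with `mean`, `sem`, `sd`, `n`; `sd`/`sem` are NA for n = 1.
#' @export
summarize_sample <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) stop("empty sample")
  s <- if (n > 1L) stats::sd(x) else NA_real_
  list(mean = mean(x), sem = if (n > 1L) s / sqrt(n) else NA_real_,
       sd = s, n = n)
}

#' Format a summary the caption way
#'
#' @param s A [summarize_sample()] result.
#' @param digits Significant digits.
#' @return `"mean ± SEM, SD = sd, n = n"` string.
#' @export
format_summary <- function(s, digits = 3) {
  sprintf("%s ± %s, SD = %s, n = %d",
          signif(s$mean, digits), signif(s$sem, digits), signif(s$sd, digits),
          s$n)
}

#' Jarque-Bera normality test
#'
#' Classic moment-based test: with sample skewness S and kurtosis K,
#' \eqn{JB = n/6 (S^2 + (K-3)^2/4)}, compared against a chi-square
#' distribution with 2 degrees of freedom.
#'
#' @param x Numeric sample (n >= 3).
#' @return List with `statistic` and `p.value`.
#' @export
jarque_bera <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) stop("Jarque-Bera test needs at least 3 observations")
  m <- x - mean(x)
  m2 <- mean(m^2)
  if (m2 == 0) return(list(statistic = 0, p.value = 1))
  s <- mean(m^3) / m2^1.5
  k <- mean(m^4) / m2^2
  jb <- n / 6 * (s^2 + (k - 3)^2 / 4)
  list(statistic = jb, p.value = stats::pchisq(jb, df = 2, lower.tail = FALSE))
}

#' Gated choice between Student's t and Mann-Whitney
#'
#' Both samples are tested for normality (Jarque-Bera) and for equality of
#' variances (two-tailed F-test). Student's (pooled-variance) t-test is
#' selected iff all three gate p-values exceed `alpha`; otherwise the
#' Mann-Whitney-Wilcoxon test.
#'
#' @param x,y Numeric samples (each n >= 3).
#' @param alpha Gate significance level.
#' @return List: `test` ("student_t"/"mann_whitney"), `normality_p_x`,
#'   `normality_p_y`, `variance_p`.
#' @export
select_two_sample_test <- function(x, y, alpha = 0.05) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3L || length(y) < 3L) {
    stop("both samples need at least 3 observations")
  }
  p_nx <- jarque_bera(x)$p.value
  p_ny <- jarque_bera(y)$p.value
  p_var <- stats::var.test(x, y)$p.value
  test <- if (p_nx > alpha && p_ny > alpha && p_var > alpha) {
    "student_t"
  } else "mann_whitney"
  list(test = test, normality_p_x = p_nx, normality_p_y = p_ny,
       variance_p = p_var)
}

#' Gated two-sample comparison
#'
#' Runs [select_two_sample_test()] and executes the selected test two-tailed:
#' pooled-variance Student's t (the gate already required equal variances) or
#' Mann-Whitney-Wilcoxon (exact for small tie-free samples, otherwise the
#' tie-corrected normal approximation with continuity correction).
#'
#' @param x,y Numeric samples (each n >= 3).
#' @param alpha Gate significance level.
#' @return Object of class `group_comparison`: `test_used`, `statistic`,
#'   `p`, gate p-values, and `summary_x`/`summary_y`.
#' @export
run_two_sample <- function(x, y, alpha = 0.05) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  gate <- select_two_sample_test(x, y, alpha)
  if (gate$test == "student_t") {
    tt <- stats::t.test(x, y, var.equal = TRUE)
    statistic <- unname(tt$statistic); p <- tt$p.value
  } else {
    exact <- length(x) < 50 && length(y) < 50 &&
      !anyDuplicated(c(x, y))
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                              correct = !exact))
    statistic <- unname(wt$statistic); p <- wt$p.value
  }
  structure(list(test_used = gate$test, statistic = statistic, p = p,
                 normality_p_x = gate$normality_p_x,
                 normality_p_y = gate$normality_p_y,
                 variance_p = gate$variance_p,
                 summary_x = summarize_sample(x),
                 summary_y = summarize_sample(y)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison (%s): statistic %.4g, p = %.3g\n",
              x$test_used, x$statistic, x$p))
  cat("  x:", format_summary(x$summary_x), "\n")
  cat("  y:", format_summary(x$summary_y), "\n")
  invisible(x)
}

#' Kruskal-Wallis omnibus with Dunn's post-hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H (via [stats::kruskal.test()]) followed by
#' Dunn's pairwise z statistics on the pooled ranks,
#' \deqn{z_{ij} = \frac{\bar R_i - \bar R_j}
#'   {\sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum_t (t^3 - t)}{12 (N-1)}\right)
#'    \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}},}
#' with multiplicity adjustment of the two-sided p-values.
#'
#' @param groups Named list of >= 3 numeric samples (each n >= 2).
#' @param p_adjust Multiplicity correction: "holm" (default), "bonferroni"
#'   or "sidak".
#' @return List: `h`, `df`, `p_omnibus`, and `pairwise` (data.frame
#'   `group1`, `group2`, `z`, `p`, `p_adj`).
#' @export
kruskal_dunn <- function(groups, p_adjust = c("holm", "bonferroni", "sidak")) {
  p_adjust <- match.arg(p_adjust)
  if (length(groups) < 3L) {
    stop("kruskal_dunn needs >= 3 groups; use the two-sample path (run_two_sample) instead")
  }
  if (any(vapply(groups, length, 1L) < 2L)) {
    stop("every group needs at least 2 observations")
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(names(groups), vapply(groups, length, 1L)),
                levels = names(groups))
  kw <- stats::kruskal.test(values, grp)
  N <- length(values)
  rk <- rank(values)
  rbar <- tapply(rk, grp, mean)
  ni <- tapply(rk, grp, length)
  tie_tab <- table(values)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  var0 <- N * (N + 1) / 12 - tie_term
  combs <- utils::combn(names(groups), 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(combs)), function(c0) {
    g1 <- combs[1, c0]; g2 <- combs[2, c0]
    z <- (rbar[[g1]] - rbar[[g2]]) /
      sqrt(var0 * (1 / ni[[g1]] + 1 / ni[[g2]]))
    data.frame(group1 = g1, group2 = g2, z = z,
               p = 2 * stats::pnorm(-abs(z)))
  }))
  pw$p_adj <- if (p_adjust == "sidak") {
    pmin(1, 1 - (1 - pw$p)^nrow(pw))
  } else stats::p.adjust(pw$p, method = p_adjust)
  list(h = unname(kw$statistic), df = unname(kw$parameter),
       p_omnibus = kw$p.value, pairwise = pw)
}
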