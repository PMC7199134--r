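# Cohort-level densities, hypothesis tests and effect sizes over
# participant pattern summaries.

#' Density estimate of a pattern's cohort distribution
#'
#' Discrete variables get a normalized histogram over the observed support;
#' continuous variables a Gaussian-kernel KDE with Silverman's
#' rule-of-thumb bandwidth.
#'
#' @param values numeric sample (n >= 2)
#' @param kind "discrete-histogram" or "continuous-kde"
#' @return data.frame(x, density); for the discrete kind, \code{density}
#'   are probability masses summing to 1
#' @export
density_estimate <- function(values, kind = c("continuous-kde", "discrete-histogram")) {
  kind <- match.arg(kind)
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 observations")
  if (kind == "discrete-histogram") {
    tab <- table(values)
    data.frame(x = as.numeric(names(tab)), density = as.numeric(tab) / length(values))
  } else {
    # exact Gaussian kernel sums (no FFT binning) on a 512-point grid
    bw <- stats::bw.nrd0(values)
    grid <- seq(min(values) - 5 * bw, max(values) + 5 * bw, length.out = 512)
    y <- vapply(grid, function(p) mean(stats::dnorm((p - values) / bw)) / bw, 1)
    data.frame(x = grid, density = y)
  }
}

#' Two-sample distribution comparison
#'
#' Continuous samples are compared with the two-sample Kolmogorov-Smirnov
#' test (asymptotic p-value); discrete samples with a Pearson chi-square
#' test on the two-group contingency of category counts (no continuity
#' correction; a message is logged when any expected count is below 5).
#' The null hypothesis is that both samples come from the same underlying
#' distribution.
#'
#' @param a,b numeric samples
#' @param discrete logical
#' @return list(statistic, p_value, test)
#' @export
compare_distributions <- function(a, b, discrete = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs at least 2 observations")
  if (discrete) {
    lev <- sort(unique(c(a, b)))
    tab <- rbind(tabulate(match(a, lev), length(lev)),
                 tabulate(match(b, lev), length(lev)))
    exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(exp_counts < 5)) {
      message("chi-square: some expected counts below 5; p-value approximate")
    }
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
         test = "chi-square")
  } else {
    kt <- suppressWarnings(ks.test(a, b, exact = FALSE))
    list(statistic = unname(kt$statistic), p_value = unname(kt$p.value),
         test = "ks")
  }
}

#' Point-biserial correlation between a pattern and group membership
#'
#' Pearson correlation of the values with a 0/1 coding of the labels; the
#' first-listed group is coded 0, so a negative r means lower scores in
#' that group.
#'
#' @param values numeric vector
#' @param labels vector with exactly two levels; the first level (by factor
#'   order or first appearance) is coded 0
#' @return r in [-1, 1]; NA when the values have zero variance
#' @export
point_biserial <- function(values, labels) {
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]; labels <- labels[ok]
  lev <- if (is.factor(labels)) levels(droplevels(labels)) else unique(labels)
  if (length(lev) != 2L) stop("labels must have exactly two levels present")
  if (length(values) < 3L) stop("need at least 3 observations")
  y <- as.numeric(labels == lev[2])
  if (sd(values) == 0 || sd(y) == 0) return(NA_real_)
  unname(cor(values, y))
}

#' Pairwise group comparison report over participant summaries
#'
#' For every pattern mean and every pair of groups: a distribution test
#' (KS, or chi-square for patterns listed as discrete) plus the
#' point-biserial correlation with group membership, with significance
#' (p < .05) and strength (|r| > 0.3) flags. No multiple-comparison
#' correction is applied; effect sizes are reported alongside p-values
#' instead, and rows are ranked by |r|.
#'
#' @param summaries list of \code{\link{summarize_participant}} outputs
#' @param labels group label per participant
#' @param discrete_patterns patterns tested with the chi-square (counts)
#' @param alpha significance level (default .05)
#' @param r_strong threshold for a "statistically strong" association
#' @return data.frame of class \code{group_comparison}: pattern, pair,
#'   test, statistic, p_value, point_biserial_r, significant, strong
#' @export
pairwise_group_report <- function(summaries, labels,
                                  discrete_patterns = "n_wake_ups",
                                  alpha = 0.05, r_strong = 0.3) {
  if (length(summaries) != length(labels)) stop("one label per participant required")
  groups <- unique(labels)
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(table(labels) < 3L)) stop("need at least 3 participants per group")
  reg <- pattern_registry()
  mat <- t(vapply(summaries, function(s) s$mean[reg], setNames(numeric(length(reg)), reg)))
  out <- list()
  for (gi in seq_len(length(groups) - 1L)) for (gj in (gi + 1L):length(groups)) {
    g1 <- groups[gi]; g2 <- groups[gj]
    pair <- sprintf("%s vs %s", g1, g2)
    sel <- labels %in% c(g1, g2)
    for (p in reg) {
      a <- mat[labels == g1, p]; b <- mat[labels == g2, p]
      if (all(is.na(a)) || all(is.na(b))) {
        message("pattern ", p, " missing for a whole group in ", pair, "; skipped")
        next
      }
      disc <- p %in% discrete_patterns
      cmp <- tryCatch(
        compare_distributions(if (disc) round(a) else a, if (disc) round(b) else b,
                              discrete = disc),
        error = function(e) list(statistic = NA_real_, p_value = NA_real_,
                                 test = if (disc) "chi-square" else "ks"))
      r <- tryCatch(point_biserial(mat[sel, p],
                                   factor(labels[sel], levels = c(g1, g2))),
                    error = function(e) NA_real_)
      out[[length(out) + 1L]] <- data.frame(
        pattern = p, pair = pair, test = cmp$test,
        statistic = cmp$statistic, p_value = cmp$p_value,
        point_biserial_r = r,
        significant = isTRUE(cmp$p_value < alpha),
        strong = isTRUE(abs(r) > r_strong))
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(-abs(res$point_biserial_r)), ]
  rownames(res) <- NULL
  class(res) <- c("group_comparison", "data.frame")
  res
}
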