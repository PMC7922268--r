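# Cohort statistics: group summaries (mean +/- SD, range), Welch t-test,
# one-way ANOVA with Tukey HSD and a compact-letter display, Pearson
# chi-squared, balance-rate tables and imbalance histograms.

#' Group summary of an imbalance metric
#'
#' Arithmetic mean, sample SD (n-1 denominator), minimum and maximum of one
#' metric, optionally filtered by alignment group and/or posterior reference
#' method — the "Mean +/- SD (Range)" cell of a cohort table.
#'
#' @param records Imbalance record data frame (see [simulate_cohort()]).
#' @param metric Column name, e.g. `"mli_ext"`, `"mli_flex"`, `"fei_med"`.
#' @param group Optional `"varus"`/`"valgus"` filter.
#' @param method Optional method filter (`"TEA"`, ...).
#' @return List of class `group_summary`: `n`, `mean`, `sd`, `min`, `max`.
#'   `sd` is `NA` when `n = 1`.
#' @export
summarize_metric <- function(records, metric, group = NULL, method = NULL) {
  if (!metric %in% names(records))
    stop(sprintf("no column '%s' in records", metric), call. = FALSE)
  keep <- rep(TRUE, nrow(records))
  if (!is.null(group)) keep <- keep & records$group == group
  if (!is.null(method)) keep <- keep & records$method == method
  x <- records[[metric]][keep]
  if (length(x) == 0L) stop("empty selection", call. = FALSE)
  structure(list(n = length(x), mean = mean(x),
                 sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
                 min = min(x), max = max(x)),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("n = %d: %.2f +/- %s (%.2f, %.2f)\n", x$n, x$mean,
              if (is.na(x$sd)) "NA" else sprintf("%.2f", x$sd), x$min, x$max))
  invisible(x)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations", call. = FALSE)
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

# compact-letter display: groups (ordered by decreasing mean) share a letter
# iff they belong to a common maximal clique of the "not significantly
# different" graph; brute-force over subsets (k is small)
.compact_letters <- function(means, pmat, alpha = 0.05) {
  k <- length(means)
  ord <- order(-means)
  ns <- pmat > alpha | is.na(pmat)
  diag(ns) <- TRUE
  cliques <- list()
  for (mask in seq_len(2^k - 1L)) {
    members <- which(bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0L)
    if (all(ns[members, members])) cliques[[length(cliques) + 1L]] <- members
  }
  keep <- vapply(cliques, function(cl) {
    !any(vapply(cliques, function(other)
      length(other) > length(cl) && all(cl %in% other), TRUE))
  }, TRUE)
  cliques <- cliques[keep]
  # order cliques by the best-ranked member so letters follow the mean order
  cliques <- cliques[order(vapply(cliques, function(cl) min(match(cl, ord)), 0))]
  letters_out <- rep("", k)
  for (i in seq_along(cliques))
    letters_out[cliques[[i]]] <- paste0(letters_out[cliques[[i]]], letters[i])
  names(letters_out) <- names(means)
  letters_out
}

#' One-way ANOVA with Tukey HSD post hoc
#'
#' Compares three or more groups (the reference methods); pairwise Tukey
#' honest-significant-difference comparisons are condensed into a
#' compact-letter display (groups sharing a letter are not significantly
#' different at `alpha`).
#'
#' @param values Numeric vector of observations.
#' @param groups Factor/character vector of group labels (>= 3 levels).
#' @param alpha Significance level for the letter display (default 0.05).
#' @return List with `F`, `p`, `tukey` (data frame of pairwise comparisons)
#'   and `letters` (named character vector).
#' @export
anova_posthoc <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 3L) stop("need at least 3 groups", call. = FALSE)
  if (any(table(groups) < 2L))
    stop("every group needs at least 2 observations", call. = FALSE)
  d <- data.frame(y = values, g = groups)
  fit <- stats::aov(y ~ g, data = d)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  pmat <- matrix(NA_real_, nlevels(groups), nlevels(groups),
                 dimnames = list(levels(groups), levels(groups)))
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(pairs)) {
    a <- pairs[[i]][1]; b <- pairs[[i]][2]
    pmat[a, b] <- pmat[b, a] <- tk[i, "p adj"]
  }
  means <- tapply(values, groups, mean)
  list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1],
       tukey = as.data.frame(tk),
       letters = .compact_letters(means, pmat, alpha))
}

#' Pearson chi-squared test on a contingency table
#'
#' No continuity correction; df = (r-1)(c-1). Errors on zero expected
#' counts.
#'
#' @param counts Integer matrix (e.g. 2 x k).
#' @return List with `chi2`, `df`, `p`.
#' @export
chi_squared <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected <= 0)) stop("zero expected cell count", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Balance-rate table
#'
#' Percentage of knees per method and alignment group whose medial and
#' lateral flexion-extension imbalances are simultaneously within each
#' threshold.
#'
#' @param records Imbalance record data frame.
#' @param thresholds Positive thresholds in mm (default 1, 2, 3).
#' @return Data frame with columns `method`, `group`, `threshold`, `n`,
#'   `rate` (percent, in `[0, 100]`, non-decreasing in threshold).
#' @export
balance_rate_table <- function(records, thresholds = c(1, 2, 3)) {
  if (nrow(records) == 0L) stop("no records", call. = FALSE)
  if (any(thresholds <= 0)) stop("thresholds must be positive", call. = FALSE)
  out <- expand.grid(method = unique(records$method),
                     group = unique(records$group),
                     threshold = sort(thresholds),
                     stringsAsFactors = FALSE)
  out$n <- NA_integer_; out$rate <- NA_real_
  for (i in seq_len(nrow(out))) {
    sel <- records[records$method == out$method[i] &
                     records$group == out$group[i], ]
    ok <- balanced_both_compartments(sel$fei_med, sel$fei_lat, out$threshold[i])
    out$n[i] <- nrow(sel)
    out$rate[i] <- 100 * mean(ok)
  }
  out
}

#' Imbalance histogram
#'
#' Half-open 1 mm (by default) bins `[k, k + width)` covering the observed
#' range; proportions sum to 1.
#'
#' @param records Imbalance record data frame.
#' @param metric Column name of the imbalance metric.
#' @param bin_width Bin width in mm (default 1).
#' @return Data frame with `bin_left`, `bin_right`, `count`, `proportion`.
#' @export
imbalance_histogram <- function(records, metric, bin_width = 1) {
  x <- records[[metric]]
  if (is.null(x) || length(x) == 0L) stop("no values to bin", call. = FALSE)
  lo <- floor(min(x) / bin_width) * bin_width
  hi <- floor(max(x) / bin_width) * bin_width + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  idx <- findInterval(x, breaks, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  data.frame(bin_left = breaks[-length(breaks)], bin_right = breaks[-1L],
             count = counts, proportion = counts / length(x))
}
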