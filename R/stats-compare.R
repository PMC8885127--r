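testResult <- function(statistic, df, p_value, method, post_hoc = NULL) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), method = method,
                 post_hoc = post_hoc),
            class = "vmTestResult")
}

#' @export
print.vmTestResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n", x$method,
              x$statistic, paste(x$df, collapse = ","), x$p_value))
  if (!is.null(x$post_hoc) && nrow(x$post_hoc)) {
    cat("post hoc:\n")
    print(x$post_hoc, row.names = FALSE)
  }
  invisible(x)
}

#' Stratified Cochran-Mantel-Haenszel test with Fisher post hocs
#'
#' Tests the association between a two-level outcome (e.g.
#' responsive/non-responsive) and K groups (vessel categories) across S
#' strata (stimulus conditions) with the generalized Cochran-Mantel-
#' Haenszel statistic. Strata with a zero row or column margin are dropped
#' with a warning. Post hoc comparisons are pairwise Fisher exact tests on
#' the 2x2 tables collapsed over strata, Holm-adjusted by default.
#'
#' @param counts numeric array `2 x K x S` (a single-stratum `2 x K` matrix
#'   is promoted to `S = 1`).
#' @param post_hoc_adjust `"holm"` (default) or `"none"`.
#' @return A test-result list: `statistic`, `df`, `p_value`, `method`,
#'   `post_hoc` (data.frame of `pair`, `p_raw`, `p_adjusted`).
#' @export
cmhTest <- function(counts, post_hoc_adjust = c("holm", "none")) {
  post_hoc_adjust <- match.arg(post_hoc_adjust)
  if (length(dim(counts)) == 2L)
    counts <- array(counts, dim = c(dim(counts), 1L),
                    dimnames = c(dimnames(counts), list(NULL)))
  stopifnot(length(dim(counts)) == 3L, dim(counts)[1] == 2L)
  ok <- vapply(seq_len(dim(counts)[3]), function(s) {
    tab <- counts[, , s]
    all(rowSums(tab) > 0) && all(colSums(tab) > 0) && sum(tab) > 1
  }, logical(1))
  if (!all(ok)) {
    warning(sum(!ok), " degenerate stratum/strata dropped")
    counts <- counts[, , ok, drop = FALSE]
  }
  if (dim(counts)[3] == 0) stop("no usable stratum")
  if (dim(counts)[3] == 1L) {
    # single stratum: the generalized CMH statistic reduces to
    # (N - 1)/N times the Pearson chi-square of the collapsed table
    tab <- counts[, , 1]
    N <- sum(tab)
    E <- outer(rowSums(tab), colSums(tab)) / N
    stat <- (N - 1) / N * sum((tab - E)^2 / E)
    df <- (nrow(tab) - 1) * (ncol(tab) - 1)
    ht <- list(statistic = stat, parameter = df,
               p.value = stats::pchisq(stat, df, lower.tail = FALSE))
  } else {
    ht <- stats::mantelhaen.test(counts, correct = FALSE)
  }
  K <- dim(counts)[2]
  groups <- dimnames(counts)[[2]]
  if (is.null(groups)) groups <- as.character(seq_len(K))
  collapsed <- apply(counts, c(1, 2), sum)
  ph <- NULL
  if (K > 2) {
    pairs <- utils::combn(K, 2)
    p_raw <- apply(pairs, 2, function(ij) {
      stats::fisher.test(collapsed[, ij])$p.value
    })
    p_adj <- if (post_hoc_adjust == "holm")
      stats::p.adjust(p_raw, "holm") else p_raw
    ph <- data.frame(
      pair = apply(pairs, 2, function(ij)
        paste(groups[ij], collapse = " vs ")),
      p_raw = p_raw, p_adjusted = p_adj, stringsAsFactors = FALSE)
  }
  testResult(ht$statistic, ht$parameter, ht$p.value,
             "Cochran-Mantel-Haenszel (generalized, uncorrected)", ph)
}

#' Pearson chi-square test of independence
#'
#' Pearson chi-square on an R x C contingency table with
#' `(R - 1)(C - 1)` degrees of freedom and no continuity correction. Rows
#' or columns with a zero margin are dropped with a warning.
#'
#' @param counts numeric matrix of nonnegative counts (>= 2 x 2 after
#'   dropping zero margins).
#' @return A test-result list.
#' @export
chiSquareIndependence <- function(counts) {
  counts <- as.matrix(counts)
  keep_r <- rowSums(counts) > 0
  keep_c <- colSums(counts) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("zero-margin rows/columns dropped")
    counts <- counts[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("need at least a 2x2 table after dropping zero margins")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  testResult(ht$statistic, ht$parameter, ht$p.value,
             "Pearson chi-square (uncorrected)")
}

#' Kruskal-Wallis test with pairwise Wilcoxon rank-sum post hocs
#'
#' Tie-corrected Kruskal-Wallis H with the chi-square approximation, then
#' pairwise two-sided Wilcoxon rank-sum tests: exact when both groups have
#' at most 8 observations and there are no ties, otherwise the normal
#' approximation with continuity correction. Post hoc p values are
#' unadjusted by default (matching common reporting), with Holm adjustment
#' available.
#'
#' @param groups list of numeric vectors (>= 2 groups, each nonempty).
#' @param post_hoc_adjust `"none"` (default) or `"holm"`.
#' @return A test-result list with a `post_hoc` table.
#' @export
kruskalWallisPosthoc <- function(groups, post_hoc_adjust = c("none", "holm")) {
  post_hoc_adjust <- match.arg(post_hoc_adjust)
  stopifnot(is.list(groups), length(groups) >= 2,
            all(lengths(groups) >= 1))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1L) {
    res <- testResult(0, length(groups) - 1, 1,
                      "Kruskal-Wallis (degenerate: all values identical)")
    return(res)
  }
  ht <- stats::kruskal.test(x, g)
  nm <- names(groups)
  if (is.null(nm)) nm <- as.character(seq_along(groups))
  pairs <- utils::combn(length(groups), 2)
  p_raw <- apply(pairs, 2, function(ij) {
    a <- groups[[ij[1]]]; b <- groups[[ij[2]]]
    exact <- length(a) <= 8 && length(b) <= 8 &&
      !any(duplicated(c(a, b)))
    suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
  })
  p_adj <- if (post_hoc_adjust == "holm") stats::p.adjust(p_raw, "holm")
           else p_raw
  ph <- data.frame(
    pair = apply(pairs, 2, function(ij) paste(nm[ij], collapse = " vs ")),
    p_raw = p_raw, p_adjusted = p_adj, stringsAsFactors = FALSE)
  testResult(ht$statistic, ht$parameter, ht$p.value,
             "Kruskal-Wallis with pairwise Wilcoxon rank-sum", ph)
}

#' One-way ANOVA with Tukey HSD post hocs
#'
#' Standard one-way F test followed by Tukey honest significant differences
#' (studentized-range adjusted pairwise p values). With zero residual
#' variance and unequal means the p value is reported as 0 with a
#' degenerate-variance flag in the method string; identical groups give
#' F = 0, p = 1.
#'
#' @param groups list of numeric vectors (each >= 2 values; residual
#'   df >= 1).
#' @return A test-result list with a `post_hoc` table.
#' @export
anovaTukey <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(lengths(groups) >= 2))
  x <- unlist(groups, use.names = FALSE)
  nm <- names(groups)
  if (is.null(nm)) nm <- as.character(seq_along(groups))
  g <- factor(rep(nm, lengths(groups)), levels = nm)
  df1 <- length(groups) - 1L
  df2 <- length(x) - length(groups)
  if (df2 < 1) stop("residual degrees of freedom must be >= 1")
  means <- tapply(x, g, mean)
  ssw <- sum((x - means[g])^2)
  if (ssw == 0) {
    if (stats::var(means) == 0)
      return(testResult(0, c(df1, df2), 1, "one-way ANOVA (all identical)"))
    return(testResult(Inf, c(df1, df2), 0,
                      "one-way ANOVA (zero residual variance)"))
  }
  fit <- stats::aov(x ~ g)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  ph <- data.frame(pair = gsub("-", " vs ", rownames(tk), fixed = TRUE),
                   p_raw = NA_real_, p_adjusted = tk[, "p adj"],
                   stringsAsFactors = FALSE)
  testResult(an$`F value`[1], c(an$Df[1], an$Df[2]), an$`Pr(>F)`[1],
             "one-way ANOVA with Tukey HSD", ph)
}

#' One-sample t test against 1
#'
#' Two-sided one-sample t test of the mean against 1, as used for
#' branch-point diameter and ISD ratios (a ratio of 1 means no branch-point
#' specialization).
#'
#' @param values numeric vector, n >= 2 with positive SD.
#' @param mu null value (default 1).
#' @return A test-result list.
#' @export
oneSampleVsOne <- function(values, mu = 1) {
  if (length(values) < 2) stop("need at least two values")
  if (stats::sd(values) == 0)
    stop("zero standard deviation: t statistic undefined")
  ht <- stats::t.test(values, mu = mu)
  testResult(ht$statistic, ht$parameter, ht$p.value,
             sprintf("one-sample t vs %g", mu))
}

#' Holm-Bonferroni correction
#'
#' Step-down Holm adjustment of a vector of p values: the i-th smallest p
#' is multiplied by (m - i + 1), running maxima enforce monotonicity and
#' values are capped at 1.
#'
#' @param p_values numeric vector of p values in \[0, 1\].
#' @return Adjusted p values in the original order.
#' @examples
#' holmBonferroni(c(0.01, 0.04, 0.03))  # 0.03 0.06 0.06
#' @export
holmBonferroni <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "holm")
}
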