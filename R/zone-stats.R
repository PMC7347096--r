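#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected Kruskal-Wallis H statistic with a chi-squared reference on
#' `g - 1` degrees of freedom, as used for genotype and year effects on zone
#' and shoot variables.
#'
#' @param data A data frame.
#' @param value Name of the numeric response column.
#' @param group Name of the grouping column (>= 2 levels present).
#' @return A one-row tibble: `variable`, `n_groups`, `n`, `statistic`, `df`,
#'   `p_value`.
#' @export
kruskal_wallis <- function(data, value, group) {
  x <- data[[value]]
  g <- factor(data[[group]])
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2) abort("Kruskal-Wallis needs at least two groups.")
  if (length(x) < 3) abort("Kruskal-Wallis needs total n >= 3.")
  if (length(unique(x)) == 1) {
    # fully tied data: the tie-corrected statistic is 0/0; report no effect
    return(tibble::tibble(variable = value, n_groups = nlevels(g),
                          n = length(x), statistic = 0,
                          df = nlevels(g) - 1, p_value = 1))
  }
  kt <- kruskal.test(x, g)
  tibble::tibble(
    variable = value, n_groups = nlevels(g), n = length(x),
    statistic = unname(kt$statistic), df = unname(kt$parameter),
    p_value = kt$p.value
  )
}

# Two-sided Wilcoxon-Mann-Whitney p-value. Exact distribution when both
# groups have n <= 10 and there are no ties; otherwise the normal
# approximation with tie and continuity correction.
wmw_p <- function(x, y) {
  exact <- length(x) <= 10 && length(y) <= 10 && !anyDuplicated(c(x, y))
  suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE, alternative = "two.sided")
  )$p.value
}

#' Pairwise Wilcoxon-Mann-Whitney comparisons with compact letters
#'
#' Runs all pairwise two-sided rank-sum tests between groups and summarises
#' the significance structure as a compact letter display: groups sharing a
#' letter are not significantly different at `alpha`. No multiple-testing
#' correction is applied by default, mirroring letters reported at p < 0.05;
#' `adjust = "holm"` (or any `p.adjust` method) is available.
#'
#' @inheritParams kruskal_wallis
#' @param alpha Significance level for the letter display (default 0.05).
#' @param adjust Multiple-testing adjustment applied to the pairwise p-value
#'   matrix, a `p.adjust` method name; `"none"` (default) mirrors unadjusted
#'   reporting.
#' @return An object of class `group_comparison`: tibbles `groups` (n, mean,
#'   median, letters), the omnibus Kruskal-Wallis `test`, and the symmetric
#'   pairwise `p_matrix`.
#' @export
pairwise_wilcoxon_letters <- function(data, value, group, alpha = 0.05,
                                      adjust = "none") {
  x <- data[[value]]
  g <- factor(data[[group]])
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- droplevels(g[keep])
  lv <- levels(g)
  if (length(lv) < 2) abort("Need at least two groups to compare.")
  if (any(table(g) == 0)) abort("Empty group supplied.")
  P <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in seq_along(lv)) {
    for (j in seq_along(lv)) {
      if (j <= i) next
      P[i, j] <- P[j, i] <- wmw_p(x[g == lv[i]], x[g == lv[j]])
    }
  }
  if (adjust != "none") {
    up <- upper.tri(P)
    P[up] <- stats::p.adjust(P[up], method = adjust)
    P[lower.tri(P)] <- t(P)[lower.tri(P)]
  }
  letters <- compact_letters(P, alpha = alpha)
  omnibus <- if (length(lv) >= 2 && length(x) >= 3) {
    kw <- kruskal_wallis(tibble::tibble(v = x, g = g), "v", "g")
    kw$variable <- value
    kw
  } else NULL
  groups <- tibble::tibble(
    group = lv,
    n = as.integer(table(g)[lv]),
    mean = vapply(lv, function(l) mean(x[g == l]), 0),
    median = vapply(lv, function(l) median(x[g == l]), 0),
    letters = letters[lv]
  )
  structure(list(variable = value, groups = groups, test = omnibus,
                 p_matrix = P, alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Pairwise Wilcoxon-Mann-Whitney comparison of", x$variable,
      "(alpha =", x$alpha, ")\n")
  if (!is.null(x$test)) {
    cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g\n",
                x$test$statistic, x$test$df, x$test$p_value))
  }
  print(x$groups)
  invisible(x)
}

#' @export
tidy.group_comparison <- function(x, ...) x$groups

#' @export
glance.group_comparison <- function(x, ...) {
  if (is.null(x$test)) {
    return(tibble::tibble(variable = x$variable, statistic = NA_real_,
                          df = NA_real_, p_value = NA_real_))
  }
  dplyr::select(x$test, "variable", "statistic", "df", "p_value")
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Insert-and-absorb assignment: groups are processed in order; each
#' significant pair must end up sharing no letter, each non-significant pair
#' must share at least one, and redundant letter columns are absorbed. The
#' result is a valid clique cover of the non-significance graph.
#'
#' @param P Symmetric matrix of pairwise p-values with group names on the
#'   dimnames; the diagonal is ignored.
#' @param alpha Significance threshold.
#' @return Named character vector of letter strings, one per group.
#' @export
compact_letters <- function(P, alpha = 0.05) {
  g <- nrow(P)
  nm <- rownames(P)
  # columns of a logical membership matrix are the letters
  M <- matrix(TRUE, g, 1)
  for (i in seq_len(g)) {
    for (j in seq_len(g)) {
      if (j <= i) next
      if (!is.na(P[i, j]) && P[i, j] < alpha) {
        # i and j must not share any letter: duplicate offending columns
        shared <- which(M[i, ] & M[j, ])
        for (col in shared) {
          M <- cbind(M, M[, col])
          M[j, col] <- FALSE
          M[i, ncol(M)] <- FALSE
        }
        # absorb: drop any column whose membership set is contained in another
        keep <- rep(TRUE, ncol(M))
        for (a in seq_len(ncol(M))) {
          for (b in seq_len(ncol(M))) {
            if (a != b && keep[a] && keep[b] && all(M[, a] <= M[, b])) {
              keep[a] <- FALSE
            }
          }
        }
        M <- M[, keep, drop = FALSE]
      }
    }
  }
  M <- M[, order(apply(M, 2, function(col) which(col)[1])), drop = FALSE]
  lab <- vapply(seq_len(g), function(i) {
    paste(letters[which(M[i, ])], collapse = "")
  }, "")
  setNames(lab, nm)
}

#' Pearson chi-squared test on a contingency table
#'
#' Pearson chi-squared statistic with `(r - 1)(c - 1)` degrees of freedom and
#' no continuity correction, for comparing zone-occurrence or survival
#' proportions across groups.
#'
#' @param counts An `r x c` matrix of nonnegative integer counts with every
#'   row and column margin positive.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `n`.
#' @export
proportion_chi2 <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || anyNA(counts)) abort("Counts must be nonnegative.")
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    abort("Contingency table needs at least 2 rows and 2 columns (df > 0).")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("Every margin of the contingency table must be positive.")
  }
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = ct$p.value, n = sum(counts))
}

#' Spearman rank correlation with significance limits
#'
#' Tie-aware Spearman rho (Pearson correlation of mid-ranks) together with the
#' large-sample significance limit `z[1 - alpha/2] / sqrt(n - 1)`: observed
#' coefficients between `-limit` and `+limit` are reported as not
#' significantly different from zero.
#'
#' @param x,y Paired numeric vectors, `n >= 4` complete pairs.
#' @param alpha Significance level (default 0.05).
#' @param label Optional pair label carried into the output.
#' @return A one-row tibble: `pair`, `n`, `rho`, `limit`, `significant`.
#' @export
spearman_with_limits <- function(x, y, alpha = 0.05, label = NULL) {
  label <- label %||% paste(deparse1(substitute(x)), "vs",
                            deparse1(substitute(y)))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) abort("Spearman correlation needs at least 4 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Spearman rho is undefined for a constant vector.")
  }
  rho <- cor(x, y, method = "spearman")
  limit <- qnorm(1 - alpha / 2) / sqrt(n - 1)
  tibble::tibble(
    pair = label,
    n = n, rho = rho, limit = limit,
    significant = abs(rho) > limit
  )
}
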