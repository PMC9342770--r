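## Group-level statistics: Mann-Whitney-Wilcoxon comparisons (exact by full
## enumeration for small samples, including ties; tie-corrected normal
## approximation otherwise), percent and fold change of group means, and
## time-course first-appearance tabulation.

#' Two-sample Mann-Whitney-Wilcoxon test
#'
#' Two-sided rank-sum test. The U statistic counts pairs with `a > b` plus
#' half the tied pairs (the `W` convention of [stats::wilcox.test()]; the
#' p-value does not depend on this orientation). For small samples
#' (`n_a + n_b <= 16`) the p-value is exact, computed by full enumeration of
#' all rank assignments of the combined sample (ties handled by midranks,
#' whose null distribution remains symmetric about `n_a * n_b / 2`).
#' Otherwise the tie-corrected normal approximation with continuity
#' correction is used (via [stats::wilcox.test()]).
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @return An object of class `group_comparison` with fields `n_a`, `n_b`,
#'   `mean_a`, `mean_b`, `u_statistic`, `p_value`, `method`
#'   (`"exact"` or `"normal_tie_corrected"`) and `alternative`
#'   (`"two_sided"`).
#' @examples
#' mww_test(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact two-sided p = 0.1
#' @export
mww_test <- function(sample_a, sample_b) {
  a <- as.numeric(sample_a); b <- as.numeric(sample_b)
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("samples must not contain NA")
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  comb <- c(a, b)
  m <- rank(comb)  # midranks
  ## U = #(a > b) + 0.5 #(a == b) = R_a - n_a (n_a + 1) / 2
  ## (the convention of stats::wilcox.test's W statistic)
  u <- sum(m[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  mu <- n_a * n_b / 2

  if (n <= 16L) {
    method <- "exact"
    splits <- utils::combn(n, n_a)
    u_all <- colSums(matrix(m[splits], nrow = n_a)) - n_a * (n_a + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-9)
  } else {
    method <- "normal_tie_corrected"
    if (max(comb) == min(comb)) {
      p <- 1
    } else {
      p <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    }
  }
  structure(list(n_a = n_a, n_b = n_b, mean_a = mean(a), mean_b = mean(b),
                 u_statistic = u, p_value = p, method = method,
                 alternative = "two_sided"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Mann-Whitney-Wilcoxon (", x$method, ", two-sided): U = ",
      x$u_statistic, ", p = ", signif(x$p_value, 3), "\n", sep = "")
  cat("  n = ", x$n_a, " vs ", x$n_b, "; means ", signif(x$mean_a, 4),
      " vs ", signif(x$mean_b, 4), "\n", sep = "")
  invisible(x)
}

#' Percent change of a mean relative to a reference
#'
#' `100 * (mean_obs - mean_ref) / mean_ref`, signed. Display convention in
#' this field rounds to the nearest integer percent.
#'
#' @param mean_ref non-zero reference mean.
#' @param mean_obs observed mean.
#' @return Signed percent (unrounded).
#' @examples
#' round(percent_change(179, 197))  # +10 (leptotene -> zygotene regime)
#' @export
percent_change <- function(mean_ref, mean_obs) {
  if (mean_ref == 0) stop("zero reference mean")
  100 * (mean_obs - mean_ref) / mean_ref
}

#' Fold change of a mean relative to a reference
#'
#' @param mean_a positive reference mean.
#' @param mean_b observed mean.
#' @return `mean_b / mean_a`. Display convention rounds to one decimal.
#' @export
fold_change <- function(mean_a, mean_b) {
  if (mean_a <= 0) stop("non-positive reference mean")
  mean_b / mean_a
}

#' Canonical time-course stage labels
#'
#' Interphase, leptotene, zygotene/pachytene, diplotene/metaphase I and
#' metaphase II/tetrad — the stages scored in a pulse-chase labelling time
#' course.
#' @export
timecourse_stages <- c("Int", "Lep", "Zyg/Pac", "Dip/MI", "MII/Tet")

#' Earliest labelled time per stage in a pulse-chase time course
#'
#' For each stage, the earliest time point (hours) at which labelled nuclei
#' were observed, or `NA` for stages never labelled.
#'
#' @param table data frame with columns `time_h`, `stage`, `labelled_count`
#'   (and optionally `unlabelled_count`); time points must be strictly
#'   increasing within each stage series.
#' @return Named numeric vector, one element per stage (in order of first
#'   appearance in the table).
#' @export
first_labelled_times <- function(table) {
  req <- c("time_h", "stage", "labelled_count")
  if (!all(req %in% names(table))) {
    stop("time-course table must have columns: ", paste(req, collapse = ", "))
  }
  if (any(table$labelled_count < 0) ||
      ("unlabelled_count" %in% names(table) &&
       any(table$unlabelled_count < 0))) {
    stop("counts must be non-negative")
  }
  stages <- unique(as.character(table$stage))
  out <- stats::setNames(rep(NA_real_, length(stages)), stages)
  for (s in stages) {
    rows <- table[table$stage == s, , drop = FALSE]
    if (is.unsorted(rows$time_h, strictly = TRUE)) {
      stop("time points must be strictly increasing within stage '", s, "'")
    }
    lab <- rows$time_h[rows$labelled_count > 0]
    if (length(lab)) out[s] <- min(lab)
  }
  out
}

#' Pairwise group comparisons of a per-nucleus metric
#'
#' Runs [mww_test()] on one metric column of a per-nucleus results table for
#' every pair of group labels.
#'
#' @param per_nucleus data frame with a `group_label` column and the metric
#'   column.
#' @param metric metric column name (e.g. `"overlap_fraction"`,
#'   `"n_foci"`, `"on_axis_density_per_um"`).
#' @return Data frame with one row per group pair: `comparison`, `metric`,
#'   `n_a`, `n_b`, `mean_a`, `mean_b`, `u_statistic`, `p_value`, `method`.
#' @export
compare_groups <- function(per_nucleus, metric = "overlap_fraction") {
  if (!metric %in% names(per_nucleus)) {
    stop("metric column '", metric, "' not found")
  }
  groups <- unique(per_nucleus$group_label)
  if (length(groups) < 2L) {
    stop("need at least two groups to compare")
  }
  rows <- list()
  for (i in seq_len(length(groups) - 1L)) {
    for (j in (i + 1L):length(groups)) {
      va <- per_nucleus[[metric]][per_nucleus$group_label == groups[i]]
      vb <- per_nucleus[[metric]][per_nucleus$group_label == groups[j]]
      va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
      cmp <- mww_test(va, vb)
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = paste(groups[i], "vs", groups[j]), metric = metric,
        n_a = cmp$n_a, n_b = cmp$n_b, mean_a = cmp$mean_a,
        mean_b = cmp$mean_b, u_statistic = cmp$u_statistic,
        p_value = cmp$p_value, method = cmp$method,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
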