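#' Two-sample Student's t-test
#'
#' Classical pooled-variance two-sided Student's t with
#' `df = n_a + n_b - 2` (the form named in the study protocol); Welch's
#' unequal-variance variant is available via `var_equal = FALSE`. The
#' degenerate zero-variance case is defined explicitly: equal means give
#' `t = 0, p = 1`; unequal means give `t = +/-Inf, p = 0`.
#'
#' @param a,b numeric vectors, each of length >= 2, all finite.
#' @param var_equal pool the variances (classical Student) if TRUE.
#' @return An object of class `group_comparison` with fields `t_stat`,
#'   `p_value`, `df`, `n_a`, `n_b`, `group_means`.
#' @export
students_t <- function(a, b, var_equal = TRUE) {
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("values must be finite")
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 values")
  }
  if (var(a) == 0 && var(b) == 0) {
    d <- mean(a) - mean(b)
    t_stat <- if (d == 0) 0 else sign(d) * Inf
    p <- if (d == 0) 1 else 0
    df <- length(a) + length(b) - 2L
  } else {
    tt <- t.test(a, b, var.equal = var_equal)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
    df <- unname(tt$parameter)
  }
  structure(list(t_stat = t_stat, p_value = p, df = df,
                 n_a = length(a), n_b = length(b),
                 group_means = c(a = mean(a), b = mean(b)),
                 var_equal = var_equal),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> t = %.4f, df = %.4g, p = %.4g (n = %d vs %d)\n",
              x$t_stat, x$df, x$p_value, x$n_a, x$n_b))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Builds the ROC curve over all distinct score thresholds (descending;
#' higher score = more positive) and integrates the AUC by the trapezoidal
#' rule. Tied scores enter the curve as a single threshold, which makes the
#' trapezoidal AUC equal the Mann-Whitney statistic (each positive/negative
#' pair scores 1 for a win, 0.5 for a tie) divided by `n_pos * n_neg`.
#'
#' @param scores numeric scores.
#' @param labels class labels; `positive` marks the positive class.
#' @param positive the positive label (default `1`; use `"cscc"` for section
#'   tables).
#' @return An object of class `roc_result` with fields `thresholds` (leading
#'   `Inf` for the empty-mask end), `tpr`, `fpr`, `auc`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc # 0.75
roc_auc <- function(scores, labels, positive = 1) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  y <- as.integer(labels == positive)
  n_pos <- sum(y); n_neg <- sum(1L - y)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; yy <- y[o]
  grp <- cumsum(!duplicated(s))
  tp <- tapply(yy, grp, sum)
  fp <- tapply(1L - yy, grp, sum)
  tpr <- c(0, cumsum(tp) / n_pos)
  fpr <- c(0, cumsum(fp) / n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1L) + tail(tpr, -1L)) / 2)
  structure(list(thresholds = c(Inf, unique(s)),
                 tpr = unname(tpr), fpr = unname(fpr), auc = auc,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d positives, %d negatives, %d thresholds)\n",
              x$auc, x$n_pos, x$n_neg, length(x$thresholds)))
  invisible(x)
}

#' Compare normal and carcinoma sections on mean, max and min ratios
#'
#' For each of the per-section summary statistics (mean, max, min of the
#' selected windows' nucleocytoplasmic ratios) runs the two-group Student's
#' t-test and the ROC analysis with carcinoma as the positive class.
#'
#' @param summaries section table from [summaries_table()] (columns `label`,
#'   `mean_pct`, `max_pct`, `min_pct`), or a list of `section_summary`
#'   objects.
#' @param positive positive-class label.
#' @param var_equal forwarded to [students_t()].
#' @return An object of class `cohort_evaluation`: `table` (one row per
#'   statistic with t, p, AUC and group means), `t_tests` and `roc` (named
#'   lists of the underlying objects).
#' @export
evaluate_cohort <- function(summaries, positive = "cscc", var_equal = TRUE) {
  if (!is.data.frame(summaries)) summaries <- summaries_table(summaries)
  if (any(!summaries$label %in% c("normal", "cscc"))) {
    stop("unlabeled sections present")
  }
  if (min(table(summaries$label)) < 2L) {
    stop("need at least 2 sections per label")
  }
  stats_names <- c("mean", "max", "min")
  t_tests <- list(); rocs <- list(); rows <- list()
  for (st in stats_names) {
    v <- summaries[[paste0(st, "_pct")]]
    a <- v[summaries$label == "normal"]
    b <- v[summaries$label == positive]
    tt <- students_t(a, b, var_equal = var_equal)
    rc <- roc_auc(v, summaries$label, positive = positive)
    t_tests[[st]] <- tt; rocs[[st]] <- rc
    rows[[st]] <- data.frame(statistic = st, t_stat = tt$t_stat,
                             p_value = tt$p_value, auc = rc$auc,
                             mean_normal = mean(a), mean_cscc = mean(b),
                             stringsAsFactors = FALSE)
  }
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 t_tests = t_tests, roc = rocs,
                 n_normal = sum(summaries$label == "normal"),
                 n_cscc = sum(summaries$label == positive)),
            class = "cohort_evaluation")
}

#' @export
print.cohort_evaluation <- function(x, ...) {
  cat(sprintf("<cohort_evaluation> %d normal vs %d cSCC sections\n",
              x$n_normal, x$n_cscc))
  print(x$table, row.names = FALSE)
  invisible(x)
}
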