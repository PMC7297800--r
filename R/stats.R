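#' Per-ROI mean values of one subject
#'
#' Arithmetic mean of each variable (modality map or feature map) over each
#' region of the ROI set: CE lesion, progression ROI, the NP-5..NP-20
#' non-progression bands and the NAWM control. Empty ROIs are omitted with
#' a warning.
#'
#' @param volumes Named list of 3D arrays (or a single array wrapped in a
#'   named list).
#' @param rs An [roi_set()] object on the same grid.
#' @param subject_id Optional scalar for the `subject` column.
#' @return Data frame with columns `subject` (if given), `roi`, `variable`,
#'   `mean`, one row per (ROI, variable).
#' @export
roi_means <- function(volumes, rs, subject_id = NULL) {
  stopifnot(inherits(rs, "roi_set"), is.list(volumes),
            !is.null(names(volumes)))
  rois <- c(list(CE = rs$ce, progression = rs$progression),
            stats::setNames(rs$shells, paste0("NP-", names(rs$shells))),
            list(NAWM = rs$nawm))
  rows <- list()
  for (rn in names(rois)) {
    idx <- which(rois[[rn]])
    if (length(idx) == 0) {
      warning(sprintf("ROI '%s' is empty; omitted", rn))
      next
    }
    for (vn in names(volumes)) {
      check_same_dim(volumes[[vn]], rois[[rn]])
      rows[[length(rows) + 1L]] <-
        data.frame(roi = rn, variable = vn, mean = mean(volumes[[vn]][idx]))
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(subject_id)) out <- cbind(subject = subject_id, out)
  rownames(out) <- NULL
  out
}

#' Classical paired t-test
#'
#' Two-sided paired Student t-test on per-subject differences, as used for
#' the progression vs non-progression group comparisons. Zero-variance
#' differences are flagged: all-zero differences give t = 0, p = 1; a
#' non-zero constant difference gives an infinite t and p = 0.
#'
#' @param x,y Paired numeric vectors (same subjects, two conditions).
#' @return Object of class `paired_ttest`: list with `t`, `p`, `df`, `n`,
#'   `mean_diff`, `degenerate`.
#' @examples
#' paired_ttest(c(2, 3, 4, 5), c(1, 1, 1, 1))
#' @export
paired_ttest <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2,
            all(is.finite(x)), all(is.finite(y)))
  d <- x - y
  n <- length(d)
  if (sd(d) == 0) {
    out <- list(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                p = if (mean(d) == 0) 1 else 0,
                df = n - 1, n = n, mean_diff = mean(d), degenerate = TRUE)
  } else {
    tt <- stats::t.test(x, y, paired = TRUE)
    out <- list(t = unname(tt$statistic), p = tt$p.value,
                df = unname(tt$parameter), n = n, mean_diff = mean(d),
                degenerate = FALSE)
  }
  structure(out, class = "paired_ttest")
}

#' @export
print.paired_ttest <- function(x, ...) {
  cat(sprintf("paired t = %.3f, df = %d, two-sided p = %.4g, mean difference %.4g%s\n",
              x$t, x$df, x$p, x$mean_diff,
              if (x$degenerate) " (zero-variance differences)" else ""))
  invisible(x)
}

#' Per-subject feature means in progression vs pooled non-progression tissue
#'
#' Extracts the labelled peritumoral feature table of a subject and
#' averages every registry feature over the progression ROI and over the
#' pooled non-progression bands.
#'
#' @inheritParams subject_feature_table
#' @return Data frame: `subject`, `feature`, `progression_mean`,
#'   `nonprogression_mean` (294 rows).
#' @export
subject_feature_summary <- function(subject, window = 5, n_levels = 32,
                                    distances_mm = c(5, 10, 15, 20),
                                    max_voxels = NULL, seed = 1) {
  tab <- subject_feature_table(subject, window, n_levels, distances_mm,
                               max_voxels, seed)
  if (length(unique(tab$label)) < 2)
    stop("subject lacks voxels in one of the two groups")
  f <- feature_matrix(tab)
  data.frame(subject = subject$subject_index,
             feature = colnames(f),
             progression_mean = colMeans(f[tab$label == 1, , drop = FALSE]),
             nonprogression_mean = colMeans(f[tab$label == 0, , drop = FALSE]),
             row.names = NULL)
}

#' Cohort-level feature summaries
#' @param cohort A `phantom_cohort`.
#' @inheritParams subject_feature_summary
#' @return Stacked [subject_feature_summary()] rows for all subjects.
#' @export
cohort_feature_summary <- function(cohort, window = 5, n_levels = 32,
                                   distances_mm = c(5, 10, 15, 20),
                                   max_voxels = NULL, seed = 1) {
  do.call(rbind, lapply(cohort, subject_feature_summary, window = window,
                        n_levels = n_levels, distances_mm = distances_mm,
                        max_voxels = max_voxels, seed = seed))
}

#' Significant-feature screen across the registry
#'
#' For each of the 294 features, a two-sided paired t-test across subjects
#' of the progression-ROI mean against the pooled non-progression mean.
#' Raw p-values are used by default (no multiplicity correction);
#' Benjamini-Hochberg is available via `adjust = "BH"`.
#'
#' @param summaries Stacked per-subject summaries from
#'   [cohort_feature_summary()] (columns `subject`, `feature`,
#'   `progression_mean`, `nonprogression_mean`).
#' @param alpha Significance level, default 0.05.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Object of class `feature_screen`: list with `results` (per
#'   feature: `t`, `p`, `p_adj`, `significant`, family and modality from
#'   the registry), `counts` (significant / total per family), `alpha`,
#'   `adjust`, `n_subjects`.
#' @export
feature_screen <- function(summaries, alpha = 0.05,
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(all(c("subject", "feature", "progression_mean",
                  "nonprogression_mean") %in% names(summaries)),
            alpha >= 0, alpha <= 1)
  n_sub <- length(unique(summaries$subject))
  if (n_sub < 2) stop("at least 2 subjects are required")
  reg <- feature_registry()
  res <- lapply(split(summaries, summaries$feature), function(s) {
    tt <- paired_ttest(s$progression_mean, s$nonprogression_mean)
    data.frame(feature = s$feature[1], t = tt$t, p = tt$p, n = tt$n,
               degenerate = tt$degenerate)
  })
  res <- do.call(rbind, res)
  res <- res[match(reg$name, res$feature), ]   # registry order
  res$p_adj <- if (adjust == "BH") stats::p.adjust(res$p, "BH") else res$p
  res$significant <- res$p_adj < alpha
  res$family <- ifelse(reg$family == "first_order", "first_order",
                       "second_order")
  res$modality <- reg$modality
  rownames(res) <- NULL
  counts <- vapply(split(res, res$family),
                   function(g) c(significant = sum(g$significant),
                                 total = nrow(g)),
                   integer(2))
  structure(list(results = res, counts = counts, alpha = alpha,
                 adjust = adjust, n_subjects = n_sub),
            class = "feature_screen")
}

#' @export
print.feature_screen <- function(x, ...) {
  cat(sprintf("Feature screen: paired t-tests over %d subjects, alpha = %g (%s)\n",
              x$n_subjects, x$alpha,
              if (x$adjust == "none") "raw p-values" else "BH-adjusted"))
  for (fam in colnames(x$counts))
    cat(sprintf("  %s: %d of %d significant\n", fam,
                x$counts["significant", fam], x$counts["total", fam]))
  cat(sprintf("  total: %d of %d\n", sum(x$counts["significant", ]),
              sum(x$counts["total", ])))
  invisible(x)
}
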