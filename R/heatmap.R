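#' Progression probability heat map over the peritumoral mask
#'
#' Extracts the 294-feature vector at every voxel of `mask`, evaluates the
#' trained classifier there and writes the probabilities into a 3D map
#' (0 outside the mask).
#'
#' @param model A fitted [progression_net()].
#' @param volumes Named list of the seven modality arrays.
#' @param mask Binary peritumoral mask (non-empty).
#' @param window,n_levels Feature-extraction settings; must match those the
#'   model was trained with.
#' @param threshold Binarization threshold stored with the map.
#' @return A `probability_map`: numeric 3D array in \[0, 1\] with attributes
#'   `mask` and `threshold`.
#' @export
probability_heatmap <- function(model, volumes, mask, window = 5,
                                n_levels = 32, threshold = 0.5) {
  stopifnot(inherits(model, "progression_net"))
  mask <- as_mask(mask)
  tab <- voxelwise_feature_table(volumes, mask, window, n_levels)
  p <- predict(model, feature_matrix(tab))
  map <- array(0, dim = dim(mask))
  map[which(mask)] <- p
  structure(map, mask = mask, threshold = threshold,
            class = c("probability_map", "array"))
}

#' @export
print.probability_map <- function(x, ...) {
  msk <- attr(x, "mask")
  cat(sprintf("Progression probability map: %d mask voxels, mean p = %.3f, threshold %.2f\n",
              sum(msk), mean(x[which(msk)]), attr(x, "threshold")))
  invisible(x)
}

#' @export
plot.probability_map <- function(x, slice = NULL, ...) {
  msk <- attr(x, "mask")
  if (is.null(slice)) {  # axial slice with the most mask voxels
    counts <- apply(msk, 3, sum)
    slice <- which.max(counts)
  }
  graphics::image(x[, , slice], zlim = c(0, 1), useRaster = TRUE,
                  main = sprintf("progression probability, slice %d", slice),
                  ...)
  invisible(x)
}

#' Write a probability map as NIfTI
#' @param map A [probability_heatmap()] result.
#' @param file Output path.
#' @param spacing Voxel spacing in mm.
#' @return Invisibly, `file`.
#' @export
write_probability_map <- function(map, file, spacing = c(1, 1, 1)) {
  write_nifti_vol(unclass(map), spacing, file)
  invisible(file)
}

#' External validation with repeated re-training
#'
#' Re-trains the classifier `n_repeats` times (fresh split and weight
#' initialization per repeat) on the pooled training-cohort voxels and
#' scores each model on the pooled voxels of held-out subjects, reporting
#' per-repeat positive predictive value, negative predictive value and
#' overall accuracy plus their mean. Errors if any subject appears in both
#' cohorts.
#'
#' @param train_table,valid_table Labelled feature tables (see
#'   [cohort_feature_table()]) with `subject` and `label` columns, from
#'   disjoint subject sets.
#' @param n_repeats Number of re-trained repeats, default 3.
#' @param seed Base seed; repeat r trains with a seed derived from
#'   `(seed, r)`.
#' @param threshold Binarization threshold, default 0.5.
#' @param hidden,max_iter,patience Passed to [progression_net()].
#' @return A `validation_report`: data frame with rows `Test 1..n` and
#'   `Mean`, columns `ppv`, `npv`, `accuracy` (percent).
#' @export
external_validate <- function(train_table, valid_table, n_repeats = 3,
                              seed = 1, threshold = 0.5, hidden = 10,
                              max_iter = 300, patience = 25) {
  stopifnot(n_repeats >= 1, "label" %in% names(train_table),
            "label" %in% names(valid_table))
  if (!("subject" %in% names(train_table)) ||
      !("subject" %in% names(valid_table)))
    stop("both tables need a 'subject' column to check cohort disjointness")
  leaked <- intersect(unique(train_table$subject), unique(valid_table$subject))
  if (length(leaked) > 0)
    stop("subject leakage between training and validation cohorts: ",
         paste(leaked, collapse = ", "))
  xtr <- feature_matrix(train_table)
  xva <- feature_matrix(valid_table)
  rows <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    fit <- progression_net(xtr, train_table$label, hidden = hidden,
                           seed = derive_seed(seed, r), max_iter = max_iter,
                           patience = patience)
    cm <- confusion_metrics(predict(fit, xva), valid_table$label, threshold)
    rows[[r]] <- data.frame(repeat_ = sprintf("Test %d", r),
                            ppv = cm$metrics["ppv"], npv = cm$metrics["npv"],
                            accuracy = cm$metrics["accuracy"])
  }
  rep_df <- do.call(rbind, rows)
  agg <- data.frame(repeat_ = "Mean", ppv = mean(rep_df$ppv),
                    npv = mean(rep_df$npv), accuracy = mean(rep_df$accuracy))
  out <- rbind(rep_df, agg)
  rownames(out) <- NULL
  names(out)[1] <- "repeat"
  class(out) <- c("validation_report", "data.frame")
  attr(out, "n_repeats") <- n_repeats
  attr(out, "threshold") <- threshold
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat("External validation (re-trained per repeat)\n")
  cat(sprintf("  %-8s %8s %8s %10s\n", "", "PPV (%)", "NPV (%)", "Acc. (%)"))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-8s %8.1f %8.1f %10.1f\n", x[["repeat"]][i], x$ppv[i],
                x$npv[i], x$accuracy[i]))
  invisible(x)
}
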