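#' Random 70/15/15 split of table rows
#'
#' Partitions `1:n` into disjoint, exhaustive train/validation/test index
#' sets. Validation and test sizes are `round(n * fraction)`; the remainder
#' goes to training. Deterministic given `seed`.
#'
#' @param n Number of rows (>= 3).
#' @param fractions Positive fractions summing to 1, default
#'   `c(train = 0.70, validation = 0.15, test = 0.15)`.
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#' @return List of integer index vectors `train`, `validation`, `test`.
#' @examples
#' lengths(random_split(100, seed = 1))
#' @export
random_split <- function(n, fractions = c(train = 0.70, validation = 0.15,
                                          test = 0.15), seed = NULL) {
  stopifnot(n >= 3, length(fractions) == 3, all(fractions > 0))
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  perm <- if (is.null(seed)) sample.int(n) else with_seed(seed, sample.int(n))
  n_val <- round(n * fractions[2])
  n_test <- round(n * fractions[3])
  n_train <- n - n_val - n_test
  if (n_train < 1) stop("training partition is empty")
  list(train = sort(perm[seq_len(n_train)]),
       validation = sort(perm[n_train + seq_len(n_val)]),
       test = sort(perm[n_train + n_val + seq_len(n_test)]))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# forward pass; returns list(p, a1)
net_forward <- function(X, wts) {
  a1 <- tanh(sweep(X %*% t(wts$W1), 2, wts$b1, `+`))
  p <- sigmoid(drop(a1 %*% t(wts$W2)) + wts$b2)
  list(p = p, a1 = a1)
}

pack_weights <- function(wts) c(wts$W1, wts$b1, wts$W2, wts$b2)

unpack_weights <- function(par, d, h) {
  W1 <- matrix(par[seq_len(h * d)], h, d)
  b1 <- par[h * d + seq_len(h)]
  W2 <- matrix(par[h * d + h + seq_len(h)], 1, h)
  b2 <- par[h * d + 2 * h + 1]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

# mean binary cross-entropy, clamped away from log(0)
cross_entropy <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Voxel-wise progression classifier (feed-forward network, SCG)
#'
#' Fits a fully connected network with one hidden layer of `hidden` tanh
#' units and a sigmoid output to binary voxel labels, minimizing mean
#' binary cross-entropy with Moller's scaled conjugate gradient (conjugate
#' directions with an adaptively damped curvature estimate; no line
#' search). Rows are split 70/15/15 into training, validation and test
#' partitions; features are z-scored by training-partition statistics;
#' training stops when the validation cross-entropy has not improved for
#' `patience` consecutive accepted steps (the best-validation weights are
#' kept), on a vanishing gradient, or at `max_iter`.
#'
#' @param x Numeric feature matrix (rows = voxels), or a formula.
#' @param y Binary labels (0/1, logical, or 2-level factor); 1 = progression.
#' @param hidden Hidden-layer width, default 10.
#' @param split Train/validation/test fractions, default 0.70/0.15/0.15.
#' @param seed Seed governing split, weight initialization and any
#'   downstream simulation; the fit is bit-reproducible given it.
#' @param max_iter Maximum SCG iterations, default 300.
#' @param patience Validation patience (accepted steps), default 25.
#' @param standardize Z-score features by training statistics, default TRUE.
#' @param ... Unused; for method dispatch.
#' @return An object of class `progression_net`: weights, scaling, split
#'   indices, training trace (`iter`, `train_ce`, `val_ce`), stop reason
#'   and fitted probabilities. Methods: `print`, `summary`, `coef`,
#'   `predict`, `plot`, `residuals`, `simulate`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(400), 200, 2)
#' y <- as.integer(x[, 1] + x[, 2] > 0)
#' fit <- progression_net(x, y, hidden = 4, seed = 1, max_iter = 100)
#' summary(fit)
#' @export
progression_net <- function(x, ...) UseMethod("progression_net")

#' @rdname progression_net
#' @param formula Model formula, e.g. `label ~ .`.
#' @param data Data frame holding the formula's variables.
#' @export
progression_net.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- stats::model.matrix(attr(mf, "terms"), mf)
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  out <- progression_net.default(x, y, ...)
  out$call <- match.call()
  out
}

#' @rdname progression_net
#' @export
progression_net.default <- function(x, y, hidden = 10,
                                    split = c(train = 0.70, validation = 0.15,
                                              test = 0.15),
                                    seed = 1, max_iter = 300, patience = 25,
                                    standardize = TRUE, ...) {
  x <- as.matrix(x)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("labels must be binary (0/1)")
  if (nrow(x) != length(y)) stop("x and y disagree in length")
  if (!all(is.finite(x))) stop("non-finite feature values")
  d <- ncol(x); h <- as.integer(hidden)
  idx <- random_split(nrow(x), split, seed = derive_seed(seed, 1))
  if (length(unique(y[idx$train])) < 2)
    stop("training partition contains a single class")

  if (standardize) {
    centre <- colMeans(x[idx$train, , drop = FALSE])
    scale_ <- apply(x[idx$train, , drop = FALSE], 2, sd)
    scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  } else {
    centre <- rep(0, d); scale_ <- rep(1, d)
  }
  xs <- sweep(sweep(x, 2, centre), 2, scale_, `/`)
  Xtr <- xs[idx$train, , drop = FALSE]; ytr <- y[idx$train]
  Xva <- xs[idx$validation, , drop = FALSE]; yva <- y[idx$validation]

  par0 <- with_seed(derive_seed(seed, 2), {
    c(rnorm(h * d) / sqrt(d), rep(0, h), rnorm(h) / sqrt(h), 0)
  })

  fn <- function(par) {
    wts <- unpack_weights(par, d, h)
    cross_entropy(net_forward(Xtr, wts)$p, ytr)
  }
  gr <- function(par) {
    wts <- unpack_weights(par, d, h)
    fwd <- net_forward(Xtr, wts)
    dz <- (fwd$p - ytr) / length(ytr)
    dW2 <- crossprod(dz, fwd$a1)               # 1 x h
    db2 <- sum(dz)
    da1 <- tcrossprod(dz, t(wts$W2))           # n x h
    dz1 <- da1 * (1 - fwd$a1^2)
    dW1 <- crossprod(dz1, Xtr)                 # h x d
    db1 <- colSums(dz1)
    c(dW1, db1, dW2, db2)
  }

  env <- new.env()
  env$best_val <- Inf; env$best_par <- par0; env$since <- 0L
  env$trace <- list()
  monitor <- function(k, w, fval) {
    vce <- if (length(yva) > 0)
      cross_entropy(net_forward(Xva, unpack_weights(w, d, h))$p, yva)
    else NA_real_
    env$trace[[length(env$trace) + 1L]] <- c(k, fval, vce)
    if (is.na(vce) || vce < env$best_val - 1e-9) {
      if (!is.na(vce)) { env$best_val <- vce; env$best_par <- w }
      env$since <- 0L
      FALSE
    } else {
      env$since <- env$since + 1L
      env$since >= patience
    }
  }

  opt <- scg_optimize(par0, fn, gr, max_iter = max_iter, monitor = monitor)
  final_par <- if (is.finite(env$best_val)) env$best_par else opt$par
  wts <- unpack_weights(final_par, d, h)
  tr <- do.call(rbind, env$trace)
  trace <- data.frame(iter = tr[, 1], train_ce = tr[, 2], val_ce = tr[, 3])

  fitted_all <- net_forward(xs, wts)$p
  structure(list(weights = wts, hidden = h, centre = centre, scale = scale_,
                 split = idx, trace = trace, stop_reason = opt$stop_reason,
                 fitted = fitted_all, y = y,
                 feature_names = colnames(x), seed = seed,
                 call = match.call()),
            class = "progression_net")
}

#' @export
print.progression_net <- function(x, ...) {
  cat(sprintf("Feed-forward progression classifier: %d-%d-1, trained by scaled conjugate gradient\n",
              length(x$centre), x$hidden))
  cat(sprintf("  %d/%d/%d train/validation/test rows; stopped after %d iterations (%s)\n",
              length(x$split$train), length(x$split$validation),
              length(x$split$test), nrow(x$trace), x$stop_reason))
  if (nrow(x$trace) > 0)
    cat(sprintf("  cross-entropy %.4f -> %.4f (train)\n",
                x$trace$train_ce[1], x$trace$train_ce[nrow(x$trace)]))
  invisible(x)
}

#' @export
coef.progression_net <- function(object, ...) object$weights

#' @rdname progression_net
#' @param object,newdata,type,threshold Prediction arguments: feature matrix
#'   or data frame; `"response"` for probabilities, `"class"` for the
#'   thresholded 0/1 call.
#' @export
predict.progression_net <- function(object, newdata,
                                    type = c("response", "class"),
                                    threshold = 0.5, ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) {
    if (!is.null(object$feature_names) &&
        all(object$feature_names %in% names(newdata)))
      newdata <- newdata[, object$feature_names, drop = FALSE]
    newdata <- as.matrix(newdata)
  }
  if (ncol(newdata) != length(object$centre))
    stop(sprintf("model expects %d features, got %d",
                 length(object$centre), ncol(newdata)))
  xs <- sweep(sweep(newdata, 2, object$centre), 2, object$scale, `/`)
  p <- net_forward(xs, object$weights)$p
  if (type == "class") as.integer(p >= threshold) else p
}

#' @export
residuals.progression_net <- function(object, ...) object$y - object$fitted

#' @export
simulate.progression_net <- function(object, nsim = 1, seed = NULL, ...) {
  draw <- function() rbinom(length(object$fitted), 1, object$fitted)
  out <- if (is.null(seed)) replicate(nsim, draw())
         else with_seed(seed, replicate(nsim, draw()))
  as.data.frame(out)
}

#' @export
summary.progression_net <- function(object, threshold = 0.5, ...) {
  parts <- lapply(object$split, function(ii)
    confusion_metrics(object$fitted[ii], object$y[ii], threshold))
  out <- list(model = object, partitions = parts, threshold = threshold)
  class(out) <- "summary.progression_net"
  out
}

#' @export
print.summary.progression_net <- function(x, ...) {
  print(x$model)
  for (nm in names(x$partitions)) {
    m <- x$partitions[[nm]]$metrics
    cat(sprintf("  %-10s accuracy %5.1f%%  sensitivity %5.1f%%  specificity %5.1f%%  PPV %5.1f%%  NPV %5.1f%%\n",
                nm, m["accuracy"], m["sensitivity"], m["specificity"],
                m["ppv"], m["npv"]))
  }
  invisible(x)
}

#' @export
plot.progression_net <- function(x, ...) {
  if (nrow(x$trace) == 0) stop("no training trace to plot")
  ylim <- range(c(x$trace$train_ce, x$trace$val_ce), na.rm = TRUE)
  graphics::plot(x$trace$iter, x$trace$train_ce, type = "l",
                 xlab = "SCG iteration", ylab = "cross-entropy",
                 ylim = ylim, ...)
  if (!all(is.na(x$trace$val_ce)))
    graphics::lines(x$trace$iter, x$trace$val_ce, lty = 2)
  graphics::legend("topright", c("training", "validation"), lty = 1:2,
                   bty = "n")
  invisible(x)
}

#' Confusion-matrix metrics of binary predictions
#'
#' Standard 2x2-table metrics, reported in percent: sensitivity,
#' specificity, accuracy, positive and negative predictive value. Ratios
#' with a zero denominator are returned as `NA` and listed in the
#' `undefined` element.
#'
#' @param probs Predicted probabilities (or 0/1 calls).
#' @param labels True binary labels.
#' @param threshold Binarization threshold, default 0.5.
#' @return Object of class `confusion_metrics`: list with `metrics` (named
#'   percentages), `counts` (tp/fp/tn/fn), `threshold`, `undefined`.
#' @examples
#' confusion_metrics(c(.9, .2, .8, .4), c(1, 0, 1, 0))
#' @export
confusion_metrics <- function(probs, labels, threshold = 0.5) {
  stopifnot(length(probs) == length(labels), length(probs) >= 1)
  labels <- as.integer(labels != 0)
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  ratio <- function(a, b) if (b == 0) NA_real_ else 100 * a / b
  metrics <- c(sensitivity = ratio(tp, tp + fn),
               specificity = ratio(tn, tn + fp),
               accuracy = 100 * (tp + tn) / length(labels),
               ppv = ratio(tp, tp + fp),
               npv = ratio(tn, tn + fn))
  structure(list(metrics = metrics,
                 counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
                 threshold = threshold,
                 undefined = names(metrics)[is.na(metrics)]),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%, PPV %.1f%%, NPV %.1f%% (threshold %.2f)\n",
              m["accuracy"], m["sensitivity"], m["specificity"], m["ppv"],
              m["npv"], x$threshold))
  if (length(x$undefined) > 0)
    cat("  undefined (zero denominator):", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}
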