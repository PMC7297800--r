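toy_blobs <- function(n = 60, gap = 4, seed = 31) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n, -gap / 2, 0.5), n / 2, 2),
             matrix(rnorm(n, gap / 2, 0.5), n / 2, 2))
  list(x = x, y = rep(c(0, 1), each = n / 2))
}

test_that("random split honors the 70/15/15 default and is a seeded partition", {
  sp <- random_split(100, seed = 3)
  expect_equal(lengths(sp), c(train = 70L, validation = 15L, test = 15L))
  expect_equal(sort(unlist(sp)), 1:100, ignore_attr = TRUE)
  expect_identical(random_split(100, seed = 3), random_split(100, seed = 3))
  expect_false(identical(random_split(100, seed = 3), random_split(100, seed = 4)))
  expect_error(random_split(100, fractions = c(.7, .2, .2)), "sum to 1")
  expect_error(random_split(2))
})

test_that("a linearly separable toy set is fit to 100% training accuracy", {
  d <- toy_blobs()
  expect_true(perceptron_separable(d$x, d$y))  # separability oracle
  fit <- progression_net(d$x, d$y, hidden = 4, seed = 2, max_iter = 200,
                         patience = 200)
  acc <- mean((fit$fitted[fit$split$train] >= .5) == d$y[fit$split$train])
  expect_equal(acc, 1)
  expect_lte(nrow(fit$trace), 200)
})

test_that("ten hidden units solve the XOR cluster arrangement", {
  set.seed(17)
  n <- 40
  centers <- rbind(c(-2, -2), c(2, 2), c(-2, 2), c(2, -2))
  x <- do.call(rbind, lapply(1:4, function(k)
    sweep(matrix(rnorm(2 * n, 0, 0.4), n, 2), 2, centers[k, ], `+`)))
  y <- rep(c(0, 0, 1, 1), each = n)
  hits <- sapply(1:3, function(s) {
    fit <- progression_net(x, y, hidden = 10, seed = s, max_iter = 400,
                           patience = 400)
    mean((fit$fitted[fit$split$train] >= .5) == y[fit$split$train])
  })
  expect_gte(sum(hits > 0.95), 2)
})

test_that("training cross-entropy decreases from its initial value", {
  d <- toy_blobs(n = 80, gap = 2, seed = 5)
  fit <- progression_net(d$x, d$y, hidden = 3, seed = 1, max_iter = 50)
  expect_lt(fit$trace$train_ce[nrow(fit$trace)], fit$trace$train_ce[1])
})

test_that("training is bit-for-bit reproducible given the seed", {
  d <- toy_blobs(n = 50, gap = 3, seed = 9)
  f1 <- progression_net(d$x, d$y, hidden = 5, seed = 11, max_iter = 60)
  f2 <- progression_net(d$x, d$y, hidden = 5, seed = 11, max_iter = 60)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$split, f2$split)
  f3 <- progression_net(d$x, d$y, hidden = 5, seed = 12, max_iter = 60)
  expect_false(identical(f1$weights, f3$weights))
})

test_that("degenerate training inputs are rejected", {
  x <- matrix(rnorm(40), 20, 2)
  expect_error(progression_net(x, rep(1, 20), seed = 1), "single class")
  x[3, 1] <- NA
  expect_error(progression_net(x, rep(c(0, 1), 10), seed = 1), "finite")
  expect_error(progression_net(matrix(1, 5, 2), c(0, 1, 2, 0, 1)), "binary")
})

test_that("a zero-weight network outputs probability one half", {
  skel <- progression_net(matrix(rnorm(60), 30, 2), rep(c(0, 1), 15),
                          hidden = 4, seed = 1, max_iter = 5)
  skel$weights <- list(W1 = matrix(0, 4, 2), b1 = rep(0, 4),
                       W2 = matrix(0, 1, 4), b2 = 0)
  p <- predict(skel, matrix(rnorm(20), 10, 2))
  expect_equal(p, rep(0.5, 10))
})

test_that("prediction is monotone along a positive single path and batch-consistent", {
  skel <- progression_net(matrix(rnorm(60), 30, 2), rep(c(0, 1), 15),
                          hidden = 1, seed = 1, max_iter = 5,
                          standardize = FALSE)
  skel$weights <- list(W1 = matrix(c(1, 0), 1, 2), b1 = 0,
                       W2 = matrix(2, 1, 1), b2 = 0)
  skel$centre <- c(0, 0); skel$scale <- c(1, 1)
  xs <- cbind(seq(-2, 2, length.out = 9), 0)
  p <- predict(skel, xs)
  expect_true(all(diff(p) > 0))
  # batch vs single-row agreement
  single <- sapply(1:9, function(i) predict(skel, xs[i, , drop = FALSE]))
  expect_equal(p, single)
})

test_that("model methods: coef, residuals, simulate, plot, formula interface", {
  d <- toy_blobs(n = 40, gap = 3, seed = 13)
  df <- data.frame(label = d$y, f1 = d$x[, 1], f2 = d$x[, 2])
  fit <- progression_net(label ~ f1 + f2, df, hidden = 3, seed = 2,
                         max_iter = 40)
  expect_named(coef(fit), c("W1", "b1", "W2", "b2"))
  expect_equal(residuals(fit), d$y - fit$fitted)
  sim <- simulate(fit, nsim = 2, seed = 4)
  expect_equal(dim(sim), c(40L, 2L))
  expect_true(all(unlist(sim) %in% 0:1))
  expect_identical(simulate(fit, 2, seed = 4), simulate(fit, 2, seed = 4))
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
})

test_that("confusion metrics follow the 2x2 table arithmetic", {
  cm <- confusion_metrics(c(.9, .8, .2, .1), c(1, 1, 0, 0))
  expect_equal(unname(cm$metrics), rep(100, 5))

  # TP=80 FN=20 TN=880 FP=20
  probs <- c(rep(.9, 80), rep(.1, 20), rep(.1, 880), rep(.9, 20))
  labels <- c(rep(1, 100), rep(0, 900))
  cm <- confusion_metrics(probs, labels)
  expect_equal(unname(cm$metrics["sensitivity"]), 80)
  expect_equal(unname(cm$metrics["ppv"]), 80)
  expect_equal(unname(cm$metrics["accuracy"]), 96)
  expect_equal(unname(cm$metrics["specificity"]), 100 * 880 / 900)

  cm <- confusion_metrics(c(.2, .7), c(0, 0))
  expect_true(is.na(cm$metrics["sensitivity"]))
  expect_true("sensitivity" %in% cm$undefined)
})

test_that("accuracy decomposes as prevalence-weighted sensitivity and specificity", {
  set.seed(19)
  for (rep in 1:5) {
    labels <- rbinom(300, 1, 0.3)
    probs <- runif(300)
    cm <- confusion_metrics(probs, labels)
    prev <- mean(labels)
    expect_equal(cm$metrics[["accuracy"]],
                 prev * cm$metrics[["sensitivity"]] +
                   (1 - prev) * cm$metrics[["specificity"]])
  }
})

test_that("a fitted model survives the JSON round trip", {
  d <- toy_blobs(n = 40, gap = 3, seed = 21)
  fit <- progression_net(d$x, d$y, hidden = 3, seed = 5, max_iter = 40)
  f <- tempfile(fileext = ".json")
  write_progression_net(fit, f)
  back <- read_progression_net(f)
  xnew <- matrix(rnorm(20), 10, 2)
  expect_equal(predict(back, xnew), predict(fit, xnew), tolerance = 1e-12)
})
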