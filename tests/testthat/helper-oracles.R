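# Independent brute-force oracles, written in plain R with a different
# algorithmic route than the package kernels. Everything here enumerates.

# distance to the nearest mask voxel, by direct minimization over mask voxels
bf_edt <- function(mask, spacing = c(1, 1, 1)) {
  dm <- dim(mask)
  src <- which(mask, arr.ind = TRUE)
  co <- arrayInd(seq_len(prod(dm)), dm)
  best <- rep(Inf, prod(dm))
  for (i in seq_len(nrow(src))) {
    d2 <- ((co[, 1] - src[i, 1]) * spacing[1])^2 +
          ((co[, 2] - src[i, 2]) * spacing[2])^2 +
          ((co[, 3] - src[i, 3]) * spacing[3])^2
    best <- pmin(best, d2)
  }
  array(sqrt(best), dm)
}

# 6-neighbourhood binary dilation
dilate6 <- function(mask) {
  dm <- dim(mask)
  out <- mask
  for (ax in 1:3) for (by in c(-1, 1)) {
    n <- dm[ax]
    to <- rep(list(quote(expr = )), 3)
    from <- rep(list(quote(expr = )), 3)
    if (by == 1) { to[[ax]] <- 2:n; from[[ax]] <- 1:(n - 1) }
    else { to[[ax]] <- 1:(n - 1); from[[ax]] <- 2:n }
    sh <- array(FALSE, dm)
    sh <- do.call(`[<-`, c(list(sh), to,
                           list(do.call(`[`, c(list(mask), from)))))
    out <- out | sh
  }
  out
}

# left-closed equal-width binning over [min, max]
bf_quantize <- function(x, n_levels) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo || n_levels == 1) return(array(1L, dim = dim(x) %||% length(x)))
  lev <- cut(as.vector(x), breaks = seq(lo, hi, length.out = n_levels + 1),
             right = FALSE, include.lowest = FALSE, labels = FALSE)
  lev[is.na(lev)] <- n_levels  # x == hi falls past the last left-closed bin
  array(as.integer(lev), dim = dim(x) %||% length(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

bf_first_order <- function(x, n_levels = 32) {
  x <- as.vector(x)
  n <- length(x)
  q <- as.vector(bf_quantize(x, n_levels))
  m <- sum(x) / n
  mom <- function(k) sum((x - m)^k) / n
  h <- tabulate(q, n_levels) / n
  ent <- -sum(ifelse(h > 0, h * log2(h), 0))
  c(mean = m,
    sd = sqrt(mom(2)),
    median = median(x),
    min = min(x),
    max = max(x),
    variance = mom(2),
    skewness = if (mom(2) > 0) mom(3) / mom(2)^1.5 else 0,
    kurtosis = if (mom(2) > 0) mom(4) / mom(2)^2 else 0,
    energy = sum(x^2),
    entropy = ent,
    uniformity = sum(h^2),
    rms = sqrt(sum(x^2) / n),
    mean_gray_level = mean(q))
}

# pair enumeration over every voxel and offset
bf_glcm <- function(q, n_levels, offsets) {
  dm <- dim(q)
  P <- matrix(0, n_levels, n_levels)
  for (o in seq_len(nrow(offsets))) {
    off <- offsets[o, ]
    for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
      i2 <- i + off[1]; j2 <- j + off[2]; k2 <- k + off[3]
      if (i2 >= 1 && i2 <= dm[1] && j2 >= 1 && j2 <= dm[2] &&
          k2 >= 1 && k2 <= dm[3]) {
        a <- q[i, j, k]; b <- q[i2, j2, k2]
        P[a, b] <- P[a, b] + 1
        P[b, a] <- P[b, a] + 1
      }
    }
  }
  if (sum(P) > 0) P <- P / sum(P)
  P
}

# literal term-by-term transcription of each co-occurrence statistic
bf_glcm_features <- function(P) {
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  l2 <- function(p) ifelse(p > 0, log2(p), 0)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum((1:ng) * px); muy <- sum((1:ng) * py)
  sx <- sqrt(sum(((1:ng) - mux)^2 * px)); sy <- sqrt(sum(((1:ng) - muy)^2 * py))
  pxy <- sapply(2:(2 * ng), function(k) sum(P[(i + j) == k]))
  pxd <- sapply(0:(ng - 1), function(k) sum(P[abs(i - j) == k]))
  sum_avg <- sum((2:(2 * ng)) * pxy)
  hxy <- -sum(P * l2(P))
  hx <- -sum(px * l2(px)); hy <- -sum(py * l2(py))
  PPxy <- outer(px, py)
  hxy1 <- -sum(P[PPxy > 0] * log2(PPxy[PPxy > 0]))
  hxy2 <- -sum(PPxy[PPxy > 0] * log2(PPxy[PPxy > 0]))
  dmu <- sum((0:(ng - 1)) * pxd)
  c(autocorrelation = sum(i * j * P),
    contrast = sum((i - j)^2 * P),
    correlation_m = if (sx > 0 && sy > 0)
      sum((i - mux) * (j - muy) * P) / (sx * sy) else 0,
    correlation_p = if (sx > 0 && sy > 0)
      (sum(i * j * P) - mux * muy) / (sx * sy) else 0,
    cluster_prominence = sum((i + j - mux - muy)^4 * P),
    cluster_shade = sum((i + j - mux - muy)^3 * P),
    dissimilarity = sum(abs(i - j) * P),
    energy = sum(P^2),
    entropy = hxy,
    homogeneity_m = sum(P / (1 + abs(i - j))),
    homogeneity_p = sum(P / (1 + (i - j)^2)),
    sum_of_squares = sum((i - mux)^2 * P),
    sum_average = sum_avg,
    sum_variance = sum(((2:(2 * ng)) - sum_avg)^2 * pxy),
    sum_entropy = -sum(pxy * l2(pxy)),
    difference_variance = sum(((0:(ng - 1)) - dmu)^2 * pxd),
    difference_entropy = -sum(pxd * l2(pxd)),
    imc1 = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0,
    imc2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))),
    idn = sum(P / (1 + abs(i - j) / ng)),
    maximum_probability = max(P))
}

# run enumeration via line extraction and rle()
bf_glrlm <- function(q, n_levels, directions) {
  dm <- dim(q)
  lmax <- max(dm)
  R <- matrix(0, n_levels, lmax)
  co <- arrayInd(seq_len(prod(dm)), dm)
  for (d in seq_len(nrow(directions))) {
    dir <- directions[d, ]
    prev <- sweep(co, 2, dir)
    starts <- which(prev[, 1] < 1 | prev[, 1] > dm[1] |
                    prev[, 2] < 1 | prev[, 2] > dm[2] |
                    prev[, 3] < 1 | prev[, 3] > dm[3])
    for (s in starts) {
      pos <- co[s, ]
      vals <- c()
      while (all(pos >= 1) && all(pos <= dm)) {
        vals <- c(vals, q[pos[1], pos[2], pos[3]])
        pos <- pos + dir
      }
      r <- rle(vals)
      for (t in seq_along(r$lengths))
        R[r$values[t], r$lengths[t]] <- R[r$values[t], r$lengths[t]] + 1
    }
  }
  R
}

bf_glrlm_features <- function(R, n_voxels, n_dir) {
  ng <- nrow(R); lmax <- ncol(R)
  g <- row(R); l <- col(R)
  nr <- sum(R)
  c(sre = sum(R / l^2) / nr,
    lre = sum(R * l^2) / nr,
    gln = sum(rowSums(R)^2) / nr,
    run_percentage = nr / (n_voxels * n_dir),
    rln = sum(colSums(R)^2) / nr,
    lgle = sum(R / g^2) / nr,
    hgle = sum(R * g^2) / nr,
    rlnn = sum(colSums(R)^2) / nr^2)
}

# clipped cubic patch around a (1-based) voxel
bf_patch <- function(vol, at, window) {
  dm <- dim(vol)
  h <- window %/% 2
  rng <- lapply(1:3, function(a) max(1, at[a] - h):min(dm[a], at[a] + h))
  vol[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
}

# perceptron oracle: returns TRUE if the labelled set is linearly separable
perceptron_separable <- function(x, y, max_epochs = 1000) {
  x <- cbind(1, x)
  w <- rep(0, ncol(x))
  yy <- ifelse(y > 0, 1, -1)
  for (e in seq_len(max_epochs)) {
    wrong <- which(yy * drop(x %*% w) <= 0)
    if (length(wrong) == 0) return(TRUE)
    i <- wrong[1]
    w <- w + yy[i] * x[i, ]
  }
  FALSE
}
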