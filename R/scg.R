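# Scaled conjugate gradient minimizer (Moller 1993): conjugate directions
# with a scalar Hessian-damping term lambda adapted by the comparison ratio
# Delta; no line search. fn/gr take the parameter vector; `monitor`, if
# given, is called after every accepted step as monitor(iter, w, fval) and
# may return TRUE to stop early (used for validation-based early stopping).
scg_optimize <- function(par, fn, gr, max_iter = 300, tol = 1e-8,
                         sigma0 = 5e-5, lambda0 = 5e-7, monitor = NULL) {
  w <- par
  fw <- fn(w)
  r <- -gr(w)
  p <- r
  success <- TRUE
  lambda <- lambda0
  lambda_bar <- 0
  nparam <- length(w)
  trace <- numeric(0)
  reason <- "max_iter"
  delta <- 0

  for (k in seq_len(max_iter)) {
    p2 <- sum(p * p)
    if (p2 == 0) { reason <- "gradient"; break }
    if (success) {
      sigma <- sigma0 / sqrt(p2)
      s <- (gr(w + sigma * p) - (-r)) / sigma
      delta <- sum(p * s)
    }
    delta <- delta + (lambda - lambda_bar) * p2
    if (delta <= 0) {                    # make the Hessian approx. definite
      lambda_bar <- 2 * (lambda - delta / p2)
      delta <- -delta + lambda * p2
      lambda <- lambda_bar
    }
    mu <- sum(p * r)
    alpha <- mu / delta
    w_try <- w + alpha * p
    f_try <- fn(w_try)
    Delta <- 2 * delta * (fw - f_try) / mu^2   # comparison ratio

    if (Delta >= 0) {                    # successful step
      w <- w_try
      fw <- f_try
      r_new <- -gr(w)
      lambda_bar <- 0
      success <- TRUE
      if (k %% nparam == 0) {
        p <- r_new                       # restart with steepest descent
      } else {
        beta <- (sum(r_new * r_new) - sum(r_new * r)) / mu
        p <- r_new + beta * p
      }
      r <- r_new
      if (Delta >= 0.75) lambda <- lambda / 4
      trace <- c(trace, fw)
      if (!is.null(monitor) && isTRUE(monitor(k, w, fw))) {
        reason <- "early_stopping"
        break
      }
      if (sqrt(sum(r * r)) < tol) { reason <- "gradient"; break }
    } else {                             # reject, increase damping
      lambda_bar <- lambda
      success <- FALSE
    }
    if (Delta < 0.25) lambda <- lambda + delta * (1 - Delta) / p2
    if (!is.finite(lambda)) { reason <- "stalled"; break }
    if (lambda > 1e30) { reason <- "stalled"; break }
  }
  list(par = w, value = fw, trace = trace, stop_reason = reason,
       iterations = length(trace))
}
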