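# Shared fixtures and independent oracles for the test suite. Everything
# here stays deliberately naive (scalar loops, finite differences) so it
# cannot share a bug with the vectorized implementation.

make_toy_stack <- function(n = 4, k = 2, m = 3, p = 1, seed = 1,
                           labels = NULL) {
  set.seed(seed)
  x <- array(rnorm(n * k * m * p), c(n, k, m, p))
  if (is.null(labels)) labels <- rep_len(c(0L, 1L), n)
  omics_stack(x, labels)
}

make_toy_params <- function(k = 2, m = 3, p = 1, seed = 2) {
  set.seed(seed)
  network_params(v = array(rnorm(k * m * p), c(k, m, p)),
                 w = matrix(rnorm(k * m, mean = 1), k, m),
                 beta0 = rnorm(1), beta = rnorm(k))
}

# scalar-loop feedforward: the brute-force oracle for the whole network
loop_forward <- function(stack, params) {
  d <- dim(stack$x)
  n <- d[1]; k <- d[2]; m <- d[3]; np <- d[4]
  a <- array(0, c(n, k, m)); O <- array(0, c(n, k, m))
  C <- matrix(0, n, k); yhat <- numeric(n)
  for (i in seq_len(n)) {
    for (kk in seq_len(k)) {
      nw <- sqrt(sum(params$w[kk, ]^2))
      for (mm in seq_len(m)) {
        s <- 0
        for (pp in seq_len(np))
          s <- s + params$v[kk, mm, pp] * stack$x[i, kk, mm, pp]
        a[i, kk, mm] <- s
        O[i, kk, mm] <- max(s, 0)
        C[i, kk] <- C[i, kk] + params$w[kk, mm] * O[i, kk, mm] / nw
      }
    }
    yhat[i] <- params$beta0 + sum(params$beta * C[i, ])
  }
  list(a = a, O = O, C = C, yhat = yhat, f = 1 / (1 + exp(-yhat)))
}

# scalar-loop penalized objective
loop_loss <- function(f, labels, beta, lambda) {
  s <- 0
  for (i in seq_along(f))
    s <- s - (labels[i] * log(f[i]) + (1 - labels[i]) * log(1 - f[i]))
  s / length(f) + lambda * sum(abs(beta))
}

# central finite differences of fn at x
num_grad <- function(fn, x, h = 1e-6) {
  g <- numeric(length(x))
  for (j in seq_along(x)) {
    e <- rep(0, length(x)); e[j] <- h
    g[j] <- (fn(x + e) - fn(x - e)) / (2 * h)
  }
  g
}

# full objective as a function of the parameter set; with every |beta_k|
# far from 0 relative to the step h this is differentiable along any
# direction the finite-difference probes use
objective_of <- function(stack, params, lambda) {
  penalized_loss(forward_pass(stack, params)$f, stack$labels, params, lambda)
}
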