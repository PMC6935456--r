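test_that("initialization sets unit hidden weights and the ridge closed form", {
  stack <- make_toy_stack(8, 2, 3, seed = 20)
  ctl <- idl_control(ridge_lambda = 0.5)
  p <- init_params(stack, ctl)
  expect_true(all(p$v == 1))
  expect_true(all(p$w == 1))
  # independent closed-form evaluation on the same design
  unit <- network_params(v = array(1, c(2, 3, 1)), w = matrix(1, 2, 3),
                         beta0 = 0, beta = c(0, 0))
  C <- loop_forward(stack, unit)$C
  X <- cbind(1, C)
  bhat <- solve(t(X) %*% X + 0.5 * diag(3)) %*% t(X) %*% stack$labels
  expect_equal(p$beta0, bhat[1], tolerance = 1e-10)
  expect_equal(p$beta, as.numeric(bhat[-1]), tolerance = 1e-10)
})

test_that("infinite ridge shrinkage drives the initial coefficients to zero", {
  stack <- make_toy_stack(10, 3, 2, seed = 21)
  p <- init_params(stack, idl_control(ridge_lambda = 1e12))
  expect_lt(max(abs(c(p$beta0, p$beta))), 1e-6)
})

test_that("output-coefficient gradient has the stated special cases", {
  stack <- make_toy_stack(5, 2, 2, seed = 22)
  params <- make_toy_params(2, 2, seed = 23)
  cache <- forward_pass(stack, params)
  # perfect predictions: data term vanishes, gradient equals lambda * sign
  fake <- cache
  fake$f <- as.numeric(stack$labels)
  params_pos <- params
  params_pos$beta <- abs(params$beta)
  g <- grad_beta(fake, stack$labels, params_pos, lambda = 0.7)
  expect_equal(g, rep(0.7, 2))
  # single sample, lambda 0: (f - y) * C
  one <- subset_stack(stack, 1)
  c1 <- forward_pass(one, params)
  expect_equal(grad_beta(c1, one$labels, params, 0),
               as.numeric((c1$f - one$labels) * c1$C))
})

test_that("analytic gradients match central finite differences", {
  # beta away from 0 so the L1 term is smooth along the probe
  for (seed in c(31, 32)) {
    stack <- make_toy_stack(6, 2, 3, seed = seed)
    params <- make_toy_params(2, 3, seed = seed + 50)
    params$beta <- params$beta + sign(params$beta) * 0.5
    lam <- 0.2
    cache <- forward_pass(stack, params)

    g_beta <- grad_beta(cache, stack$labels, params, lam)
    fd_beta <- num_grad(function(b) {
      p2 <- params; p2$beta <- b
      objective_of(stack, p2, lam)
    }, params$beta)
    expect_equal(g_beta, fd_beta, tolerance = 1e-5)

    fd_beta0 <- num_grad(function(b0) {
      p2 <- params; p2$beta0 <- b0
      objective_of(stack, p2, lam)
    }, params$beta0)
    expect_equal(mean(cache$f - stack$labels), fd_beta0, tolerance = 1e-5)

    g_w <- grad_w(cache, stack$labels, params)
    fd_w <- num_grad(function(wv) {
      p2 <- params; p2$w <- matrix(wv, 2, 3)
      objective_of(stack, p2, lam)
    }, as.numeric(params$w))
    expect_equal(as.numeric(g_w), fd_w, tolerance = 1e-5)

    g_v <- grad_v(cache, stack, stack$labels, params)
    fd_v <- num_grad(function(vv) {
      p2 <- params; p2$v <- array(vv, c(2, 3, 1))
      objective_of(stack, p2, lam)
    }, as.numeric(params$v))
    expect_equal(as.numeric(g_v), fd_v, tolerance = 1e-5)
  }
})

test_that("consolidation-weight gradient is orthogonal to w", {
  # degree-0 homogeneity of C in w forces sum_m w_m dC/dw_m = 0, hence the
  # objective gradient restricted to each gene is orthogonal to that w
  stack <- make_toy_stack(7, 3, 3, seed = 40)
  params <- make_toy_params(3, 3, seed = 41)
  cache <- forward_pass(stack, params)
  g <- grad_w(cache, stack$labels, params)
  expect_equal(rowSums(g * params$w), rep(0, 3), tolerance = 1e-10)
})

test_that("genes with zero output coefficient get zero w and v gradients", {
  stack <- make_toy_stack(6, 2, 2, seed = 42)
  params <- make_toy_params(2, 2, seed = 43)
  params$beta <- c(0, params$beta[2])
  cache <- forward_pass(stack, params)
  expect_equal(grad_w(cache, stack$labels, params)[1, ], c(0, 0))
  expect_equal(as.numeric(grad_v(cache, stack, stack$labels, params)[1, , ]),
               c(0, 0))
})

test_that("dead ReLU nodes and zero inputs give zero v gradient", {
  stack <- make_toy_stack(5, 1, 2, seed = 44)
  params <- make_toy_params(1, 2, seed = 45)
  # force node 1 dead for all samples
  stack$x[, 1, 1, 1] <- -abs(stack$x[, 1, 1, 1])
  params$v[1, 1, 1] <- 1
  cache <- forward_pass(stack, params)
  expect_equal(grad_v(cache, stack, stack$labels, params)[1, 1, 1], 0)
  # zero regressor
  stack$x[, 1, 2, 1] <- 0
  cache <- forward_pass(stack, params)
  expect_equal(grad_v(cache, stack, stack$labels, params)[1, 2, 1], 0)
})

test_that("Newton-style update is a fixed point at zero gradient", {
  stack <- make_toy_stack(5, 2, 2, seed = 46)
  params <- make_toy_params(2, 2, seed = 47)
  cache <- forward_pass(stack, params)
  cache$f <- as.numeric(stack$labels)        # numerator vanishes at lambda 0
  upd <- update_beta(cache, stack$labels, params, idl_control(lambda = 0))
  expect_equal(upd, params$beta)
})

test_that("Newton-style update matches a hand-computed scalar step", {
  # N = 3, K = 1: every quantity computable by hand
  x <- array(c(0.5, 1.2, -0.3), c(3, 1, 1, 1))
  stack <- omics_stack(x, c(1L, 1L, 0L))
  params <- network_params(v = array(1, c(1, 1, 1)), w = matrix(1),
                           beta0 = 0.1, beta = 0.4)
  ctl <- idl_control(lambda = 0.05)
  cache <- forward_pass(stack, params)
  C <- as.numeric(cache$C); f <- cache$f; y <- stack$labels
  num <- sum((f - y) * C) + 3 * 0.05 * 1
  den <- sum(f * (1 - f) * C^2) + 3 * 0.05 * smooth_sign(0.4, ctl$s)$dz
  expected <- 0.4 - num / den
  # verify the full step descends here, so no backtracking applies
  p2 <- params; p2$beta <- expected
  expect_lt(objective_of(stack, p2, 0.05), objective_of(stack, params, 0.05))
  expect_equal(update_beta(cache, y, params, ctl), expected,
               tolerance = 1e-12)
})

test_that("intercept update follows its gradient and freezes at eta 0", {
  stack <- make_toy_stack(6, 2, 2, seed = 48)
  params <- make_toy_params(2, 2, seed = 49)
  cache <- forward_pass(stack, params)
  perfect <- cache
  perfect$f <- as.numeric(stack$labels)
  expect_equal(update_beta0(perfect, stack$labels, params, idl_control()),
               params$beta0)
  got <- update_beta0(cache, stack$labels, params, idl_control(eta = 0.25))
  expect_equal(got,
               params$beta0 - 0.25 * mean(cache$f - stack$labels))
})

test_that("frozen hidden layers with lambda 0 reduce to logistic regression", {
  set.seed(50)
  stack <- make_toy_stack(40, 3, 2, seed = 50,
                          labels = rbinom(40, 1, 0.5))
  ctl <- idl_control(lambda = 0, freeze_wv = TRUE, epochs = 4000,
                     tol = 1e-12, ridge_lambda = 1e-8)
  fit <- fit_idl(stack, ctl)
  C <- forward_pass(stack, fit$params)$C
  ref <- stats::glm(stack$labels ~ C, family = stats::binomial())
  expect_equal(unname(fit$params$beta), unname(stats::coef(ref)[-1]),
               tolerance = 1e-3)
  expect_equal(as.numeric(predict(fit, stack)),
               unname(stats::fitted(ref)), tolerance = 1e-4)
})

test_that("training composes the four reference updates in order", {
  stack <- make_toy_stack(12, 3, 2, seed = 51,
                          labels = rep_len(c(0L, 1L), 12))
  ctl <- idl_control(lambda = 0.05, epochs = 3, tol = 0)
  start <- init_params(stack, ctl)
  fit <- fit_idl(stack, ctl, init = start)
  pr <- start
  y <- stack$labels
  for (e in 1:3) {
    ca <- forward_pass(stack, pr)
    pr$beta <- update_beta(ca, y, pr, ctl)
    ca <- forward_pass(stack, pr)
    pr$beta0 <- update_beta0(ca, y, pr, ctl)
    ca <- forward_pass(stack, pr)
    pr$w <- update_w(ca, y, pr, ctl)
    ca <- forward_pass(stack, pr)
    pr$v <- update_v(ca, stack, y, pr, ctl)
  }
  expect_equal(fit$params$beta, pr$beta, tolerance = 1e-10)
  expect_equal(fit$params$beta0, pr$beta0, tolerance = 1e-10)
  expect_equal(fit$params$w, pr$w, tolerance = 1e-10)
  expect_equal(fit$params$v, pr$v, tolerance = 1e-10)
  expect_length(fit$loss_history, fit$epoch + 1L)
})

test_that("a huge penalty drives every output coefficient below threshold", {
  stack <- generate_stack(sim_design(n_samples = 40), seed = 52)
  fit <- fit_idl(stack, idl_control(lambda = 1e3, epochs = 100))
  expect_lt(max(abs(fit$params$beta)), fit$control$select_eps)
})

test_that("training reduces cross-entropy on strongly separated toy data", {
  set.seed(53)
  n <- 30
  labels <- rep_len(c(0L, 1L), n)
  x <- array(rnorm(n * 2 * 2, sd = 0.01), c(n, 2, 2, 1))
  x[labels == 1L, 1, , 1] <- x[labels == 1L, 1, , 1] + 1
  stack <- omics_stack(x, labels)
  fit <- fit_idl(stack, idl_control(lambda = 0, eta = 0.05, epochs = 50))
  expect_lt(fit$loss_history[fit$epoch + 1L], fit$loss_history[1L])
  expect_true(all(diff(fit$loss_history) <= 1e-8))
})

test_that("training is deterministic given identical inputs", {
  stack <- generate_stack(sim_design(n_samples = 40, sigma = 0.5), seed = 54)
  f1 <- fit_idl(stack, idl_control(lambda = 0.02, epochs = 30))
  f2 <- fit_idl(stack, idl_control(lambda = 0.02, epochs = 30))
  expect_identical(f1$loss_history, f2$loss_history)
  expect_identical(f1$params$beta, f2$params$beta)
})
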