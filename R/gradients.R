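# Backpropagation updates. Each update_* takes a cache freshly computed for
# the current parameters; staleness is the caller's responsibility.

w_norms <- function(w) sqrt(rowSums(w^2))

#' Gradient of the penalized objective in the output coefficients
#'
#' Mean of the residual-weighted consolidation values plus the lasso
#' subgradient; `sign(0)` is taken as 0.
#'
#' @param cache a `forward_cache` for the current parameters.
#' @param labels binary outcomes.
#' @param params current [network_params()].
#' @param lambda lasso penalty.
#' @return Numeric vector of length K.
#' @export
grad_beta <- function(cache, labels, params, lambda = 0) {
  r <- cache$f - labels
  as.numeric(crossprod(cache$C, r)) / length(labels) +
    lambda * sign(params$beta)
}

#' Newton-style update of the output coefficients
#'
#' Each gene coefficient moves by the ratio of the penalized gradient to the
#' penalized curvature; the curvature of the L1 term comes from the smooth
#' sign approximation, so the step is defined at 0 and large there (pinning
#' small coefficients). Curvatures below `1e-10` trigger a plain gradient
#' step of size `eta` for that gene; a non-finite step leaves the
#' coefficient unchanged with a warning.
#'
#' The per-gene curvature is diagonal and ignores coupling between genes,
#' so the simultaneous full step can overshoot; a backtracking halving of a
#' common step factor accepts the largest factor (starting at 1) that does
#' not increase the penalized objective with the consolidation values held
#' fixed. The unguarded full step is used whenever it already descends.
#'
#' @inheritParams grad_beta
#' @param control an [idl_control()].
#' @return Updated coefficient vector of length K.
#' @export
update_beta <- function(cache, labels, params, control = idl_control()) {
  n <- length(labels)
  r <- cache$f - labels
  lam <- control$lambda
  num <- as.numeric(crossprod(cache$C, r)) + n * lam * sign(params$beta)
  curv <- cache$f * (1 - cache$f)
  den <- as.numeric(crossprod(cache$C^2, curv)) +
    n * lam * smooth_sign(params$beta, control$s)$dz
  step <- num / den
  flat <- den < 1e-10
  if (any(flat)) step[flat] <- control$eta * num[flat] / n
  bad <- !is.finite(step)
  if (any(bad)) {
    warning(sprintf("non-finite output-coefficient update for %d gene(s); left unchanged",
                    sum(bad)))
    step[bad] <- 0
  }
  beta_obj <- function(b) {
    f <- stats::plogis(params$beta0 + as.numeric(cache$C %*% b))
    f <- pmin(pmax(f, .prob_clip), 1 - .prob_clip)
    -mean(labels * log(f) + (1 - labels) * log(1 - f)) + lam * sum(abs(b))
  }
  base <- beta_obj(params$beta)
  t <- 1
  for (half in 1:60) {
    new <- params$beta - t * step
    if (beta_obj(new) <= base + 1e-12) return(new)
    t <- t / 2
  }
  params$beta
}

#' Gradient-descent update of the intercept
#'
#' @inheritParams update_beta
#' @return Updated scalar intercept.
#' @export
update_beta0 <- function(cache, labels, params, control = idl_control()) {
  params$beta0 - control$eta * mean(cache$f - labels)
}

#' Gradient of the objective in the consolidation weights
#'
#' Exact derivative of the norm-normalized consolidation: for gene k and
#' node m the direction combines the node's activation (scaled by 1/||w||)
#' with the projection correction (scaled by w_m/||w||^3). Setting
#' `control$exact_w_grad = FALSE` replaces the cubed norm by a squared norm
#' in the correction term.
#'
#' @inheritParams update_beta
#' @return Numeric matrix K x M.
#' @export
grad_w <- function(cache, labels, params, control = idl_control()) {
  n <- length(labels)
  r <- cache$f - labels
  w <- params$w
  k <- nrow(w); m <- ncol(w)
  nw <- w_norms(w)
  # S[i,k] = sum_s w_s O_s = C * ||w||
  rS <- as.numeric(crossprod(cache$C, r)) * nw       # sum_i r_i S_ik
  A <- matrix(0, k, m)                               # sum_i r_i O[i,k,j]
  for (j in seq_len(m)) {
    Oj <- cache$O[, , j, drop = FALSE]
    dim(Oj) <- c(n, k)
    A[, j] <- as.numeric(crossprod(Oj, r))
  }
  pow <- if (control$exact_w_grad) 3 else 2
  g <- sweep(A, 1, params$beta / nw, "*") -
    sweep(w, 1, params$beta * rS / nw^pow, "*")
  g / n
}

#' Gradient-descent update of the consolidation weights
#'
#' Steps each gene's `w` vector along the negative gradient; if a step
#' would drive a gene's norm below `1e-8` the updated vector is rescaled to
#' that floor (the consolidation divides by the norm) with a warning.
#'
#' @inheritParams update_beta
#' @return Updated K x M weight matrix.
#' @export
update_w <- function(cache, labels, params, control = idl_control()) {
  w <- params$w - control$eta * grad_w(cache, labels, params, control)
  nw <- w_norms(w)
  low <- nw < 1e-8
  if (any(low)) {
    warning(sprintf("consolidation-weight norm floored at 1e-8 for %d gene(s)",
                    sum(low)))
    for (i in which(low)) {
      w[i, ] <- if (nw[i] > 0) w[i, ] * (1e-8 / nw[i]) else params$w[i, ] *
          (1e-8 / w_norms(params$w)[i])
    }
  }
  w
}

#' Gradient of the objective in the input-to-hidden weights
#'
#' Chain rule through the ReLU: only samples with positive pre-activation
#' contribute, weighted by the residual, the gene's output coefficient and
#' its normalized consolidation weight.
#'
#' @inheritParams update_beta
#' @param stack the [omics_stack()] the cache was computed from.
#' @return Numeric array K x M x P.
#' @export
grad_v <- function(cache, stack, labels, params, control = idl_control()) {
  d <- dim(stack$x)
  n <- d[1]
  r <- cache$f - labels
  nw <- w_norms(params$w)
  coef <- sweep(params$w, 1, params$beta / nw, "*")   # beta_k * w_km / ||w_k||
  g <- array(0, d[2:4])
  for (j in seq_len(d[3])) {
    aj <- cache$a[, , j, drop = FALSE]
    dim(aj) <- c(n, d[2])
    act <- (aj > 0) * r                                # N x K
    for (p in seq_len(d[4])) {
      xjp <- stack$x[, , j, p, drop = FALSE]
      dim(xjp) <- c(n, d[2])
      g[, j, p] <- as.numeric(colSums(act * xjp)) * coef[, j] / n
    }
  }
  g
}

#' Gradient-descent update of the input-to-hidden weights
#'
#' @inheritParams grad_v
#' @return Updated K x M x P weight array.
#' @export
update_v <- function(cache, stack, labels, params, control = idl_control()) {
  params$v - control$eta * grad_v(cache, stack, labels, params, control)
}
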