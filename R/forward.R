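#' Hidden-layer activations
#'
#' Computes, for every sample, the per-(gene, node) pre-activation as the
#' weighted sum of that node's input features, and applies the ReLU
#' activation.
#'
#' @param stack an [omics_stack()].
#' @param params a [network_params()] conformant with the stack.
#' @return List with arrays `a` (pre-activations) and `O` (ReLU outputs),
#'   both N x K x M.
#' @export
forward_hidden <- function(stack, params) {
  check_conformance(stack, params)
  d <- dim(stack$x)
  a <- array(0, d[1:3])
  vmat <- params$v
  for (p in seq_len(d[4])) {
    xp <- stack$x[, , , p, drop = FALSE]
    dim(xp) <- d[1:3]
    vp <- vmat[, , p, drop = FALSE]
    dim(vp) <- d[2:3]
    a <- a + sweep(xp, c(2, 3), vp, "*", check.margin = FALSE)
  }
  list(a = a, O = pmax(a, 0))
}

#' Gene-wise consolidation of hidden activations
#'
#' Collapses each gene's hidden nodes (one per study by default) into a
#' single consolidation value, weighting node outputs by `w` and dividing
#' by the Euclidean norm of that gene's `w` vector. The normalization makes
#' the consolidation invariant to positive rescaling of `w`, so the scale
#' of gene-level evidence is carried solely by the output coefficients.
#'
#' @param O hidden activations, array N x K x M (from [forward_hidden()]).
#' @param params a [network_params()].
#' @return Numeric matrix C of consolidation values, N x K.
#' @export
consolidate <- function(O, params) {
  w <- params$w
  nw <- sqrt(rowSums(w^2))
  if (any(nw <= 0)) {
    bad <- which(nw <= 0)[1]
    stop(sprintf("consolidation weights for gene %d have zero norm", bad))
  }
  n <- dim(O)[1]; k <- dim(O)[2]; m <- dim(O)[3]
  C <- matrix(0, n, k)
  for (j in seq_len(m)) {
    Oj <- O[, , j, drop = FALSE]
    dim(Oj) <- c(n, k)
    C <- C + sweep(Oj, 2, w[, j], "*", check.margin = FALSE)
  }
  sweep(C, 2, nw, "/", check.margin = FALSE)
}

#' Output-layer prediction
#'
#' Linear combination of consolidation values plus intercept, mapped to a
#' probability through the logistic function.
#'
#' @param C consolidation matrix N x K.
#' @param params a [network_params()].
#' @return List with `yhat` (linear predictor) and `f` (probabilities).
#' @export
predict_output <- function(C, params) {
  yhat <- as.numeric(params$beta0 + C %*% params$beta)
  list(yhat = yhat, f = stats::plogis(yhat))
}

#' Full feedforward pass
#'
#' Runs hidden, consolidation and output layers, retaining every
#' intermediate needed by backpropagation.
#'
#' @inheritParams forward_hidden
#' @return A `forward_cache` list with `a`, `O`, `C`, `yhat`, `f`.
#' @export
forward_pass <- function(stack, params) {
  h <- forward_hidden(stack, params)
  C <- consolidate(h$O, params)
  out <- predict_output(C, params)
  structure(list(a = h$a, O = h$O, C = C, yhat = out$yhat, f = out$f),
            class = "forward_cache")
}

# probabilities are clipped away from {0,1} before taking logs
.prob_clip <- 1e-12

#' Lasso-penalized cross-entropy objective
#'
#' Mean binary cross-entropy of the predicted probabilities plus an L1
#' penalty on the gene-level output coefficients. The intercept is not
#' penalized. Probabilities equal to 0 or 1 are clipped to `1e-12` /
#' `1 - 1e-12` before the logarithms.
#'
#' @param f predicted probabilities, length N.
#' @param labels binary outcomes, length N.
#' @param params a [network_params()] (supplies `beta` for the penalty).
#' @param lambda nonnegative lasso penalty weight.
#' @return Scalar objective value.
#' @export
penalized_loss <- function(f, labels, params, lambda = 0) {
  stopifnot(lambda >= 0, length(f) == length(labels))
  f <- pmin(pmax(f, .prob_clip), 1 - .prob_clip)
  ce <- -mean(labels * log(f) + (1 - labels) * log(1 - f))
  ce + lambda * sum(abs(params$beta))
}

#' Smooth approximation of the sign function
#'
#' The scaled logistic `z(b) = 2 * plogis(b / s) - 1` tends to `sign(b)` as
#' `s` tends to 0; its derivative `(2/s) * plogis(b/s) * (1 - plogis(b/s))`
#' supplies the curvature of the L1 penalty used in the Newton-style update
#' of the output coefficients, which the raw sign function lacks at 0.
#'
#' @param beta numeric vector.
#' @param s positive scale; smaller values approximate the sign more
#'   sharply (default `1e-3`).
#' @return List with `z` and its derivative `dz`, both the shape of `beta`.
#' @export
smooth_sign <- function(beta, s = 1e-3) {
  stopifnot(s > 0)
  p <- stats::plogis(beta / s)
  list(z = 2 * p - 1, dz = (2 / s) * p * (1 - p))
}
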