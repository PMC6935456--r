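#' Training hyperparameters
#'
#' Collects every tunable of the optimizer in one validated list.
#'
#' @param lambda nonnegative lasso penalty on the gene-level output
#'   coefficients. 0 disables selection pressure.
#' @param eta learning rate for the gradient-descent updates of the
#'   intercept and the hidden-layer weight families.
#' @param s scale of the smooth sign approximation used for the penalty
#'   curvature in the Newton-style output update; smaller is sharper.
#' @param epochs maximum number of full-batch training sweeps.
#' @param tol stop when the absolute change in the penalized objective
#'   between consecutive epochs falls below this value.
#' @param select_eps magnitude threshold above which a fitted output
#'   coefficient declares its gene selected.
#' @param ridge_lambda ridge penalty used by the closed-form
#'   initialization of the output coefficients.
#' @param exact_w_grad if `TRUE` (default) the consolidation-weight
#'   gradient is the exact derivative of the normalized consolidation
#'   (cubed-norm second term); `FALSE` uses the squared-norm variant for
#'   comparison.
#' @param freeze_wv if `TRUE`, only the output layer (intercept and gene
#'   coefficients) is updated; the hidden and consolidation weights stay at
#'   their current values. With `lambda = 0` this reduces training to an
#'   ordinary logistic regression on the consolidation values.
#' @param verbose print one line per epoch (epoch, objective, L1 norm of
#'   beta, active-gene count).
#' @return A list of class `idl_control`.
#' @export
idl_control <- function(lambda = 0, eta = 0.3, s = 1e-3, epochs = 200,
                        tol = 1e-6, select_eps = 1e-2, ridge_lambda = 1,
                        exact_w_grad = TRUE, freeze_wv = FALSE,
                        verbose = FALSE) {
  stopifnot(lambda >= 0, eta > 0, s > 0, epochs >= 1, tol >= 0,
            select_eps > 0, ridge_lambda >= 0)
  structure(list(lambda = lambda, eta = eta, s = s,
                 epochs = as.integer(epochs), tol = tol,
                 select_eps = select_eps, ridge_lambda = ridge_lambda,
                 exact_w_grad = isTRUE(exact_w_grad),
                 freeze_wv = isTRUE(freeze_wv),
                 verbose = isTRUE(verbose)),
            class = "idl_control")
}

#' Ridge-based parameter initialization
#'
#' All hidden (`v`) and consolidation (`w`) weights start at 1. One
#' feedforward pass with those unit weights yields the consolidation matrix
#' C; the output coefficients are then the ridge solution
#' \eqn{(X^T X + \lambda I)^{-1} X^T y} on the design `[1 | C]`, which is
#' well-posed even when genes outnumber samples.
#'
#' @param stack an [omics_stack()].
#' @param control an [idl_control()]; only `ridge_lambda` is used.
#' @return A [network_params()] object.
#' @export
init_params <- function(stack, control = idl_control()) {
  d <- dim(stack$x)
  if (d[1] < 2) stop("at least two samples are required")
  if (length(unique(stack$labels)) < 2)
    stop("both outcome classes must be present")
  params <- network_params(v = array(1, d[c(2, 3, 4)]),
                           w = matrix(1, d[2], d[3]),
                           beta0 = 0, beta = rep(0, d[2]))
  C <- consolidate(forward_hidden(stack, params)$O, params)
  X <- cbind(1, C)
  bhat <- tryCatch(
    solve(crossprod(X) + control$ridge_lambda * diag(ncol(X)),
          crossprod(X, stack$labels)),
    error = function(e)
      stop("ridge system is singular; use ridge_lambda > 0 (",
           conditionMessage(e), ")"))
  params$beta0 <- bhat[1]
  params$beta <- as.numeric(bhat[-1])
  params
}
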