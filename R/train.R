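#' Fit the consolidation-layer network
#'
#' Full-batch training of the integrative model. Parameters start at the
#' ridge initialization (unit hidden/consolidation weights, closed-form
#' output coefficients) unless a warm start is supplied. Each epoch applies,
#' in order, the Newton-style update of the gene-level output coefficients,
#' then gradient-descent updates of the intercept, the consolidation
#' weights and the input-to-hidden weights — each from a freshly
#' recomputed forward pass. Training stops when the penalized objective
#' changes by less than `control$tol` between epochs, or after
#' `control$epochs` sweeps.
#'
#' @param stack an [omics_stack()] with both outcome classes present.
#' @param control an [idl_control()].
#' @param init optional [network_params()] warm start (used by the
#'   regularization path); default is [init_params()].
#' @return An object of class `idl_fit`: `params` (fitted weights),
#'   `epoch` (epochs run), `loss_history` (objective per epoch, initial
#'   value included), `converged`, and the `control` used.
#' @export
fit_idl <- function(stack, control = idl_control(), init = NULL) {
  if (is.null(init)) init <- init_params(stack, control)
  check_conformance(stack, init)
  d <- dim(stack$x)
  n <- d[1]; k <- d[2]; m <- d[3]; np <- d[4]
  km <- k * m
  Xf <- stack$x
  dim(Xf) <- c(n, km * np)
  y <- stack$labels
  lam <- control$lambda
  eta <- control$eta

  vf <- as.numeric(init$v)
  w <- init$w
  beta0 <- init$beta0
  beta <- init$beta

  # Flat-matrix feedforward, identical arithmetic to forward_pass() on the
  # (sample, gene, node, feature) array. Between the four updates of an
  # epoch only the layers downstream of the touched weights are recomputed:
  # the beta/beta0 steps leave A, O, C unchanged and the w step leaves A, O
  # unchanged, so the refreshed cache each update sees is exact.
  A <- O <- C <- nw <- yhat <- f <- NULL
  fwd_hidden <- function() {
    if (np == 1L) {
      A <<- Xf * rep(vf, each = n)
    } else {
      A <<- matrix(0, n, km)
      for (p in seq_len(np)) {
        cols <- (p - 1L) * km + seq_len(km)
        A <<- A + Xf[, cols, drop = FALSE] * rep(vf[cols], each = n)
      }
    }
    O <<- A * (A > 0)
  }
  fwd_consol <- function() {
    nw <<- sqrt(rowSums(w^2))
    Cw <- O * rep(as.numeric(w / nw), each = n)
    Ct <- Cw[, seq_len(k), drop = FALSE]
    if (m > 1) for (j in 2:m)
      Ct <- Ct + Cw[, (j - 1L) * k + seq_len(k), drop = FALSE]
    C <<- Ct
  }
  fwd_out <- function() {
    yhat <<- beta0 + as.numeric(C %*% beta)
    f <<- stats::plogis(yhat)
  }
  obj <- function(fv, b) {
    fv <- pmin(pmax(fv, .prob_clip), 1 - .prob_clip)
    -mean(y * log(fv) + (1 - y) * log(1 - fv)) + lam * sum(abs(b))
  }

  fwd_hidden(); fwd_consol(); fwd_out()
  loss <- obj(f, beta)
  loss_history <- numeric(control$epochs + 1L)
  loss_history[1L] <- loss
  converged <- FALSE
  epoch <- 0L
  while (epoch < control$epochs) {
    epoch <- epoch + 1L

    # Newton-style output update with backtracking (see update_beta)
    r <- f - y
    num <- as.numeric(crossprod(C, r)) + n * lam * sign(beta)
    den <- as.numeric(crossprod(C^2, f * (1 - f))) +
      n * lam * smooth_sign(beta, control$s)$dz
    step <- num / den
    flat <- den < 1e-10
    if (any(flat)) step[flat] <- eta * num[flat] / n
    step[!is.finite(step)] <- 0
    base <- obj(f, beta)
    t <- 1
    for (half in 1:60) {
      cand <- beta - t * step
      fc <- stats::plogis(beta0 + as.numeric(C %*% cand))
      if (obj(fc, cand) <= base + 1e-12) { beta <- cand; break }
      t <- t / 2
    }
    fwd_out()

    beta0 <- beta0 - eta * mean(f - y)
    fwd_out()

    if (!control$freeze_wv) {
      r <- f - y
      Aw <- matrix(as.numeric(crossprod(O, r)), k, m)
      rS <- as.numeric(crossprod(C, r)) * nw
      pow <- if (control$exact_w_grad) 3 else 2
      gw <- (Aw * (beta / nw) - w * (beta * rS / nw^pow)) / n
      wnew <- w - eta * gw
      nwn <- sqrt(rowSums(wnew^2))
      low <- nwn < 1e-8
      if (any(low)) {
        warning(sprintf("consolidation-weight norm floored at 1e-8 for %d gene(s)",
                        sum(low)))
        for (i in which(low))
          wnew[i, ] <- if (nwn[i] > 0) wnew[i, ] * (1e-8 / nwn[i]) else
            w[i, ] * (1e-8 / sqrt(sum(w[i, ]^2)))
      }
      w <- wnew
      fwd_consol(); fwd_out()

      r <- f - y
      act <- (A > 0) * r
      coef <- as.numeric((w / nw) * beta)          # beta_k * w_km / ||w_k||
      if (np == 1L) {
        vf <- vf - eta * (colSums(act * Xf) * coef / n)
      } else {
        for (p in seq_len(np)) {
          cols <- (p - 1L) * km + seq_len(km)
          vf[cols] <- vf[cols] -
            eta * (colSums(act * Xf[, cols, drop = FALSE]) * coef / n)
        }
      }
      fwd_hidden(); fwd_consol(); fwd_out()
    }

    new_loss <- obj(f, beta)
    if (!is.finite(new_loss))
      stop(sprintf("training diverged at epoch %d (eta = %g): objective is not finite",
                   epoch, eta))
    loss_history[epoch + 1L] <- new_loss
    if (control$verbose)
      message(sprintf("epoch %4d  R = %.6f  |beta|_1 = %.4f  active = %d",
                      epoch, new_loss, sum(abs(beta)),
                      sum(abs(beta) > control$select_eps)))
    if (abs(new_loss - loss) < control$tol) {
      converged <- TRUE
      loss <- new_loss
      break
    }
    loss <- new_loss
  }
  params <- network_params(v = array(vf, c(k, m, np)), w = w,
                           beta0 = beta0, beta = beta)
  structure(list(params = params, epoch = epoch,
                 loss_history = loss_history[seq_len(epoch + 1L)],
                 converged = converged, control = control),
            class = "idl_fit")
}

#' @export
print.idl_fit <- function(x, ...) {
  cat(sprintf("idl_fit: %d epochs (%s), lambda = %g\n", x$epoch,
              if (x$converged) "converged" else "max epochs", x$control$lambda))
  cat(sprintf("  objective: %.6f -> %.6f\n",
              x$loss_history[1], x$loss_history[length(x$loss_history)]))
  cat(sprintf("  active genes (|beta| > %g): %d of %d\n", x$control$select_eps,
              sum(abs(x$params$beta) > x$control$select_eps),
              length(x$params$beta)))
  invisible(x)
}

#' Predicted class probabilities from a fit
#'
#' @param object an `idl_fit`.
#' @param stack an [omics_stack()] of new (or the training) samples.
#' @param ... unused.
#' @return Numeric vector of probabilities of class 1.
#' @export
predict.idl_fit <- function(object, stack, ...) {
  forward_pass(stack, object$params)$f
}
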