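#' Gene-selection call from fitted output coefficients
#'
#' The optimizer smooths the L1 penalty, so fitted coefficients are never
#' exactly zero; a gene is called selected when its coefficient magnitude
#' exceeds `eps`.
#'
#' @param params a [network_params()] or an `idl_fit`.
#' @param eps selection threshold on `|beta|`.
#' @return Logical vector of length K.
#' @export
select_genes <- function(params, eps = 1e-2) {
  if (inherits(params, "idl_fit")) {
    if (missing(eps)) eps <- params$control$select_eps
    params <- params$params
  }
  abs(params$beta) > eps
}

#' Sensitivity, specificity and Youden J of a selection call
#'
#' Sensitivity is the fraction of true signal genes selected, specificity
#' the fraction of nonsignal genes left unselected, and the Youden J index
#' their sum minus one. If the truth contains only one class the undefined
#' rate (and hence the Youden index) is `NA`, or an error when
#' `strict = TRUE`.
#'
#' @param selected logical selection call per gene, or a [network_params()]
#'   / `idl_fit` to be thresholded via [select_genes()].
#' @param truth logical ground-truth signal flags per gene.
#' @param eps threshold forwarded to [select_genes()] when `selected` is
#'   not already logical.
#' @param strict error on degenerate truth instead of returning `NA`.
#' @return A list of class `selection_result` with `selected`,
#'   `sensitivity`, `specificity`, `youden`.
#' @export
call_selection <- function(selected, truth, eps = 1e-2, strict = FALSE) {
  if (!is.logical(selected)) selected <- select_genes(selected, eps)
  truth <- as.logical(truth)
  if (length(selected) != length(truth))
    stop("selection call and truth must have one entry per gene")
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (strict && (n_pos == 0 || n_neg == 0))
    stop("truth is single-class: sensitivity/specificity undefined")
  sens <- if (n_pos > 0) sum(selected & truth) / n_pos else NA_real_
  spec <- if (n_neg > 0) sum(!selected & !truth) / n_neg else NA_real_
  structure(list(selected = selected, sensitivity = sens,
                 specificity = spec, youden = sens + spec - 1),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: %d of %d genes selected\n",
              sum(x$selected), length(x$selected)))
  cat(sprintf("  sensitivity %.4f  specificity %.4f  Youden J %.4f\n",
              x$sensitivity, x$specificity, x$youden))
  invisible(x)
}

#' Regularization path of the output coefficients
#'
#' Fits the network at each penalty value of an increasing grid, warm
#' starting every fit from the previous one (the first from the ridge
#' initialization). As the penalty grows all coefficients shrink to zero.
#' A fit that diverges is recorded as a missing row with a warning.
#'
#' @param stack an [omics_stack()].
#' @param control an [idl_control()]; its `lambda` is ignored in favor of
#'   the grid.
#' @param lambdas strictly increasing nonnegative penalty grid.
#' @return An object of class `lambda_path` with `lambdas`, a
#'   `length(lambdas)` x K matrix `betas`, vector `beta0s`, and the list of
#'   fits.
#' @export
lambda_path <- function(stack, control = idl_control(),
                        lambdas = default_lambda_grid()) {
  stopifnot(length(lambdas) >= 1, all(lambdas >= 0),
            !is.unsorted(lambdas, strictly = TRUE))
  k <- dim(stack$x)[2]
  betas <- matrix(NA_real_, length(lambdas), k,
                  dimnames = list(NULL, stack$gene_ids))
  beta0s <- rep(NA_real_, length(lambdas))
  fits <- vector("list", length(lambdas))
  warm <- init_params(stack, control)
  for (i in seq_along(lambdas)) {
    ctl <- control
    ctl$lambda <- lambdas[i]
    fit <- tryCatch(fit_idl(stack, ctl, init = warm), error = function(e) {
      warning(sprintf("fit at lambda = %g failed: %s", lambdas[i],
                      conditionMessage(e)))
      NULL
    })
    if (!is.null(fit)) {
      betas[i, ] <- fit$params$beta
      beta0s[i] <- fit$params$beta0
      warm <- fit$params
      fits[[i]] <- fit
    }
  }
  structure(list(lambdas = lambdas, betas = betas, beta0s = beta0s,
                 fits = fits),
            class = "lambda_path")
}

#' Default penalty grid
#'
#' Six log-spaced values spanning weak to strong selection pressure for
#' standardized-scale expression data.
#' @return Increasing numeric vector.
#' @export
default_lambda_grid <- function() 10^seq(-2.5, -0.5, length.out = 6)

#' Cross-validated choice of the lasso penalty
#'
#' Stratified k-fold cross-validation over an increasing penalty grid:
#' within each fold the grid is fit with warm starts and scored by the
#' unpenalized cross-entropy of the held-out samples. The penalty with the
#' lowest mean held-out loss wins; ties go to the larger penalty.
#'
#' @param stack an [omics_stack()].
#' @param control an [idl_control()].
#' @param lambdas increasing penalty grid.
#' @param n_folds number of folds (default 5).
#' @param seed optional integer seed controlling fold assignment.
#' @return List of class `cv_lambda` with `lambda_opt`, `cv_scores`
#'   (mean held-out loss per grid point) and the `lambdas`.
#' @export
cv_lambda <- function(stack, control = idl_control(),
                      lambdas = default_lambda_grid(), n_folds = 5,
                      seed = NULL) {
  stopifnot(n_folds >= 2, length(lambdas) >= 1,
            !is.unsorted(lambdas, strictly = TRUE))
  if (!is.null(seed)) set.seed(seed)
  n <- dim(stack$x)[1]
  folds <- integer(n)
  for (cls in split(seq_len(n), stack$labels)) {
    if (length(cls) < n_folds)
      stop("stratification failed: a class has fewer samples than folds")
    folds[sample(cls)] <- rep_len(seq_len(n_folds), length(cls))
  }
  scores <- matrix(NA_real_, n_folds, length(lambdas))
  for (fold in seq_len(n_folds)) {
    train <- subset_stack(stack, which(folds != fold))
    held <- subset_stack(stack, which(folds == fold))
    if (length(unique(train$labels)) < 2 || length(unique(held$labels)) < 2)
      stop("stratification failed: a fold is single-class")
    warm <- init_params(train, control)
    for (i in seq_along(lambdas)) {
      ctl <- control
      ctl$lambda <- lambdas[i]
      fit <- tryCatch(fit_idl(train, ctl, init = warm),
                      error = function(e) NULL)
      if (is.null(fit)) next
      warm <- fit$params
      f_held <- forward_pass(held, fit$params)$f
      scores[fold, i] <- penalized_loss(f_held, held$labels, fit$params,
                                        lambda = 0)
    }
  }
  cv_scores <- colMeans(scores, na.rm = TRUE)
  best <- max(which(cv_scores <= min(cv_scores, na.rm = TRUE) + 1e-12))
  structure(list(lambda_opt = lambdas[best], cv_scores = cv_scores,
                 lambdas = lambdas, fold_scores = scores),
            class = "cv_lambda")
}

#' Repetition harness for the simulation study
#'
#' Repeats the full pipeline `n_reps` times: generate a synthetic
#' multi-study stack, split it into training and testing cohorts, tune the
#' lasso penalty on the training cohort by cross-validation, refit at the
#' chosen penalty, and score the gene-selection call against the
#' generator's ground truth. Reports the mean and standard error
#' (sample SD / sqrt(reps)) of sensitivity and specificity and the mean
#' Youden J index.
#'
#' @param design a [sim_design()].
#' @param control an [idl_control()].
#' @param lambdas penalty grid for the per-repetition cross-validation.
#' @param n_reps number of repetitions (default 30).
#' @param n_folds cross-validation folds (default 5).
#' @param cv_epochs epoch cap for the cross-validation fits; the fold fits
#'   only rank penalties by held-out loss, so they run shorter than the
#'   final fit (default 100).
#' @param seed integer seed for the whole experiment.
#' @return A one-row data.frame of class `idl_experiment` with columns
#'   method, sigma, n_random, sensitivity, se_sens, specificity, se_spec,
#'   youden, n_reps; per-repetition results are attached as the
#'   `"reps"` attribute.
#' @export
run_experiment <- function(design, control = idl_control(),
                           lambdas = default_lambda_grid(), n_reps = 30,
                           n_folds = 5, cv_epochs = 100, seed = 1) {
  stopifnot(n_reps >= 1)
  cv_control <- control
  cv_control$epochs <- as.integer(min(control$epochs, cv_epochs))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  sens <- spec <- youden <- rep(NA_real_, n_reps)
  failed <- 0L
  for (r in seq_len(n_reps)) {
    res <- tryCatch({
      set.seed(rep_seeds[r])
      stack <- generate_stack(design)
      sp <- split_train_test(stack, design$train_fraction)
      cv <- cv_lambda(sp$train, cv_control, lambdas, n_folds)
      ctl <- control
      ctl$lambda <- cv$lambda_opt
      fit <- fit_idl(sp$train, ctl)
      call_selection(fit, stack$signal, eps = control$select_eps)
    }, error = function(e) {
      warning(sprintf("repetition %d failed: %s", r, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) { failed <- failed + 1L; next }
    sens[r] <- res$sensitivity
    spec[r] <- res$specificity
    youden[r] <- res$youden
  }
  if (failed > n_reps / 2)
    stop(sprintf("%d of %d repetitions failed", failed, n_reps))
  ok <- !is.na(youden)
  n_ok <- sum(ok)
  se <- function(x) stats::sd(x[ok]) / sqrt(n_ok)
  out <- data.frame(method = "integrative deep learning",
                    sigma = design$sigma,
                    n_random = design$n_random_studies,
                    sensitivity = mean(sens[ok]), se_sens = se(sens),
                    specificity = mean(spec[ok]), se_spec = se(spec),
                    youden = mean(youden[ok]), n_reps = n_ok,
                    stringsAsFactors = FALSE)
  attr(out, "reps") <- data.frame(rep = seq_len(n_reps), seed = rep_seeds,
                                  sensitivity = sens, specificity = spec,
                                  youden = youden)
  class(out) <- c("idl_experiment", "data.frame")
  out
}
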