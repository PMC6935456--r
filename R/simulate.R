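#' Design of the multi-study simulation
#'
#' Parameters of the synthetic generator: each informative study draws its
#' nonsignal genes from MVN(0, sigma^2 I) for every sample and its signal
#' genes from MVN(m, sigma^2 Sigma), where the mean vector m equals `mu` on
#' every signal gene for case samples and 0 for controls, and Sigma is
#' block-exchangeable with correlation `rho` inside each signal-gene
#' cluster and independence between clusters. All-noise "random" studies
#' draw every gene from MVN(0, sigma^2 I) regardless of class.
#'
#' @param n_signal number of signal genes (default 16).
#' @param n_nonsignal number of nonsignal genes (default 64).
#' @param n_studies total number of studies (default 3).
#' @param n_random_studies how many of the studies are pure noise
#'   (0 to `n_studies - 1`).
#' @param sigma noise standard deviation.
#' @param mu mean shift of signal genes in case samples.
#' @param rho within-cluster correlation of signal genes.
#' @param n_clusters number of signal-gene clusters (default 2).
#' @param n_samples samples per study (shared cohort; default 100).
#' @param case_fraction proportion of samples labeled 1.
#' @param train_fraction proportion used for training in the split.
#' @return A validated list of class `sim_design`.
#' @export
sim_design <- function(n_signal = 16, n_nonsignal = 64, n_studies = 3,
                       n_random_studies = 0, sigma = 0.1, mu = 1,
                       rho = 0.5, n_clusters = 2, n_samples = 100,
                       case_fraction = 0.5, train_fraction = 0.7) {
  stopifnot(n_signal >= 1, n_nonsignal >= 0, n_studies >= 1,
            n_random_studies >= 0, n_random_studies < n_studies,
            sigma > 0, n_clusters >= 1, n_clusters <= n_signal,
            n_samples >= 4, case_fraction > 0, case_fraction < 1,
            train_fraction > 0, train_fraction < 1)
  sizes <- cluster_sizes(n_signal, n_clusters)
  if (rho >= 1 || rho <= -1 / (max(sizes) - 1 + (max(sizes) == 1)))
    stop(sprintf("rho = %g does not give a positive-definite exchangeable block of size %d",
                 rho, max(sizes)))
  structure(list(n_signal = n_signal, n_nonsignal = n_nonsignal,
                 n_studies = n_studies, n_random_studies = n_random_studies,
                 sigma = sigma, mu = mu, rho = rho, n_clusters = n_clusters,
                 n_samples = n_samples, case_fraction = case_fraction,
                 train_fraction = train_fraction),
            class = "sim_design")
}

cluster_sizes <- function(n_signal, n_clusters) {
  base <- n_signal %/% n_clusters
  sizes <- rep(base, n_clusters)
  extra <- n_signal - base * n_clusters
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

signal_covariance <- function(design) {
  sizes <- cluster_sizes(design$n_signal, design$n_clusters)
  blocks <- lapply(sizes, function(b) {
    m <- matrix(design$rho, b, b); diag(m) <- 1; m
  })
  S <- matrix(0, design$n_signal, design$n_signal)
  at <- 0L
  for (b in blocks) {
    idx <- at + seq_len(nrow(b))
    S[idx, idx] <- b
    at <- at + nrow(b)
  }
  design$sigma^2 * S
}

#' Generate a synthetic multi-study stack
#'
#' Draws the studies described by a [sim_design()] over a shared cohort of
#' `n_samples` with fixed labels (the first `round(case_fraction * n)`
#' samples are cases). Signal genes come first in gene order; the returned
#' stack carries per-gene ground-truth flags in its `signal` element. The
#' last `n_random_studies` studies are all-noise.
#'
#' @param design a [sim_design()].
#' @param seed optional integer seed for reproducibility.
#' @return An [omics_stack()] with `signal` set.
#' @export
generate_stack <- function(design, seed = NULL) {
  stopifnot(inherits(design, "sim_design"))
  if (!is.null(seed)) set.seed(seed)
  n <- design$n_samples
  k <- design$n_signal + design$n_nonsignal
  n_case <- round(n * design$case_fraction)
  labels <- c(rep(1L, n_case), rep(0L, n - n_case))
  Sigma <- signal_covariance(design)
  gene_ids <- c(sprintf("signal_%02d", seq_len(design$n_signal)),
                sprintf("noise_%02d", seq_len(design$n_nonsignal)))
  studies <- vector("list", design$n_studies)
  n_inform <- design$n_studies - design$n_random_studies
  for (m in seq_len(design$n_studies)) {
    if (m <= n_inform) {
      sig <- MASS::mvrnorm(n, mu = rep(0, design$n_signal), Sigma = Sigma)
      sig[labels == 1L, ] <- sig[labels == 1L, ] + design$mu
      nonsig <- matrix(stats::rnorm(n * design$n_nonsignal, 0, design$sigma),
                       n, design$n_nonsignal)
      studies[[m]] <- cbind(sig, nonsig)
    } else {
      studies[[m]] <- matrix(stats::rnorm(n * k, 0, design$sigma), n, k)
    }
    colnames(studies[[m]]) <- gene_ids
  }
  omics_stack(studies, labels, gene_ids = gene_ids,
              study_ids = sprintf("study_%d", seq_len(design$n_studies)),
              signal = rep(c(TRUE, FALSE),
                           c(design$n_signal, design$n_nonsignal)))
}

#' Stratified train/test split
#'
#' Splits the cohort at `train_fraction`, stratified by outcome so both
#' classes appear on both sides; the same sample indices are applied to
#' every study. Resamples up to 100 times if a side ends up single-class.
#'
#' @param stack an [omics_stack()] with at least 10 samples.
#' @param train_fraction proportion of samples assigned to training; a
#'   [sim_design()] may be given instead, in which case its
#'   `train_fraction` is used.
#' @param seed optional integer seed.
#' @return List with `train` and `test` stacks plus the `train_idx` used.
#' @export
split_train_test <- function(stack, train_fraction = 0.7, seed = NULL) {
  if (inherits(train_fraction, "sim_design"))
    train_fraction <- train_fraction$train_fraction
  stopifnot(train_fraction > 0, train_fraction < 1)
  n <- dim(stack$x)[1]
  if (n < 10) stop("at least 10 samples are required for a split")
  if (!is.null(seed)) set.seed(seed)
  for (try in seq_len(100)) {
    idx <- unlist(lapply(split(seq_len(n), stack$labels), function(ix) {
      sample(ix, round(length(ix) * train_fraction))
    }), use.names = FALSE)
    idx <- sort(idx)
    test <- setdiff(seq_len(n), idx)
    if (length(unique(stack$labels[idx])) == 2 &&
        length(unique(stack$labels[test])) == 2)
      return(list(train = subset_stack(stack, idx),
                  test = subset_stack(stack, test),
                  train_idx = idx))
  }
  stop("could not produce a split with both classes on both sides")
}
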