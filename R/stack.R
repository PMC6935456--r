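#' Multi-study omics container
#'
#' An `omics_stack` holds D gene-aligned study matrices together with a
#' binary outcome. Internally values live in a 4-dimensional array indexed
#' (sample, gene, hidden node, input feature); in the common case of one
#' measured value per gene per study there is one hidden node per study and
#' a single input feature per node, so a list of N x K study matrices maps
#' onto dimensions N x K x D x 1.
#'
#' @param studies list of numeric matrices, one per study, each N samples x
#'   K genes with identical gene order, or a 4-d numeric array already in
#'   (sample, gene, node, feature) layout.
#' @param labels binary (0/1) outcome vector of length N.
#' @param gene_ids optional character vector of K gene identifiers; taken
#'   from the first study's column names when present.
#' @param study_ids optional character vector of study identifiers.
#' @param signal optional logical vector of length K flagging ground-truth
#'   signal genes (carried by the simulator).
#'
#' @return An object of class `omics_stack` with elements `x` (the 4-d
#'   array), `labels`, `gene_ids`, `study_ids` and optionally `signal`.
#' @export
omics_stack <- function(studies, labels, gene_ids = NULL, study_ids = NULL,
                        signal = NULL) {
  if (is.array(studies) && length(dim(studies)) == 4L) {
    x <- studies
  } else {
    if (!is.list(studies) || length(studies) == 0L)
      stop("`studies` must be a non-empty list of matrices or a 4-d array")
    studies <- lapply(studies, as.matrix)
    dims <- vapply(studies, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("all studies must share the same samples x genes dimensions")
    if (is.null(gene_ids)) gene_ids <- colnames(studies[[1]])
    cn <- lapply(studies, colnames)
    if (!is.null(gene_ids) && any(vapply(cn, function(v)
      !is.null(v) && !identical(v, gene_ids), logical(1))))
      stop("gene columns are not aligned across studies; see read_stack()")
    x <- array(0, c(dims[1, 1], dims[2, 1], length(studies), 1L))
    for (m in seq_along(studies)) x[, , m, 1L] <- studies[[m]]
  }
  n <- dim(x)[1]; k <- dim(x)[2]; d <- dim(x)[3]
  labels <- as.integer(labels)
  if (length(labels) != n)
    stop(sprintf("labels length (%d) does not match sample count (%d)",
                 length(labels), n))
  if (!all(labels %in% c(0L, 1L))) stop("labels must be coded 0/1")
  if (!all(is.finite(x))) stop("study values must all be finite")
  if (is.null(gene_ids)) gene_ids <- sprintf("gene_%03d", seq_len(k))
  if (is.null(study_ids)) study_ids <- sprintf("study_%d", seq_len(d))
  if (length(gene_ids) != k) stop("gene_ids must have one entry per gene")
  if (length(study_ids) != d) stop("study_ids must have one entry per study")
  if (!is.null(signal)) {
    signal <- as.logical(signal)
    if (length(signal) != k) stop("signal flags must have one entry per gene")
  }
  structure(list(x = x, labels = labels, gene_ids = gene_ids,
                 study_ids = study_ids, signal = signal),
            class = "omics_stack")
}

#' @export
print.omics_stack <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("omics_stack: %d samples, %d genes, %d hidden nodes/gene, %d feature(s)/node\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  labels: %d cases / %d controls\n",
              sum(x$labels == 1L), sum(x$labels == 0L)))
  if (!is.null(x$signal))
    cat(sprintf("  ground truth: %d signal / %d nonsignal genes\n",
                sum(x$signal), sum(!x$signal)))
  invisible(x)
}

#' @export
dim.omics_stack <- function(x) dim(x$x)

#' Number of samples, genes, nodes in a stack
#' @param stack an `omics_stack`.
#' @return Named integer vector with elements `n`, `k`, `m`, `p`.
#' @export
stack_dims <- function(stack) {
  d <- dim(stack$x)
  c(n = d[1], k = d[2], m = d[3], p = d[4])
}

#' Subset an omics stack by sample index
#'
#' Applies the same sample selection to every study; gene metadata and
#' ground-truth flags are carried through unchanged.
#'
#' @param stack an `omics_stack`.
#' @param idx integer vector of sample indices to keep.
#' @return An `omics_stack` with `length(idx)` samples.
#' @export
subset_stack <- function(stack, idx) {
  idx <- as.integer(idx)
  n <- dim(stack$x)[1]
  if (any(idx < 1L | idx > n)) stop("sample index out of range")
  structure(list(x = stack$x[idx, , , , drop = FALSE],
                 labels = stack$labels[idx],
                 gene_ids = stack$gene_ids,
                 study_ids = stack$study_ids,
                 signal = stack$signal),
            class = "omics_stack")
}

#' Network parameters for the consolidation-layer model
#'
#' Holds the three weight families of the architecture: `v` (input to
#' hidden, indexed gene x node x feature), `w` (hidden to consolidation,
#' indexed gene x node) and the output coefficients `beta0` (intercept) and
#' `beta` (one per gene). The consolidation step normalizes each gene's `w`
#' vector by its Euclidean norm, so every row of `w` must have nonzero norm.
#'
#' @param v numeric array K x M x P.
#' @param w numeric matrix K x M.
#' @param beta0 numeric scalar intercept.
#' @param beta numeric vector of length K.
#' @return An object of class `network_params`.
#' @export
network_params <- function(v, w, beta0, beta) {
  v <- as.array(v)
  if (length(dim(v)) == 2L) dim(v) <- c(dim(v), 1L)
  w <- as.matrix(w)
  if (!identical(dim(v)[1:2], dim(w)))
    stop("v and w disagree on gene/node dimensions")
  if (length(beta) != nrow(w))
    stop("beta must have one coefficient per gene")
  if (!all(is.finite(v)) || !all(is.finite(w)) ||
      !all(is.finite(beta)) || !is.finite(beta0))
    stop("all parameters must be finite")
  nw <- sqrt(rowSums(w^2))
  if (any(nw == 0)) {
    bad <- which(nw == 0)[1]
    stop(sprintf("consolidation weights for gene %d have zero norm", bad))
  }
  structure(list(v = v, w = w, beta0 = as.numeric(beta0),
                 beta = as.numeric(beta)),
            class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  d <- dim(x$v)
  cat(sprintf("network_params: %d genes, %d hidden nodes/gene, %d feature(s)/node\n",
              d[1], d[2], d[3]))
  cat(sprintf("  |beta| range: [%.4g, %.4g], intercept %.4g\n",
              min(abs(x$beta)), max(abs(x$beta)), x$beta0))
  invisible(x)
}

check_conformance <- function(stack, params) {
  sd <- dim(stack$x); pd <- dim(params$v)
  if (sd[2] != pd[1] || sd[3] != pd[2] || sd[4] != pd[3])
    stop(sprintf(
      "stack (genes=%d, nodes=%d, features=%d) does not conform to params (genes=%d, nodes=%d, features=%d)",
      sd[2], sd[3], sd[4], pd[1], pd[2], pd[3]))
  invisible(TRUE)
}
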