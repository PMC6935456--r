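#' Read aligned study matrices and labels from delimited text
#'
#' Each study file is a samples x genes table with a header row of gene
#' symbols; the delimiter (tab or comma) is auto-detected per file. Gene
#' columns are intersected across studies by symbol and re-ordered to the
#' first study's order; dropped symbols are reported via `message()`.
#'
#' @param study_paths character vector of study file paths (one per study).
#' @param labels_path path to a single-column text file of 0/1 labels.
#' @param study_ids optional study identifiers; defaults to file basenames.
#' @return An [omics_stack()].
#' @export
read_stack <- function(study_paths, labels_path, study_ids = NULL) {
  stopifnot(length(study_paths) >= 1)
  for (p in c(study_paths, labels_path))
    if (!file.exists(p)) stop(sprintf("file not found: %s", p))
  mats <- lapply(study_paths, read_study_matrix)
  genes <- Reduce(intersect, lapply(mats, colnames))
  if (length(genes) == 0)
    stop("no gene symbols are shared by all studies")
  dropped <- unique(unlist(lapply(mats, function(m)
    setdiff(colnames(m), genes))))
  if (length(dropped) > 0)
    message(sprintf("dropped %d gene(s) absent from some study: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  genes <- genes[order(match(genes, colnames(mats[[1]])))]
  mats <- lapply(mats, function(m) m[, genes, drop = FALSE])
  ns <- vapply(mats, nrow, integer(1))
  if (any(ns != ns[1]))
    stop(sprintf("studies disagree on sample count: %s",
                 paste(ns, collapse = ", ")))
  labels <- scan(labels_path, what = numeric(), quiet = TRUE)
  if (length(labels) != ns[1])
    stop(sprintf("labels length (%d) does not match sample count (%d)",
                 length(labels), ns[1]))
  if (is.null(study_ids))
    study_ids <- tools::file_path_sans_ext(basename(study_paths))
  omics_stack(mats, labels, gene_ids = genes, study_ids = study_ids)
}

read_study_matrix <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(!vapply(df, is.numeric, logical(1)))[1]
    stop(sprintf("non-numeric values in %s, column '%s'", path,
                 colnames(df)[bad]))
  }
  m
}

#' Write a stack as per-study TSV matrices plus labels and truth files
#'
#' Inverse of [read_stack()]: one `<study_id>.tsv` per study (samples x
#' genes with a gene-symbol header), `labels.txt`, and — when the stack
#' carries ground-truth flags — `truth.tsv` with columns gene_id,
#' is_signal.
#'
#' @param stack an [omics_stack()] with one feature per node.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_stack <- function(stack, dir) {
  d <- dim(stack$x)
  if (d[4] != 1)
    stop("only stacks with one feature per node can be written as study matrices")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (m in seq_len(d[3])) {
    mat <- stack$x[, , m, 1]
    dim(mat) <- d[1:2]
    colnames(mat) <- stack$gene_ids
    p <- file.path(dir, paste0(stack$study_ids[m], ".tsv"))
    utils::write.table(mat, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  lp <- file.path(dir, "labels.txt")
  writeLines(as.character(stack$labels), lp)
  paths <- c(paths, lp)
  if (!is.null(stack$signal)) {
    tp <- file.path(dir, "truth.tsv")
    utils::write.table(data.frame(gene_id = stack$gene_ids,
                                  is_signal = as.integer(stack$signal)),
                       tp, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, tp)
  }
  invisible(paths)
}

params_format_version <- "1.0"

#' Serialize network parameters to JSON
#'
#' Writes all three weight families with explicit index keys and a format
#' version so files remain readable across package versions.
#'
#' @param params a [network_params()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_params <- function(params, path) {
  d <- dim(params$v)
  obj <- list(format_version = params_format_version,
              dims = list(genes = d[1], nodes = d[2], features = d[3]),
              beta0 = params$beta0,
              beta = as.numeric(params$beta),
              w = lapply(seq_len(d[1]), function(k) as.numeric(params$w[k, ])),
              v = lapply(seq_len(d[1]), function(k) {
                lapply(seq_len(d[2]), function(m)
                  as.numeric(params$v[k, m, ]))
              }))
  # I(17) significant digits: lossless double round trip
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read network parameters from JSON written by [write_params()]
#'
#' @param path file path.
#' @return A [network_params()].
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$format_version))
    stop("not a parameters file: missing format_version")
  k <- obj$dims$genes; m <- obj$dims$nodes; p <- obj$dims$features
  w <- matrix(vapply(obj$w, function(row) unlist(row, use.names = FALSE),
                     numeric(m)), k, m, byrow = TRUE)
  v <- array(0, c(k, m, p))
  for (i in seq_len(k)) for (j in seq_len(m))
    v[i, j, ] <- unlist(obj$v[[i]][[j]], use.names = FALSE)
  network_params(v = v, w = w, beta0 = obj$beta0,
                 beta = unlist(obj$beta, use.names = FALSE))
}

#' Write an experiment report as TSV
#'
#' @param report an `idl_experiment` data.frame (rows may be rbind-ed from
#'   several [run_experiment()] calls).
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a regularization path as long-format TSV
#'
#' Columns lambda, gene_id, beta_hat — suitable for re-plotting coefficient
#' trajectories.
#'
#' @param path_obj a `lambda_path`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_lambda_path <- function(path_obj, path) {
  long <- data.frame(
    lambda = rep(path_obj$lambdas, each = ncol(path_obj$betas)),
    gene_id = rep(colnames(path_obj$betas), length(path_obj$lambdas)),
    beta_hat = as.numeric(t(path_obj$betas)))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Reproducibility manifest
#'
#' Records the configuration, seed and session versions of a run as JSON.
#'
#' @param config named list echoing the run configuration.
#' @param seed the seed used.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(config, seed, path) {
  obj <- list(config = config, seed = seed,
              r_version = as.character(getRversion()),
              package_version =
                as.character(utils::packageVersion("conslayer")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
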