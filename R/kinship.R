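#' Centered genomic kinship matrix
#'
#' Computes the centered relatedness matrix
#' \deqn{K = \frac{1}{m} \sum_i (x_i - 2\hat p_i)(x_i - 2\hat p_i)^T}
#' over the panel's sites (GEMMA's centered convention, `-gk 1`), with
#' missing dosages mean-imputed per site. The eigendecomposition is cached
#' on the object because every mixed-model fit reuses it.
#'
#' @param g A [genotype_matrix()] with at least 2 samples, at least one of
#'   whose sites is polymorphic.
#' @return An object of class `kinship_matrix`: `sample_ids`, `values`
#'   (n x n), `eigen` (as from [eigen()]), `m` (site count) and
#'   `scaling = "centered"`.
#' @export
compute_kinship <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- length(g$sample_ids)
  if (n < 2L) stop("compute_kinship: need >= 2 samples", call. = FALSE)
  X <- impute_dosage(g)
  Xc <- sweep(X, 2L, colMeans(X))
  if (max(abs(Xc)) < 1e-12) {
    stop("compute_kinship: all sites monomorphic - kinship undefined",
      call. = FALSE
    )
  }
  K <- tcrossprod(Xc) / ncol(Xc)
  K <- (K + t(K)) / 2
  structure(list(
    sample_ids = g$sample_ids,
    values = K,
    eigen = eigen(K, symmetric = TRUE),
    m = ncol(Xc),
    scaling = "centered"
  ), class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(
    "<kinship_matrix>", length(x$sample_ids), "samples,",
    x$scaling, "scaling, from", x$m, "sites\n"
  )
  cat("  mean diagonal:", format(mean(diag(x$values)), digits = 4), "\n")
  invisible(x)
}

#' @rdname compute_kinship
#' @param k A `kinship_matrix`.
#' @param path Output TSV path (square matrix, header = sample ids).
#' @export
write_kinship <- function(k, path) {
  d <- as.data.frame(k$values)
  names(d) <- k$sample_ids
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
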