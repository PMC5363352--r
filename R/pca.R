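#' First principal component of an intensity matrix
#'
#' PC1 of the column-mean-centred samples-by-probes matrix, with every
#' probe weighted equally (no variance rescaling). The sign is fixed so
#' that PC1 correlates negatively with the per-sample mean log2 ratio:
#' deletions, which lower the mean ratio, therefore sit at high PC1, the
#' orientation under which a high-PC1 cutoff isolates homozygous
#' deletions.
#'
#' @param x An `intensity_matrix` or a numeric samples-by-probes matrix.
#' @param probe_subset Optional probe ids or column indices to restrict to.
#' @return Object of class `pc_result`: list with `scores` (named
#'   per-sample values), `loadings` (unit-norm per-probe weights),
#'   `orientation` (+1/-1 applied sign) and `center`.
#' @export
pc_scores <- function(x, probe_subset = NULL) {
  m <- if (inherits(x, "intensity_matrix")) x$values else as.matrix(x)
  if (!is.null(probe_subset)) m <- m[, probe_subset, drop = FALSE]
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("need at least 2 samples and 2 probes", call. = FALSE)
  if (anyNA(m)) stop("missing values in intensity matrix", call. = FALSE)
  ctr <- colMeans(m)
  mc <- sweep(m, 2L, ctr)
  if (max(abs(mc)) < .Machine$double.eps^0.5) {
    warning("constant matrix: PC1 scores are all zero")
    return(structure(list(scores = setNames(rep(0, nrow(m)), rownames(m)),
                          loadings = c(1, rep(0, ncol(m) - 1L)),
                          orientation = 1, center = ctr),
                     class = "pc_result"))
  }
  sv <- svd(mc, nu = 1L, nv = 1L)
  scores <- drop(mc %*% sv$v[, 1L])
  flip <- 1
  rm_ <- rowMeans(m)
  if (sd(rm_) > 0 && sd(scores) > 0) {
    if (cor(scores, rm_) > 0) flip <- -1
  }
  structure(list(scores = setNames(flip * scores, rownames(m)),
                 loadings = flip * sv$v[, 1L],
                 orientation = flip, center = ctr),
            class = "pc_result")
}

#' @export
print.pc_result <- function(x, ...) {
  cat(sprintf("pc_result: %d samples, orientation %+d, score range [%.3f, %.3f]\n",
              length(x$scores), x$orientation, min(x$scores), max(x$scores)))
  invisible(x)
}
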