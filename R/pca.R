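#' Principal component analysis of reporter signatures
#'
#' Eigen-decomposition of the covariance matrix of the (optionally
#' standardized) reporter matrix. Deterministic up to sign; the sign of each
#' component is fixed so that its largest-magnitude loading is positive,
#' making scores comparable across runs. Explained-variance ratios are
#' eigenvalues over the total variance, so they are nonincreasing and sum to
#' 1 over all `min(n, k)` components of centred data.
#'
#' @param ds A [reporter_dataset()] or numeric matrix (samples x reporters).
#' @param n_components Number of components to keep, at most `min(n, k)`.
#' @param standardize Scale reporters to unit variance before the
#'   decomposition (zero-variance reporters are left unscaled).
#' @return An object of class `pca_result`: `scores` (n x c), `loadings`
#'   (k x c), `explained_variance_ratio` (length c), plus the centring and
#'   scaling vectors used.
#' @export
reporter_pca <- function(ds, n_components = 2L, standardize = FALSE) {
  x <- if (inherits(ds, "reporter_dataset")) ds$values else as.matrix(ds)
  n <- nrow(x); k <- ncol(x)
  if (n_components < 1L || n_components > min(n, k)) {
    stop("`n_components` must be between 1 and min(n, k) = ", min(n, k),
         call. = FALSE)
  }
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  scl <- rep(1, k)
  if (standardize) {
    scl <- apply(xc, 2L, stats::sd)
    scl[!is.finite(scl) | scl == 0] <- 1
    xc <- sweep(xc, 2L, scl, "/")
  }
  S <- stats::cov(xc)
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  evr <- vals / sum(vals)
  idx <- seq_len(n_components)
  load <- e$vectors[, idx, drop = FALSE]
  for (j in seq_len(ncol(load))) {
    peak <- which.max(abs(load[, j]))
    if (load[peak, j] < 0) load[, j] <- -load[, j]
  }
  dimnames(load) <- list(colnames(x), paste0("PC", idx))
  scores <- xc %*% load
  dimnames(scores) <- list(rownames(x), paste0("PC", idx))
  structure(list(scores = scores, loadings = load,
                 explained_variance_ratio = evr[idx],
                 center = ctr, scale = scl),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d components; explained variance: %s\n",
              ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained_variance_ratio),
                    collapse = ", ")))
  invisible(x)
}

#' Score plot of a PCA result
#'
#' @param pca A [reporter_pca()] result.
#' @param class_labels Character vector colouring the samples.
#' @param path Optional figure path; when given the plot is written there.
#' @return A ggplot object, invisibly when written to file.
#' @export
plot_pca <- function(pca, class_labels, path = NULL) {
  df <- data.frame(PC1 = pca$scores[, 1],
                   PC2 = if (ncol(pca$scores) >= 2L) pca$scores[, 2] else 0,
                   class = class_labels)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                        colour = .data$class)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * pca$explained_variance_ratio[1]),
      y = if (ncol(pca$scores) >= 2L)
        sprintf("PC2 (%.1f%%)", 100 * pca$explained_variance_ratio[2])
      else "") +
    ggplot2::theme_classic()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 5, height = 4)
    return(invisible(p))
  }
  p
}
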