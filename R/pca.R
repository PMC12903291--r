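#' Principal component analysis of an intensity matrix
#'
#' Centered (and optionally scaled) PCA on log2 intensities via singular
#' value decomposition. Component signs are fixed so the largest-magnitude
#' loading of each component is positive, making score plots reproducible.
#'
#' @param matrix A complete \code{\link{intensity_matrix}} (no missing
#'   values; see \code{\link{impute_missing}}).
#' @param n_components Number of components, at most
#'   \code{min(n_samples - 1, n_metabolites)}.
#' @param scaling \code{"uv"} (unit variance, default), \code{"pareto"} or
#'   \code{"none"}; centering is always applied.
#' @param log2_transform Analyze \code{log2(x + 1)} intensities (default
#'   TRUE, matching the multiplicative nature of LC-MS data).
#' @return A \code{pca_result}: \code{scores} (samples x components),
#'   \code{loadings} (metabolites x components, orthonormal columns) and
#'   \code{explained_variance_fraction}.
#' @export
run_pca <- function(matrix, n_components = 2,
                    scaling = c("uv", "pareto", "none"),
                    log2_transform = TRUE) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  if (anyNA(matrix$values)) {
    stop("matrix has missing values; impute_missing() first", call. = FALSE)
  }
  scaling <- match.arg(scaling)
  x <- matrix$values
  if (log2_transform) x <- log2(x + 1)
  kmax <- min(nrow(x) - 1L, ncol(x))
  check_scalar_number(n_components, "n_components", lower = 1, upper = kmax,
                      integerish = TRUE)
  sc <- scale_columns(x, scaling)
  pc <- stats::prcomp(sc$x, center = FALSE, scale. = FALSE)
  k <- n_components
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  # sign convention: largest-|loading| entry positive per component
  for (a in seq_len(k)) {
    i <- which.max(abs(loadings[, a]))
    if (loadings[i, a] < 0) {
      loadings[, a] <- -loadings[, a]
      scores[, a] <- -scores[, a]
    }
  }
  expl <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  rownames(scores) <- matrix$sample_ids
  rownames(loadings) <- matrix$metabolite_ids
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  structure(
    list(scores = scores, loadings = loadings,
         explained_variance_fraction = expl,
         scaling = scaling, group_labels = matrix$group_labels),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:\n")
  for (a in seq_along(x$explained_variance_fraction)) {
    cat(sprintf("  PC%d: %.2f%% of variance\n", a,
                100 * x$explained_variance_fraction[a]))
  }
  invisible(x)
}
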