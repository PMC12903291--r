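## Missingness filtering and imputation ahead of PCA / OPLS-DA.

#' Filter metabolites by within-group missingness
#'
#' A metabolite is removed only if its missing fraction strictly exceeds
#' \code{max_missing_frac} in \emph{every} group (\code{rule = "all"},
#' default), so a peak well-observed in one group survives — such peaks are
#' biologically informative. \code{rule = "any"} removes a metabolite as
#' soon as one group exceeds the threshold.
#'
#' @param matrix An \code{\link{intensity_matrix}}.
#' @param max_missing_frac Missingness threshold in [0, 1); the comparison
#'   is strict, so exactly 50\% missing is retained at the default 0.5.
#' @param rule \code{"all"} or \code{"any"} (which groups must exceed the
#'   threshold for removal).
#' @return The filtered \code{intensity_matrix}, with the removed metabolite
#'   ids in \code{attr(, "removed")}.
#' @export
filter_missing <- function(matrix, max_missing_frac = 0.5,
                           rule = c("all", "any")) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  check_scalar_number(max_missing_frac, "max_missing_frac", 0, 1,
                      strict_upper = TRUE)
  rule <- match.arg(rule)
  groups <- unique(matrix$group_labels)
  frac <- sapply(groups, function(g) {
    colMeans(is.na(matrix$values[matrix$group_labels == g, , drop = FALSE]))
  })  # metabolites x groups
  exceed <- frac > max_missing_frac
  drop <- if (rule == "all") apply(exceed, 1, all) else apply(exceed, 1, any)
  keep <- which(!drop)
  out <- intensity_matrix(matrix$values[, keep, drop = FALSE],
                          group_labels = matrix$group_labels,
                          sample_ids = matrix$sample_ids,
                          metabolite_ids = matrix$metabolite_ids[keep],
                          class_labels = matrix$class_labels[keep])
  attr(out, "removed") <- matrix$metabolite_ids[drop]
  out
}

#' Impute remaining missing intensities
#'
#' \code{half_min} (default) replaces each missing entry with half the
#' metabolite's observed minimum — the conventional stand-in for
#' below-detection-limit LC-MS peaks. \code{min} uses the observed minimum
#' itself and \code{zero} uses 0.
#'
#' @param matrix An \code{\link{intensity_matrix}}; every metabolite must
#'   have at least one observed value (run \code{\link{filter_missing}}
#'   first).
#' @param method One of \code{"half_min"}, \code{"min"}, \code{"zero"}.
#' @return A complete \code{intensity_matrix}.
#' @export
impute_missing <- function(matrix, method = c("half_min", "min", "zero")) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  method <- match.arg(method)
  v <- matrix$values
  all_missing <- colSums(!is.na(v)) == 0L
  if (any(all_missing)) {
    stop(sprintf(
      "metabolite(s) with no observed values: %s; run filter_missing() first",
      paste(matrix$metabolite_ids[all_missing], collapse = ", ")),
      call. = FALSE)
  }
  for (j in which(colSums(is.na(v)) > 0L)) {
    fill <- switch(method,
                   half_min = min(v[, j], na.rm = TRUE) / 2,
                   min = min(v[, j], na.rm = TRUE),
                   zero = 0)
    v[is.na(v[, j]), j] <- fill
  }
  intensity_matrix(v, group_labels = matrix$group_labels,
                   sample_ids = matrix$sample_ids,
                   metabolite_ids = matrix$metabolite_ids,
                   class_labels = matrix$class_labels)
}

## Column scaling used by PCA and OPLS-DA: mean-centering always, then
## unit-variance ("uv", the chemometrics auto-scaling default), Pareto
## (sqrt-sd) or none. Constant columns are centered only.
scale_columns <- function(x, scaling = c("uv", "pareto", "none")) {
  scaling <- match.arg(scaling)
  ctr <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  scl <- switch(scaling,
                uv = ifelse(sds > 0, sds, 1),
                pareto = ifelse(sds > 0, sqrt(sds), 1),
                none = rep(1, ncol(x)))
  xs <- sweep(sweep(x, 2, ctr), 2, scl, `/`)
  list(x = xs, center = ctr, scale = scl, scaling = scaling)
}

apply_scaling <- function(x, sc) {
  sweep(sweep(x, 2, sc$center), 2, sc$scale, `/`)
}
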