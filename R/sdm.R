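## Significantly differential metabolite (SDM) selection and class summary.

#' Select significantly differential metabolites
#'
#' A metabolite is selected iff VIP strictly exceeds \code{vip_threshold}
#' AND its two-sided Student's t-test p-value is strictly below
#' \code{p_threshold} — the conventional VIP > 1, P < 0.05 rule. Tests run
#' on log2-transformed intensities by default (LC-MS intensities are
#' multiplicative); direction comes from the sign of the high-vs-low log2
#' fold change.
#'
#' @param matrix A complete two-group \code{\link{intensity_matrix}}.
#' @param vip Named VIP vector from \code{\link{compute_vip}}, aligned with
#'   the matrix metabolites.
#' @param vip_threshold,p_threshold Strict selection thresholds (defaults 1
#'   and 0.05).
#' @param log2_transform Test on \code{log2(x + 1)} (default TRUE).
#' @return An \code{sdm_table} data frame sorted by VIP descending, with
#'   per-metabolite VIP, p-value, log2 fold change (high/low), direction
#'   (\code{up}/\code{down}) and \code{selected}.
#' @export
select_sdms <- function(matrix, vip, vip_threshold = 1, p_threshold = 0.05,
                        log2_transform = TRUE) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  if (anyNA(matrix$values)) {
    stop("matrix has missing values; impute_missing() first", call. = FALSE)
  }
  if (length(vip) != length(matrix$metabolite_ids) ||
      !identical(names(vip), matrix$metabolite_ids)) {
    stop("VIP vector is not aligned with the matrix metabolites",
         call. = FALSE)
  }
  x <- matrix$values
  if (log2_transform) x <- log2(x + 1)
  hi <- matrix$group_labels == "high"
  if (!any(hi)) hi <- matrix$group_labels == sort(unique(matrix$group_labels))[2]
  pvals <- apply(x, 2, function(col) {
    a <- col[hi]; b <- col[!hi]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(if (mean(a) == mean(b)) 1 else 0)
    }
    stats::t.test(a, b, var.equal = TRUE)$p.value
  })
  log2fc <- colMeans(x[hi, , drop = FALSE]) - colMeans(x[!hi, , drop = FALSE])
  out <- data.frame(
    metabolite = matrix$metabolite_ids,
    class = matrix$class_labels,
    vip = unname(vip),
    p_value = unname(pvals),
    log2_fc = unname(log2fc),
    direction = ifelse(log2fc >= 0, "up", "down"),
    selected = unname(vip) > vip_threshold & unname(pvals) < p_threshold,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$vip), ]
  rownames(out) <- NULL
  class(out) <- c("sdm_table", "data.frame")
  out
}

#' Class-level summary and z-scored heatmap matrix of selected SDMs
#'
#' Builds the class-grouped heatmap substrate: each selected metabolite's
#' log2 intensities are z-scored across samples (mean 0, sd 1 per row) and
#' rows are ordered by metabolite class; per-class counts of up- and
#' down-regulated SDMs are tallied. An empty selection yields an empty
#' summary, not an error.
#'
#' @param matrix The complete \code{\link{intensity_matrix}} the SDM table
#'   came from.
#' @param sdm An \code{\link{select_sdms}} table.
#' @param log2_transform Use \code{log2(x + 1)} intensities (default).
#' @return A list with \code{counts} (class, n_up, n_down, n_total) and
#'   \code{zmatrix} (selected metabolites x samples, z-scored, ordered by
#'   class).
#' @export
class_summary <- function(matrix, sdm, log2_transform = TRUE) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  sel <- sdm[sdm$selected, , drop = FALSE]
  if (nrow(sel) == 0L) {
    return(list(
      counts = data.frame(class = character(0), n_up = integer(0),
                          n_down = integer(0), n_total = integer(0)),
      zmatrix = matrix(numeric(0), 0, nrow(matrix$values),
                       dimnames = list(NULL, matrix$sample_ids))))
  }
  sel <- sel[order(sel$class, sel$metabolite), , drop = FALSE]
  x <- matrix$values[, sel$metabolite, drop = FALSE]
  if (log2_transform) x <- log2(x + 1)
  z <- apply(x, 2, function(col) {
    s <- stats::sd(col)
    if (s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  zmat <- t(z)  # metabolites x samples
  counts <- do.call(rbind, lapply(split(sel, sel$class), function(d) {
    data.frame(class = d$class[1],
               n_up = sum(d$direction == "up"),
               n_down = sum(d$direction == "down"),
               n_total = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(counts) <- NULL
  list(counts = counts, zmatrix = zmat)
}

#' Write the SDM table and volcano-plot substrate to TSV
#'
#' @param sdm An \code{sdm_table}.
#' @param path Destination TSV.
#' @return The path, invisibly.
#' @export
write_sdm_table <- function(sdm, path) {
  out <- sdm
  out$neg_log10_p <- -log10(out$p_value)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
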