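#' Construct a sample-by-metabolite intensity matrix
#'
#' The central container for the untargeted-metabolomics arm: a numeric
#' matrix of nonnegative LC-MS-style intensities (rows = samples, columns =
#' metabolites) with two-group sample labels, per-metabolite class
#' annotations, and missing values represented as \code{NA}.
#'
#' @param values Numeric matrix, samples in rows, metabolites in columns;
#'   \code{NA} marks a missing peak.
#' @param group_labels Character or factor of length \code{nrow(values)} with
#'   exactly two distinct values (e.g. \code{"low"} / \code{"high"}).
#' @param sample_ids Optional sample identifiers (default: row names or
#'   \code{S1..Sn}).
#' @param metabolite_ids Optional metabolite identifiers (default: column
#'   names or \code{M1..Mp}).
#' @param class_labels Optional per-metabolite class annotation drawn from
#'   \code{metabolite_class_vocabulary()}; defaults to \code{"other"}.
#' @return An object of class \code{intensity_matrix}.
#' @export
intensity_matrix <- function(values, group_labels, sample_ids = NULL,
                             metabolite_ids = NULL, class_labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_field("values", "must be a numeric matrix")
  }
  n <- nrow(values); p <- ncol(values)
  sample_ids <- sample_ids %||% rownames(values) %||% paste0("S", seq_len(n))
  metabolite_ids <- metabolite_ids %||% colnames(values) %||%
    paste0("M", seq_len(p))
  if (length(sample_ids) != n) abort_field("sample_ids", "length mismatch")
  if (length(metabolite_ids) != p) {
    abort_field("metabolite_ids", "length mismatch")
  }
  if (anyDuplicated(metabolite_ids)) {
    abort_field("metabolite_ids", "must be unique")
  }
  group_labels <- as.character(group_labels)
  if (length(group_labels) != n) abort_field("group_labels", "length mismatch")
  groups <- sort(unique(group_labels))
  if (length(groups) != 2L) {
    abort_field("group_labels", "exactly two groups are required")
  }
  if (min(table(group_labels)) < 2L) {
    abort_field("group_labels", "each group needs >= 2 samples")
  }
  class_labels <- class_labels %||% rep("other", p)
  if (length(class_labels) != p) abort_field("class_labels", "length mismatch")
  unknown <- setdiff(unique(class_labels), metabolite_class_vocabulary())
  if (length(unknown)) {
    abort_field("class_labels",
                paste("not in the class vocabulary:",
                      paste(unknown, collapse = ", ")))
  }
  if (any(values < 0, na.rm = TRUE)) {
    abort_field("values", "intensities must be nonnegative")
  }
  dimnames(values) <- list(sample_ids, metabolite_ids)
  structure(
    list(values = values, sample_ids = sample_ids,
         group_labels = group_labels, metabolite_ids = metabolite_ids,
         class_labels = class_labels),
    class = "intensity_matrix"
  )
}

#' @export
print.intensity_matrix <- function(x, ...) {
  tab <- table(x$group_labels)
  cat(sprintf("intensity_matrix: %d samples x %d metabolites\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", ")))
  cat(sprintf("  missing: %.1f%%\n", 100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' Write an intensity matrix to TSV plus a JSON sidecar
#'
#' The TSV has samples in rows and metabolites in columns with empty cells
#' for missing values; the sidecar records group labels, metabolite classes
#' and (optionally) the synthetic ground truth, so a dataset round-trips
#' losslessly through the file pair.
#'
#' @param x An \code{intensity_matrix}.
#' @param path TSV destination; the sidecar is written to
#'   \code{paste0(path, ".json")}.
#' @param truth Optional \code{synthetic_truth} attached by the generator.
#' @return Invisibly, the two paths written.
#' @export
write_intensity_matrix <- function(x, path, truth = NULL) {
  stopifnot(inherits(x, "intensity_matrix"))
  df <- as.data.frame(x$values, check.names = FALSE)
  df <- cbind(sample_id = x$sample_ids, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  sidecar <- list(
    group_labels = as.list(stats::setNames(x$group_labels, x$sample_ids)),
    class_labels = as.list(stats::setNames(x$class_labels, x$metabolite_ids))
  )
  if (!is.null(truth)) {
    sidecar$truth <- list(
      differential_ids = truth$differential_ids,
      effects_log2 = as.list(truth$effects_log2)
    )
  }
  json_path <- paste0(path, ".json")
  jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(tsv = path, json = json_path))
}

#' Read an intensity matrix written by \code{write_intensity_matrix}
#'
#' @param path TSV path; \code{paste0(path, ".json")} must exist.
#' @return A list with elements \code{matrix} (an \code{intensity_matrix})
#'   and \code{truth} (a \code{synthetic_truth} or \code{NULL}).
#' @export
read_intensity_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          na.strings = "", stringsAsFactors = FALSE)
  sidecar <- jsonlite::read_json(paste0(path, ".json"))
  sample_ids <- as.character(df$sample_id)
  values <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- sample_ids
  mat <- intensity_matrix(
    values,
    group_labels = unlist(sidecar$group_labels)[sample_ids],
    sample_ids = sample_ids,
    class_labels = unlist(sidecar$class_labels)[colnames(values)]
  )
  truth <- NULL
  if (!is.null(sidecar$truth)) {
    eff <- unlist(sidecar$truth$effects_log2)
    truth <- structure(
      list(differential_ids = unlist(sidecar$truth$differential_ids) %||%
             character(0),
           effects_log2 = eff),
      class = "synthetic_truth"
    )
  }
  list(matrix = mat, truth = truth)
}
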