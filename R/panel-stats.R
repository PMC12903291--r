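## Two-group comparison of quantified plasma metabolites: mean +/- SEM,
## Student's t-test (pooled variance by default, Welch behind a flag),
## percent change relative to the low group, and assumption checks.

sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Compare one panel metabolite between the two groups
#'
#' Pooled-variance two-sided Student's t-test with the low-minus-high sign
#' convention: a metabolite that is higher in the high-elevation group has a
#' negative t. Percent change is computed relative to the low group,
#' \code{(mean_high - mean_low) / mean_low * 100}.
#'
#' @param measurements Panel measurements (long format, as from
#'   \code{\link{generate_panel}} or \code{\link{read_panel}}).
#' @param metabolite Metabolite id to compare.
#' @param var_equal Pooled-variance t-test if \code{TRUE} (default); Welch
#'   otherwise.
#' @param p_gate Optional significance level; when supplied, direction is
#'   reported as \code{"unchanged"} unless p < p_gate. Default \code{NULL}
#'   reports direction from the sign regardless of p.
#' @return A one-row data frame (class \code{group_comparison}) with
#'   means, SEMs, \code{t_statistic} (low minus high), \code{abs_t},
#'   \code{df}, \code{p_value}, \code{percent_change} and \code{direction}.
#' @export
compare_groups <- function(measurements, metabolite, var_equal = TRUE,
                           p_gate = NULL) {
  sub <- measurements[measurements$metabolite == metabolite, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop(sprintf("metabolite '%s' not present in the panel", metabolite),
         call. = FALSE)
  }
  low <- sub$concentration[sub$group == "low"]
  high <- sub$concentration[sub$group == "high"]
  for (g in c("low", "high")) {
    if (length(get(g)) < 2L) {
      stop(sprintf("group '%s' has < 2 values for metabolite '%s'",
                   g, metabolite), call. = FALSE)
    }
  }
  if (stats::sd(low) == 0 && stats::sd(high) == 0 &&
      mean(low) == mean(high)) {
    tt <- list(statistic = c(t = 0),
               parameter = c(df = length(low) + length(high) - 2),
               p.value = 1)
  } else {
    tt <- stats::t.test(low, high, var.equal = var_equal)
  }
  pct <- (mean(high) - mean(low)) / mean(low) * 100
  dir <- if (pct > 0) "higher" else if (pct < 0) "lower" else "unchanged"
  if (!is.null(p_gate) && tt$p.value >= p_gate) dir <- "unchanged"
  out <- data.frame(
    metabolite = metabolite,
    mean_low = mean(low), sem_low = sem(low),
    mean_high = mean(high), sem_high = sem(high),
    t_statistic = unname(tt$statistic),   # (low - high) / SE
    abs_t = abs(unname(tt$statistic)),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    percent_change = pct,
    direction = dir,
    stringsAsFactors = FALSE
  )
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Compare every metabolite in a panel
#'
#' @inheritParams compare_groups
#' @return A data frame with one \code{\link{compare_groups}} row per
#'   metabolite, in panel order.
#' @export
compare_panel <- function(measurements, var_equal = TRUE, p_gate = NULL) {
  mets <- unique(measurements$metabolite)
  out <- do.call(rbind, lapply(mets, function(m) {
    compare_groups(measurements, m, var_equal = var_equal, p_gate = p_gate)
  }))
  rownames(out) <- NULL
  out
}

#' Check t-test assumptions for a two-group comparison
#'
#' Shapiro-Wilk normality per group and a two-sided F-ratio test of variance
#' homogeneity, with advisory pass/fail flags at alpha = 0.05. Zero-variance
#' groups are reported as a degenerate condition rather than an error, and
#' the homogeneity test is skipped for them.
#'
#' @param values_low,values_high Numeric vectors, length >= 3 each.
#' @param alpha Flag threshold (default 0.05).
#' @return A list with per-group normality p-values and flags, the variance
#'   homogeneity p-value and flag, and a \code{degenerate} indicator.
#' @export
check_assumptions <- function(values_low, values_high, alpha = 0.05) {
  for (nm in c("values_low", "values_high")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) < 3L) {
      abort_field(nm, "needs >= 3 numeric values")
    }
  }
  degenerate <- stats::sd(values_low) == 0 || stats::sd(values_high) == 0
  shapiro_p <- function(v) {
    if (stats::sd(v) == 0) return(NA_real_)
    stats::shapiro.test(v)$p.value
  }
  p_low <- shapiro_p(values_low)
  p_high <- shapiro_p(values_high)
  if (degenerate) {
    p_var <- NA_real_
  } else if (stats::var(values_low) == stats::var(values_high)) {
    p_var <- 1  # F = 1 exactly; var.test returns 1 too, kept explicit
  } else {
    p_var <- stats::var.test(values_low, values_high)$p.value
  }
  list(
    normality_p_low = p_low,
    normality_p_high = p_high,
    normality_ok_low = !is.na(p_low) && p_low >= alpha,
    normality_ok_high = !is.na(p_high) && p_high >= alpha,
    variance_p = p_var,
    variance_ok = !is.na(p_var) && p_var >= alpha,
    degenerate = degenerate
  )
}
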