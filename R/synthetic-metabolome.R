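## Synthetic untargeted-metabolome generator.
##
## Emulates the statistical structure the chemometrics arm assumes: log-normal
## peak intensities (effects additive on the log2 scale), a planted fraction
## of differential metabolites with known signed effects, per-entry
## missingness, and metabolite class annotations. Every generator is a pure
## function of its config (seed included), so identical configs give
## bit-identical output.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Configuration for the synthetic metabolome generator
#'
#' Defaults mirror the study design the package emulates: 6 plasma samples
#' per elevation group, 705 identified metabolites of which 222 (31.5\%) are
#' differential, intensities log-normal on the log2 scale.
#'
#' @param n_per_group Samples per group (>= 3).
#' @param n_metabolites Number of metabolites.
#' @param frac_differential Fraction of metabolites with a planted group
#'   effect, in [0, 1].
#' @param effect_log2 Magnitude of the planted log2 group difference; a
#'   single value or a range \code{c(lo, hi)} sampled uniformly.
#' @param base_log_mean,base_log_sd Location and scale (log2 units) of
#'   baseline intensities; \code{base_log_sd} is also the within-metabolite
#'   residual sd, so t-test power follows the usual normal-theory formula.
#' @param missing_rate Fraction of entries missing, in [0, 1).
#' @param missing_mode \code{"mcar"} (missing completely at random, default)
#'   or \code{"censor"} (left-censored: low-intensity entries are more likely
#'   to be missing, as in real LC-MS data).
#' @param n_classes Number of metabolite class labels to draw from the
#'   controlled vocabulary (max 14).
#' @param direction_ratio Fraction of planted effects that are up (in the
#'   high group); default 0.5 splits evenly.
#' @param seed Integer RNG seed.
#' @return A validated \code{synthetic_metabolome_config}.
#' @export
synthetic_metabolome_config <- function(n_per_group = 6,
                                        n_metabolites = 705,
                                        frac_differential = 222 / 705,
                                        effect_log2 = 2,
                                        base_log_mean = 20,
                                        base_log_sd = 1.5,
                                        missing_rate = 0.1,
                                        missing_mode = c("mcar", "censor"),
                                        n_classes = 13,
                                        direction_ratio = 0.5,
                                        seed = 1) {
  check_scalar_number(n_per_group, "n_per_group", lower = 3, integerish = TRUE)
  check_scalar_number(n_metabolites, "n_metabolites", lower = 2,
                      integerish = TRUE)
  check_scalar_number(frac_differential, "frac_differential", 0, 1)
  if (!is.numeric(effect_log2) || !length(effect_log2) %in% 1:2 ||
      any(!is.finite(effect_log2)) || any(effect_log2 < 0)) {
    abort_field("effect_log2", "must be a nonnegative value or range c(lo, hi)")
  }
  check_scalar_number(base_log_mean, "base_log_mean")
  check_scalar_number(base_log_sd, "base_log_sd", lower = 0)
  check_scalar_number(missing_rate, "missing_rate", 0, 1, strict_upper = TRUE)
  check_scalar_number(n_classes, "n_classes", lower = 1,
                      upper = length(metabolite_class_vocabulary()),
                      integerish = TRUE)
  check_scalar_number(direction_ratio, "direction_ratio", 0, 1)
  check_scalar_number(seed, "seed", integerish = TRUE)
  structure(
    list(n_per_group = as.integer(n_per_group),
         n_metabolites = as.integer(n_metabolites),
         frac_differential = frac_differential,
         effect_log2 = effect_log2,
         base_log_mean = base_log_mean, base_log_sd = base_log_sd,
         missing_rate = missing_rate,
         missing_mode = match.arg(missing_mode),
         n_classes = as.integer(n_classes),
         direction_ratio = direction_ratio,
         seed = as.integer(seed)),
    class = "synthetic_metabolome_config"
  )
}

#' Generate a synthetic intensity matrix with known ground truth
#'
#' Log2 intensities are \code{base_log_mean + b_j + delta_j * I(high) + e_ij}
#' with metabolite baselines \code{b_j ~ N(0, base_log_sd)}, residuals
#' \code{e_ij ~ N(0, base_log_sd)}, and signed planted effects
#' \code{delta_j} on the chosen differential metabolites (so the high-vs-low
#' log2 mean difference of a differential metabolite equals its planted
#' effect). Intensities are \code{2^log2} and entries are deleted per the
#' configured missingness model.
#'
#' @param config A \code{synthetic_metabolome_config}.
#' @return A list with \code{matrix} (an \code{\link{intensity_matrix}}) and
#'   \code{truth} (a \code{synthetic_truth} with \code{differential_ids} and
#'   signed \code{effects_log2}).
#' @export
generate_intensity_matrix <- function(config) {
  stopifnot(inherits(config, "synthetic_metabolome_config"))
  n <- config$n_per_group; p <- config$n_metabolites
  with_seed(config$seed, {
    met_ids <- sprintf("M%04d", seq_len(p))
    sample_ids <- c(paste0("Low", seq_len(n)), paste0("High", seq_len(n)))
    groups <- rep(c("low", "high"), each = n)

    n_diff <- round(config$frac_differential * p)
    diff_idx <- sort(sample.int(p, n_diff))
    mag <- if (length(config$effect_log2) == 1L) {
      rep(config$effect_log2, n_diff)
    } else {
      stats::runif(n_diff, config$effect_log2[1], config$effect_log2[2])
    }
    n_up <- round(config$direction_ratio * n_diff)
    signs <- rep(-1, n_diff)
    if (n_diff > 0) signs[sample.int(n_diff, n_up)] <- 1
    delta <- numeric(p)
    delta[diff_idx] <- signs * mag

    baseline <- config$base_log_mean +
      stats::rnorm(p, 0, config$base_log_sd)
    log2x <- matrix(stats::rnorm(2 * n * p, 0, config$base_log_sd),
                    nrow = 2 * n)
    log2x <- sweep(log2x, 2, baseline, `+`)
    log2x[groups == "high", ] <-
      sweep(log2x[groups == "high", , drop = FALSE], 2, delta, `+`)

    values <- 2^log2x
    if (config$missing_rate > 0) {
      n_entries <- length(values)
      if (config$missing_mode == "mcar") {
        miss <- stats::runif(n_entries) < config$missing_rate
      } else {
        # left-censoring: missingness probability decreases with the
        # intensity's rank, averaging missing_rate over the matrix
        rk <- rank(values, ties.method = "first") / (n_entries + 1)
        miss <- stats::runif(n_entries) <
          pmin(1, 2 * config$missing_rate * (1 - rk))
      }
      values[miss] <- NA_real_
    }

    classes <- sample(metabolite_class_vocabulary()[seq_len(config$n_classes)],
                      p, replace = TRUE)
    mat <- intensity_matrix(values, group_labels = groups,
                            sample_ids = sample_ids,
                            metabolite_ids = met_ids,
                            class_labels = classes)
    truth <- structure(
      list(differential_ids = met_ids[diff_idx],
           effects_log2 = stats::setNames(delta[diff_idx], met_ids[diff_idx])),
      class = "synthetic_truth"
    )
    list(matrix = mat, truth = truth)
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d differential metabolites (%d up, %d down)\n",
              length(x$differential_ids),
              sum(x$effects_log2 > 0), sum(x$effects_log2 < 0)))
  invisible(x)
}
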