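## OPLS-DA: orthogonal projections to latent structures, discriminant
## version for two classes (Trygg & Wold style). Variation in X orthogonal
## to the class response is stripped component by component, then a single
## predictive PLS component is fit on the filtered matrix. Q2 comes from
## stratified k-fold cross-validation in which the whole filter + fit is
## re-estimated inside each training fold.

encode_response <- function(group_labels, positive_class = NULL) {
  levels <- sort(unique(group_labels))
  if (length(levels) != 2L) {
    stop("OPLS-DA requires exactly two groups", call. = FALSE)
  }
  pos <- positive_class %||% (if ("high" %in% levels) "high" else levels[2])
  if (!pos %in% levels) {
    stop(sprintf("positive_class '%s' is not a group label", pos),
         call. = FALSE)
  }
  ifelse(group_labels == pos, 1, -1)
}

## Core fit on an already-scaled X and centered y. Returns everything needed
## to predict new (scaled) samples.
opls_core <- function(xs, yc, n_orth) {
  p <- ncol(xs)
  w_orth <- p_orth <- matrix(0, p, 0)
  t_orth <- matrix(0, nrow(xs), 0)
  xf <- xs
  for (a in seq_len(n_orth)) {
    w <- drop(crossprod(xf, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_ <- drop(xf %*% w)
    p_ <- drop(crossprod(xf, t_)) / sum(t_^2)
    wo <- p_ - sum(w * p_) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-10) break  # no y-orthogonal structure left
    wo <- wo / nwo
    to <- drop(xf %*% wo)
    po <- drop(crossprod(xf, to)) / sum(to^2)
    xf <- xf - tcrossprod(to, po)
    w_orth <- cbind(w_orth, wo)
    p_orth <- cbind(p_orth, po)
    t_orth <- cbind(t_orth, to)
  }
  w <- drop(crossprod(xf, yc))
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) {
    stop("X carries no covariance with the response; cannot fit OPLS-DA",
         call. = FALSE)
  }
  w <- w / nw
  t_p <- drop(xf %*% w)
  p_load <- drop(crossprod(xf, t_p)) / sum(t_p^2)
  q <- sum(yc * t_p) / sum(t_p^2)
  list(w = w, t_p = t_p, p_load = p_load, q = q,
       w_orth = w_orth, p_orth = p_orth, t_orth = t_orth, x_filtered = xf)
}

opls_predict_scores <- function(core, xs_new) {
  xf <- xs_new
  if (ncol(core$w_orth) > 0) {
    for (a in seq_len(ncol(core$w_orth))) {
      to <- drop(xf %*% core$w_orth[, a])
      xf <- xf - tcrossprod(to, core$p_orth[, a])
    }
  }
  drop(xf %*% core$w)
}

stratified_folds <- function(group_labels, k, seed) {
  folds <- integer(length(group_labels))
  with_seed(seed, {
    for (g in unique(group_labels)) {
      idx <- sample(which(group_labels == g))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

## Full fit from a raw (already log-transformed) numeric matrix; shared by
## fit_oplsda, the CV loop and the permutation test.
oplsda_fit_xy <- function(x, group_labels, n_orth, scaling, cv_folds,
                          cv_seed, positive_class = NULL) {
  y <- encode_response(group_labels, positive_class)
  yc <- y - mean(y)
  sc <- scale_columns(x, scaling)
  core <- opls_core(sc$x, yc, n_orth)

  ss_tot_y <- sum(yc^2)
  r2y <- 1 - sum((yc - core$t_p * core$q)^2) / ss_tot_y
  ssx <- sum(sc$x^2)
  ssx_pred <- sum(core$t_p^2) * sum(core$p_load^2)
  ssx_orth <- if (ncol(core$t_orth) > 0) {
    sum(vapply(seq_len(ncol(core$t_orth)), function(a) {
      sum(core$t_orth[, a]^2) * sum(core$p_orth[, a]^2)
    }, numeric(1)))
  } else 0
  r2x <- (ssx_pred + ssx_orth) / ssx

  # cross-validated Q2: the scaling, orthogonal filter and PLS fit are all
  # re-estimated inside each training fold
  folds <- stratified_folds(group_labels, cv_folds, cv_seed)
  press <- 0
  for (f in sort(unique(folds))) {
    tr <- folds != f
    sc_tr <- scale_columns(x[tr, , drop = FALSE], scaling)
    y_tr <- y[tr]
    core_tr <- opls_core(sc_tr$x, y_tr - mean(y_tr), n_orth)
    xs_te <- apply_scaling(x[!tr, , drop = FALSE], sc_tr)
    yhat <- opls_predict_scores(core_tr, xs_te) * core_tr$q + mean(y_tr)
    press <- press + sum((y[!tr] - yhat)^2)
  }
  q2 <- 1 - press / ss_tot_y

  list(core = core, scaling_spec = sc, y = y, y_mean = mean(y),
       R2X = r2x, R2Y = r2y, Q2 = q2, folds = folds)
}

#' Fit a two-class OPLS-DA model
#'
#' The class response is encoded +1/-1 (+1 for \code{positive_class},
#' defaulting to \code{"high"}) and centered. \code{n_orth} orthogonal
#' components are removed from unit-variance-scaled (default) log2
#' intensities, then one predictive PLS component is fit. \code{R2Y} is the
#' fraction of response variance explained on the training data and
#' \code{Q2} the cross-validated predictive fraction
#' (\code{1 - PRESS / SS_tot}) from seeded, group-stratified k-fold CV.
#'
#' @param matrix A complete two-group \code{\link{intensity_matrix}}.
#' @param n_orth Number of orthogonal components (default 1, the standard
#'   choice for two-class models); must be < n_samples - 2.
#' @param scaling \code{"uv"}, \code{"pareto"} or \code{"none"}.
#' @param cv_folds Cross-validation folds (default 7).
#' @param cv_seed Seed for the fold assignment.
#' @param log2_transform Model \code{log2(x + 1)} intensities (default).
#' @param positive_class Group encoded +1.
#' @return An \code{oplsda_model} with predictive scores \code{t_p},
#'   weights, loadings, orthogonal score/loading matrices, \code{R2X},
#'   \code{R2Y}, \code{Q2} and the scaling specification.
#' @export
fit_oplsda <- function(matrix, n_orth = 1,
                       scaling = c("uv", "pareto", "none"), cv_folds = 7,
                       cv_seed = 1, log2_transform = TRUE,
                       positive_class = NULL) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  if (anyNA(matrix$values)) {
    stop("matrix has missing values; impute_missing() first", call. = FALSE)
  }
  scaling <- match.arg(scaling)
  n <- nrow(matrix$values)
  check_scalar_number(n_orth, "n_orth", lower = 0, upper = n - 3,
                      integerish = TRUE)
  check_scalar_number(cv_folds, "cv_folds", lower = 2, upper = n,
                      integerish = TRUE)
  x <- matrix$values
  if (log2_transform) x <- log2(x + 1)
  fit <- oplsda_fit_xy(x, matrix$group_labels, n_orth, scaling, cv_folds,
                       cv_seed, positive_class)
  structure(
    list(t_p = stats::setNames(fit$core$t_p, matrix$sample_ids),
         weights = stats::setNames(fit$core$w, matrix$metabolite_ids),
         loadings = stats::setNames(fit$core$p_load, matrix$metabolite_ids),
         q = fit$core$q,
         orth_scores = fit$core$t_orth, orth_weights = fit$core$w_orth,
         orth_loadings = fit$core$p_orth,
         n_orth = ncol(fit$core$t_orth),
         R2X = fit$R2X, R2Y = fit$R2Y, Q2 = fit$Q2,
         scaling = scaling, y = fit$y, y_mean = fit$y_mean,
         cv_folds = cv_folds, cv_seed = cv_seed,
         log2_transform = log2_transform,
         group_labels = matrix$group_labels,
         metabolite_ids = matrix$metabolite_ids),
    class = "oplsda_model"
  )
}

#' @export
print.oplsda_model <- function(x, ...) {
  cat(sprintf(
    "oplsda_model: 1 predictive + %d orthogonal component(s)\n", x$n_orth))
  cat(sprintf("  R2X = %.3f, R2Y = %.3f, Q2 = %.3f (%d-fold CV)\n",
              x$R2X, x$R2Y, x$Q2, x$cv_folds))
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' For the predictive component(s), \code{VIP_j = sqrt(p * sum_a SSY_a *
#' (w_ja / ||w_a||)^2 / sum_a SSY_a)} with \code{p} the number of
#' metabolites and \code{SSY_a} the response variance explained by
#' component a. With one predictive component this reduces to
#' \code{sqrt(p) * |w_j|}, and \code{mean(VIP^2) = 1} exactly, making
#' VIP > 1 an above-average-importance cut.
#'
#' @param model A fitted \code{\link{fit_oplsda}} model.
#' @return Named numeric vector of VIP scores, one per metabolite.
#' @export
compute_vip <- function(model) {
  if (!inherits(model, "oplsda_model")) {
    stop("compute_vip() needs a fitted oplsda_model", call. = FALSE)
  }
  w <- model$weights            # already unit norm
  p <- length(w)
  vip <- sqrt(p * w^2 / sum(w^2))
  stats::setNames(vip, model$metabolite_ids)
}

#' Permutation test of OPLS-DA model validity
#'
#' Group labels are randomly permuted \code{n_permutations} times and the
#' full model — orthogonal filtering, predictive fit and cross-validated Q2
#' — is refit on each permutation. Empirical p-values use the add-one
#' correction \code{(1 + #(perm >= observed)) / (n_permutations + 1)}, which
#' is valid (conservative) under the null.
#'
#' @inheritParams fit_oplsda
#' @param n_permutations Number of label permutations (default 200; a
#'   warning is recorded below 20, where p-value resolution is poor).
#' @param seed Seed for the permutation stream.
#' @return A \code{permutation_result} with the observed and permuted
#'   \code{R2Y} / \code{Q2} values and their empirical p-values.
#' @export
permutation_test <- function(matrix, n_orth = 1,
                             scaling = c("uv", "pareto", "none"),
                             cv_folds = 7, cv_seed = 1, n_permutations = 200,
                             seed = 1, log2_transform = TRUE) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  scaling <- match.arg(scaling)
  check_scalar_number(n_permutations, "n_permutations", lower = 1,
                      integerish = TRUE)
  if (n_permutations < 20) {
    warning("n_permutations < 20: empirical p-value resolution is poor")
  }
  x <- matrix$values
  if (log2_transform) x <- log2(x + 1)
  observed <- oplsda_fit_xy(x, matrix$group_labels, n_orth, scaling,
                            cv_folds, cv_seed)
  perm_r2y <- perm_q2 <- numeric(n_permutations)
  with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      labels_b <- sample(matrix$group_labels)
      fit_b <- oplsda_fit_xy(x, labels_b, n_orth, scaling, cv_folds, cv_seed)
      perm_r2y[b] <- fit_b$R2Y
      perm_q2[b] <- fit_b$Q2
    }
  })
  structure(
    list(n_permutations = n_permutations,
         observed_R2Y = observed$R2Y, observed_Q2 = observed$Q2,
         permuted_R2Y = perm_r2y, permuted_Q2 = perm_q2,
         p_R2Y = (1 + sum(perm_r2y >= observed$R2Y)) / (n_permutations + 1),
         p_Q2 = (1 + sum(perm_q2 >= observed$Q2)) / (n_permutations + 1),
         seed = seed),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation_result (%d permutations):\n", x$n_permutations))
  cat(sprintf("  R2Y = %.3f (p = %.4g), Q2 = %.3f (p = %.4g)\n",
              x$observed_R2Y, x$p_R2Y, x$observed_Q2, x$p_Q2))
  invisible(x)
}
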