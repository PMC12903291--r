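## Assembly and solution of the pseudo-steady-state flux system.
##
## Equations: one homogeneous mass balance per internal_pss metabolite
## (S_row . r = 0), one anchor pinning the reference reaction to the scale
## (r_ref = 100), and one boundary equation per measured non-reference
## metabolite pinning its net production rate via the concentration->rate
## proxy: S_row . r = sign * scale * C_m / C_ref. Only concentration RATIOS
## against the reference metabolite enter, so multiplying every measured
## concentration by a constant leaves the system unchanged.

reference_metabolite <- function(network) {
  ref_rx <- network$reactions[[network$reference_reaction_id]]
  roles <- node_roles(network)
  subs <- vapply(ref_rx$substrates, `[[`, character(1), "metabolite")
  cand <- subs[roles[subs] == "boundary_measured"]
  if (length(cand) == 0L) {
    stop("reference reaction has no boundary_measured substrate",
         call. = FALSE)
  }
  cand[1]
}

#' Assemble the linear flux-balance system
#'
#' @param S Stoichiometric matrix from \code{\link{build_stoich_matrix}}.
#' @param network The \code{network_model}.
#' @param measurements Named concentration vector (µmol/mL) covering every
#'   boundary_measured metabolite.
#' @param scale Anchor value for the reference reaction (default 100).
#' @return A \code{flux_system}: matrix \code{A}, right-hand side \code{b},
#'   row labels, reaction ids and bookkeeping.
#' @export
assemble_balance_system <- function(S, network, measurements, scale = 100) {
  stopifnot(inherits(network, "network_model"))
  roles <- node_roles(network)
  boundary <- names(roles)[roles == "boundary_measured"]
  internal <- names(roles)[roles == "internal_pss"]
  missing_m <- setdiff(boundary, names(measurements))
  if (length(missing_m)) {
    stop(sprintf("missing measurement for boundary metabolite(s): %s",
                 paste(missing_m, collapse = ", ")), call. = FALSE)
  }
  if (any(!is.finite(measurements[boundary]) | measurements[boundary] <= 0)) {
    abort_field("measurements", "boundary concentrations must be > 0")
  }
  ref_met <- reference_metabolite(network)
  c_ref <- measurements[[ref_met]]
  if (c_ref <= 0) stop("zero reference concentration", call. = FALSE)

  rids <- names(network$reactions)
  rows <- list(); rhs <- c(); labels <- c()
  for (m in internal) {
    rows[[length(rows) + 1L]] <- S[m, ]
    rhs <- c(rhs, 0)
    labels <- c(labels, paste0("balance:", m))
  }
  anchor <- stats::setNames(numeric(length(rids)), rids)
  anchor[network$reference_reaction_id] <- 1
  rows[[length(rows) + 1L]] <- anchor
  rhs <- c(rhs, scale)
  labels <- c(labels, paste0("anchor:", network$reference_reaction_id))
  for (m in setdiff(boundary, ref_met)) {
    rows[[length(rows) + 1L]] <- S[m, ]
    rhs <- c(rhs, boundary_sign(network, m) * scale *
               measurements[[m]] / c_ref)
    labels <- c(labels, paste0("boundary:", m))
  }
  A <- do.call(rbind, rows)
  dimnames(A) <- list(labels, rids)
  structure(
    list(A = A, b = stats::setNames(rhs, labels), reaction_ids = rids,
         network = network, scale = scale, reference_metabolite = ref_met),
    class = "flux_system"
  )
}

## SVD-based minimum-norm least squares with tolerance-truncated rank.
svd_lstsq <- function(A, b, rtol = 1e-10) {
  sv <- svd(A)
  rank <- sum(sv$d > rtol * sv$d[1])
  if (rank == 0L) stop("flux system has rank 0", call. = FALSE)
  dinv <- c(1 / sv$d[seq_len(rank)], rep(0, length(sv$d) - rank))
  x <- sv$v %*% (dinv * crossprod(sv$u, b))
  list(x = drop(x), rank = rank)
}

#' Solve the flux-balance system
#'
#' Determined consistent systems are solved exactly; otherwise the
#' minimum-norm least-squares solution is returned (deterministic and
#' basis-independent). With \code{nonnegative = TRUE}, fluxes of
#' irreversible reactions are constrained >= 0 (reversible ones are split
#' into forward/backward parts and recombined) via nonnegative least
#' squares; if the constraints make the balances unattainable the violated
#' equations are reported as an error.
#'
#' @param system A \code{\link{assemble_balance_system}} result.
#' @param nonnegative Enforce flux >= 0 on irreversible reactions.
#' @param tolerance Relative tolerance for rank truncation and consistency
#'   checks (default 1e-8, applied relative to the anchor scale).
#' @return An unnormalized \code{flux_solution} with per-reaction fluxes,
#'   internal-balance \code{residual_norm}, and system diagnostics (rank,
#'   equation/unknown counts, determinacy class).
#' @export
solve_fluxes <- function(system, nonnegative = FALSE, tolerance = 1e-8) {
  stopifnot(inherits(system, "flux_system"))
  A <- system$A; b <- system$b
  rids <- system$reaction_ids
  if (nonnegative) {
    rev <- vapply(system$network$reactions, `[[`, logical(1), "reversible")
    # split reversible fluxes r = r+ - r- so every variable is nonnegative
    A2 <- cbind(A, -A[, rev, drop = FALSE])
    fit <- pracma::lsqnonneg(A2, unname(b))
    x <- fit$x[seq_along(rids)]
    if (any(rev)) x[rev] <- x[rev] - fit$x[-seq_along(rids)]
    fluxes <- stats::setNames(x, rids)
    rank <- qr(A)$rank
    resid <- drop(A %*% fluxes - b)
    bad <- abs(resid) > 100 * tolerance * system$scale
    # only fail when the unconstrained solution could do better: then the
    # nonnegativity constraints themselves are what is violated
    unc <- svd_lstsq(A, b, rtol = tolerance)
    resid_unc <- drop(A %*% unc$x - b)
    if (any(bad) && sqrt(sum(resid^2)) >
        sqrt(sum(resid_unc^2)) + 100 * tolerance * system$scale) {
      stop(sprintf("nonnegative flux system infeasible; violated: %s",
                   paste(names(b)[bad], collapse = ", ")), call. = FALSE)
    }
  } else {
    fit <- svd_lstsq(A, b, rtol = tolerance)
    fluxes <- stats::setNames(fit$x, rids)
    rank <- fit$rank
    resid <- drop(A %*% fluxes - b)
  }
  internal_rows <- grepl("^balance:", names(b))
  residual_norm <- sqrt(sum(resid[internal_rows]^2))
  total_residual <- sqrt(sum(resid^2))
  determinacy <- if (rank < length(rids)) {
    "underdetermined"
  } else if (total_residual <= tolerance * system$scale *
             max(1, sqrt(length(b)))) {
    "determined"
  } else {
    "overdetermined"
  }
  new_flux_solution(fluxes, system, residual_norm, total_residual, rank,
                    determinacy, normalized = FALSE)
}

new_flux_solution <- function(fluxes, system, residual_norm, total_residual,
                              rank, determinacy, normalized) {
  structure(
    list(fluxes = fluxes,
         residual_norm = residual_norm,
         total_residual = total_residual,
         rank = rank,
         n_equations = nrow(system$A),
         n_unknowns = length(fluxes),
         determinacy = determinacy,
         normalized = normalized,
         reference_reaction_id = system$network$reference_reaction_id,
         scale = system$scale,
         pathways = vapply(system$network$reactions, `[[`, character(1),
                           "pathway")),
    class = "flux_solution"
  )
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("flux_solution (%s, %s; residual %.3g):\n",
              x$determinacy, if (x$normalized) "normalized" else "raw",
              x$residual_norm))
  print(round(x$fluxes, 3))
  invisible(x)
}

#' Normalize a flux solution to the reference reaction
#'
#' Every flux is multiplied by \code{scale / flux(reference)} so the
#' reference (glucose-uptake) reaction equals exactly \code{scale}
#' (default 100), enabling cross-pathway and cross-group comparison.
#' Idempotent on already-normalized solutions.
#'
#' @param solution A \code{flux_solution}.
#' @param reference_reaction_id Reference reaction (defaults to the one
#'   recorded in the solution).
#' @param scale Normalization target (default 100).
#' @return The normalized \code{flux_solution}.
#' @export
normalize_fluxes <- function(solution, reference_reaction_id = NULL,
                             scale = 100) {
  stopifnot(inherits(solution, "flux_solution"))
  ref <- reference_reaction_id %||% solution$reference_reaction_id
  ref_flux <- solution$fluxes[[ref]]
  if (!is.finite(ref_flux) || ref_flux == 0) {
    stop(sprintf("reference reaction %s has zero flux; cannot normalize",
                 ref), call. = FALSE)
  }
  factor <- scale / ref_flux
  solution$fluxes <- solution$fluxes * factor
  solution$fluxes[[ref]] <- scale  # exact by construction
  solution$residual_norm <- solution$residual_norm * abs(factor)
  solution$total_residual <- solution$total_residual * abs(factor)
  solution$normalized <- TRUE
  solution$reference_reaction_id <- ref
  solution$scale <- scale
  solution
}

#' Write a flux table TSV (reaction, pathway, flux, normalized flux)
#'
#' @param solution A solved \code{flux_solution}.
#' @param path Destination TSV.
#' @param raw_solution Optional unnormalized solution to include as a
#'   \code{raw_flux} column.
#' @return The path, invisibly.
#' @export
write_flux_table <- function(solution, path, raw_solution = NULL) {
  df <- data.frame(reaction = names(solution$fluxes),
                   pathway = unname(solution$pathways[names(solution$fluxes)]),
                   flux = unname(solution$fluxes),
                   stringsAsFactors = FALSE)
  if (!is.null(raw_solution)) {
    df$raw_flux <- unname(raw_solution$fluxes[df$reaction])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
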