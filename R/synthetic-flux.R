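## Synthetic flux scenarios: a ground-truth flux vector satisfying every
## internal pseudo-steady-state balance exactly, plus the boundary
## concentrations that the concentration->rate proxy rule would have
## produced it from (optionally with multiplicative noise). Solving the
## emitted measurements must round-trip back to the truth at noise 0.

#' Generate a flux scenario with known ground truth
#'
#' Truth fluxes are drawn from the null space of the internal-balance rows
#' of the stoichiometric matrix (so every pseudo-steady-state balance holds
#' exactly), rejected until all irreversible fluxes are strictly positive,
#' and scaled so the reference reaction equals \code{scale}. Boundary
#' concentrations are then computed by inverting the proxy rule
#' \code{C_m = |net rate_m| / scale * C_ref}, with lognormal multiplicative
#' noise of scale \code{noise_frac}.
#'
#' @param network A \code{network_model}.
#' @param seed Integer RNG seed.
#' @param noise_frac Multiplicative noise scale (sd of log-concentration);
#'   0 gives exact round-trip recovery.
#' @param c_ref Concentration assigned to the reference metabolite
#'   (µmol/mL; default 5, a plausible plasma glucose level).
#' @param scale Normalization scale (default 100).
#' @return A list with \code{truth} (a normalized \code{flux_solution}) and
#'   \code{measurements} (named concentration vector over the
#'   boundary-measured metabolites).
#' @export
generate_flux_scenario <- function(network, seed = 1, noise_frac = 0,
                                   c_ref = 5, scale = 100) {
  stopifnot(inherits(network, "network_model"))
  check_scalar_number(noise_frac, "noise_frac", lower = 0)
  check_scalar_number(c_ref, "c_ref", lower = 0)
  roles <- node_roles(network)
  boundary <- names(roles)[roles == "boundary_measured"]
  if (length(boundary) == 0L) {
    stop("network has no boundary_measured metabolite", call. = FALSE)
  }
  S <- build_stoich_matrix(network)
  internal <- names(roles)[roles == "internal_pss"]
  S_int <- S[internal, , drop = FALSE]
  rids <- colnames(S)
  ref <- network$reference_reaction_id

  # orthonormal null-space basis of the internal balances
  sv <- svd(S_int, nv = ncol(S_int))
  rank <- sum(sv$d > 1e-10 * max(sv$d, 1))
  if (rank >= ncol(S_int)) {
    stop("internal balances leave no free flux directions", call. = FALSE)
  }
  N <- sv$v[, (rank + 1):ncol(S_int), drop = FALSE]
  irrev <- !vapply(network$reactions, `[[`, logical(1), "reversible")

  with_seed(seed, {
    truth <- NULL
    for (try in seq_len(10000)) {
      r <- drop(N %*% stats::runif(ncol(N), -1, 1))
      if (r[which(rids == ref)] < 0) r <- -r
      if (all(r[irrev] > 0.02 * max(abs(r))) && r[which(rids == ref)] > 0) {
        truth <- r * scale / r[which(rids == ref)]
        rates <- drop(S[boundary, , drop = FALSE] %*% truth)
        if (all(abs(rates) > 1e-6 * scale)) break
        truth <- NULL
      }
    }
    if (is.null(truth)) {
      stop("could not sample a strictly positive flux vector; check the ",
           "network topology", call. = FALSE)
    }
    names(truth) <- rids
    rates <- drop(S[boundary, , drop = FALSE] %*% truth)
    conc <- abs(rates) / scale * c_ref
    names(conc) <- boundary
    if (noise_frac > 0) {
      conc <- conc * exp(stats::rnorm(length(conc), 0, noise_frac))
    }
    resid <- sqrt(sum((S_int %*% truth)^2))
    truth_sol <- structure(
      list(fluxes = truth, residual_norm = resid, total_residual = resid,
           rank = NA_integer_, n_equations = nrow(S_int),
           n_unknowns = length(truth), determinacy = "truth",
           normalized = TRUE, reference_reaction_id = ref, scale = scale,
           pathways = vapply(network$reactions, `[[`, character(1),
                             "pathway")),
      class = "flux_solution")
    list(truth = truth_sol, measurements = conc)
  })
}
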