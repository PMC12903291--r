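## Central-metabolic-pathway (CMP) network model: metabolite nodes with
## roles, stoichiometric reactions, and the signed stoichiometric matrix.
##
## Roles:
##   boundary_measured — plasma concentration is available and anchors a
##                       non-homogeneous constraint (glucose, lactate,
##                       beta-HB, NADH in the default network);
##   internal_pss      — intermediate assumed at pseudo-steady state, so its
##                       mass-balance row is a homogeneous constraint;
##   sink_unmeasured   — terminal pool with no measurement and no balance
##                       constraint (e.g. TCA end products).

valid_roles <- c("boundary_measured", "internal_pss", "sink_unmeasured")
valid_pathways <- c("glycolysis", "pentose_phosphate", "TCA", "ketogenesis",
                    "fermentation", "other")

new_network_model <- function(nodes, reactions, reference_reaction_id = "r1") {
  ids <- vapply(nodes, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate metabolite id", call. = FALSE)
  rids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(rids)) {
    stop(sprintf("duplicate reaction id: %s",
                 paste(rids[duplicated(rids)], collapse = ", ")),
         call. = FALSE)
  }
  roles <- vapply(nodes, `[[`, character(1), "role")
  if (!all(roles %in% valid_roles)) {
    stop("metabolite role must be one of: ",
         paste(valid_roles, collapse = ", "), call. = FALSE)
  }
  for (rx in reactions) {
    if (length(rx$substrates) < 1L || length(rx$products) < 1L) {
      stop(sprintf("reaction %s needs >= 1 substrate and >= 1 product",
                   rx$id), call. = FALSE)
    }
    for (side in c("substrates", "products")) {
      for (term in rx[[side]]) {
        if (!term$metabolite %in% ids) {
          stop(sprintf("reaction %s references undeclared metabolite '%s'",
                       rx$id, term$metabolite), call. = FALSE)
        }
        if (!is.numeric(term$coeff) || term$coeff <= 0) {
          stop(sprintf("reaction %s has a nonpositive coefficient", rx$id),
               call. = FALSE)
        }
      }
    }
    if (!rx$pathway %in% valid_pathways) {
      stop(sprintf("reaction %s: unknown pathway tag '%s'", rx$id,
                   rx$pathway), call. = FALSE)
    }
  }
  if (!reference_reaction_id %in% rids) {
    stop(sprintf("reference reaction '%s' is not in the network",
                 reference_reaction_id), call. = FALSE)
  }
  if (!any(roles == "boundary_measured")) {
    stop("network has no boundary_measured metabolite", call. = FALSE)
  }
  names(nodes) <- ids
  names(reactions) <- rids
  structure(
    list(nodes = nodes, reactions = reactions,
         reference_reaction_id = reference_reaction_id),
    class = "network_model"
  )
}

#' @export
print.network_model <- function(x, ...) {
  roles <- vapply(x$nodes, `[[`, character(1), "role")
  cat(sprintf("network_model: %d metabolites, %d reactions (reference %s)\n",
              length(x$nodes), length(x$reactions),
              x$reference_reaction_id))
  cat(sprintf(
    "  roles: %d boundary_measured, %d internal_pss, %d sink_unmeasured\n",
    sum(roles == "boundary_measured"), sum(roles == "internal_pss"),
    sum(roles == "sink_unmeasured")))
  invisible(x)
}

node_roles <- function(network) {
  vapply(network$nodes, `[[`, character(1), "role")
}

## Boundary sign of a measured node: +1 for a net-produced output, -1 for a
## consumed input. An explicit "sign" field in the network file wins;
## otherwise a node appearing only as substrate is an input (-1), only as
## product an output (+1), and a node on both sides (NADH) defaults to a
## net-accumulation output (+1).
boundary_sign <- function(network, metabolite) {
  node <- network$nodes[[metabolite]]
  if (!is.null(node$sign)) return(sign(node$sign))
  as_sub <- as_prod <- FALSE
  for (rx in network$reactions) {
    subs <- vapply(rx$substrates, `[[`, character(1), "metabolite")
    prods <- vapply(rx$products, `[[`, character(1), "metabolite")
    if (metabolite %in% subs) as_sub <- TRUE
    if (metabolite %in% prods) as_prod <- TRUE
  }
  if (as_sub && !as_prod) -1 else 1
}

parse_stoich_string <- function(s) {
  # "2*A + B" -> list(list(metabolite="A", coeff=2), ...)
  terms <- strsplit(s, "\\+")[[1]]
  lapply(trimws(terms), function(tm) {
    if (grepl("\\*", tm)) {
      parts <- trimws(strsplit(tm, "\\*")[[1]])
      list(metabolite = parts[2], coeff = as.numeric(parts[1]))
    } else {
      list(metabolite = tm, coeff = 1)
    }
  })
}

#' Parse a metabolic network definition file
#'
#' JSON layout: \code{metabolites: [{id, name, role, sign?}]} and
#' \code{reactions: [{id, substrates: [[id, coeff], ...], products: ...,
#' pathway, reversible}]}. A TSV alternative has one reaction per line
#' (columns \code{id}, \code{substrates}, \code{products}, \code{pathway},
#' \code{reversible}; stoichiometry written \code{"2*A+B"}) and takes node
#' roles from a sidecar \code{<path>.metabolites.tsv} with columns
#' \code{id}, \code{name}, \code{role} and optional \code{sign}.
#'
#' @param path Network file (.json or .tsv).
#' @param reference_reaction_id Reaction whose flux anchors the
#'   normalization (default \code{"r1"}).
#' @return A validated \code{network_model}.
#' @export
parse_network <- function(path, reference_reaction_id = "r1") {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    spec <- jsonlite::read_json(path)
    nodes <- lapply(spec$metabolites, function(m) {
      list(id = m$id, name = m$name %||% m$id, role = m$role,
           sign = m$sign)
    })
    reactions <- lapply(spec$reactions, function(r) {
      list(id = r$id,
           substrates = lapply(r$substrates, function(t) {
             list(metabolite = t[[1]], coeff = as.numeric(t[[2]]))
           }),
           products = lapply(r$products, function(t) {
             list(metabolite = t[[1]], coeff = as.numeric(t[[2]]))
           }),
           pathway = r$pathway %||% "other",
           reversible = isTRUE(r$reversible))
    })
  } else {
    rx_df <- utils::read.table(path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
    met_path <- paste0(path, ".metabolites.tsv")
    if (!file.exists(met_path)) {
      stop(sprintf("TSV network needs a role sidecar: %s", met_path),
           call. = FALSE)
    }
    met_df <- utils::read.table(met_path, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
    nodes <- lapply(seq_len(nrow(met_df)), function(i) {
      list(id = met_df$id[i],
           name = if ("name" %in% names(met_df)) met_df$name[i] else
             met_df$id[i],
           role = met_df$role[i],
           sign = if ("sign" %in% names(met_df)) met_df$sign[i] else NULL)
    })
    reactions <- lapply(seq_len(nrow(rx_df)), function(i) {
      list(id = rx_df$id[i],
           substrates = parse_stoich_string(rx_df$substrates[i]),
           products = parse_stoich_string(rx_df$products[i]),
           pathway = rx_df$pathway[i],
           reversible = isTRUE(as.logical(rx_df$reversible[i])))
    })
  }
  new_network_model(nodes, reactions, reference_reaction_id)
}

#' Load the packaged default CMP network
#'
#' Ten irreversible reactions spanning glycolysis (glucose -> G6P -> F6P ->
#' GAP -> PEP -> pyruvate), a G6P pentose-phosphate branch, lactate
#' fermentation (consuming NADH), the pyruvate-dehydrogenase link, TCA
#' oxidation (producing NADH) and ketogenesis to beta-hydroxybutyrate. Six
#' intermediates (G6P, F6P, GAP, PEP, pyruvate, acetyl-CoA) are
#' pseudo-steady-state nodes; glucose, lactate, beta-HB and NADH are
#' boundary-measured. The network is a plain JSON data file
#' (\code{inst/extdata/cmp_network.json}) and can be replaced by any file in
#' the same layout without code changes.
#'
#' @return A \code{network_model}.
#' @export
default_cmp_network <- function() {
  parse_network(system.file("extdata", "cmp_network.json",
                            package = "cmpflux", mustWork = TRUE))
}

#' Build the signed stoichiometric matrix
#'
#' Entry (m, r) is total product coefficient minus total substrate
#' coefficient of metabolite m in reaction r (consumption negative,
#' production positive); \code{S \%*\% r} gives net production rates. Rows
#' and columns follow declaration order.
#'
#' @param network A \code{network_model}.
#' @return Numeric matrix, metabolites x reactions.
#' @export
build_stoich_matrix <- function(network) {
  stopifnot(inherits(network, "network_model"))
  mets <- names(network$nodes)
  rids <- names(network$reactions)
  S <- matrix(0, length(mets), length(rids), dimnames = list(mets, rids))
  for (rx in network$reactions) {
    for (term in rx$substrates) {
      S[term$metabolite, rx$id] <- S[term$metabolite, rx$id] - term$coeff
    }
    for (term in rx$products) {
      S[term$metabolite, rx$id] <- S[term$metabolite, rx$id] + term$coeff
    }
  }
  S
}

#' Read a two-column measurement TSV (metabolite id, concentration)
#'
#' @param path TSV path with columns \code{metabolite} and
#'   \code{concentration} (µmol/mL plasma).
#' @return Named numeric vector of concentrations.
#' @export
read_measurements <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("metabolite", "concentration") %in% names(df))) {
    abort_field("measurements",
                "needs columns 'metabolite' and 'concentration'")
  }
  stats::setNames(df$concentration, df$metabolite)
}
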