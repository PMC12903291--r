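## Workflow orchestration: the three analysis arms (untargeted metabolome,
## quantified panel, flux inference) as functions over a single config list,
## each writing its artifact set plus a run manifest with per-stage output
## checksums and the seed registry. A thin command-line wrapper lives at
## inst/exec/cmpflux.

#' Load a pipeline configuration (YAML or JSON)
#'
#' @param path Config file; extension decides the parser.
#' @return A named list.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

start_manifest <- function(config, seed) {
  list(config = config,
       package_version = as.character(utils::packageVersion("cmpflux")),
       global_seed = seed,
       seeds = list(),
       stages = list())
}

record_stage <- function(manifest, stage, outputs, elapsed) {
  checksums <- as.list(tools::md5sum(outputs))
  manifest$stages[[stage]] <- list(outputs = checksums,
                                   elapsed_sec = round(elapsed, 3))
  manifest
}

finish_manifest <- function(manifest, outdir) {
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

cfg_get <- function(config, key, default) config[[key]] %||% default

#' Run the untargeted-metabolome workflow
#'
#' filter_missing -> impute_missing -> run_pca -> fit_oplsda -> compute_vip
#' -> permutation_test -> select_sdms -> class_summary, writing the SDM /
#' volcano table, the z-scored heatmap matrix, PCA scores, a JSON model
#' report (R2X, R2Y, Q2, permutation p-values) and the run manifest.
#'
#' @param config Named list. Either \code{intensity_tsv} (a file written by
#'   \code{\link{write_intensity_matrix}}) or \code{synthetic} (arguments
#'   for \code{\link{synthetic_metabolome_config}}); optional stage
#'   parameters \code{max_missing_frac}, \code{impute_method},
#'   \code{scaling}, \code{n_orth}, \code{cv_folds}, \code{n_permutations},
#'   \code{vip_threshold}, \code{p_threshold}.
#' @param outdir Output directory (created if needed).
#' @param seed Global seed; per-stage seeds derive from it via
#'   \code{\link{derive_stage_seed}}.
#' @return Invisibly, a list with the main in-memory results and output
#'   paths.
#' @export
run_metabolome_workflow <- function(config = list(), outdir, seed = 1) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- start_manifest(config, seed)
  truth <- NULL
  if (!is.null(config$intensity_tsv)) {
    loaded <- read_intensity_matrix(config$intensity_tsv)
    mat <- loaded$matrix; truth <- loaded$truth
  } else {
    gen_seed <- derive_stage_seed(seed, "simulate_metabolome")
    manifest$seeds$simulate_metabolome <- gen_seed
    syn_args <- config$synthetic %||% list()
    syn_args$seed <- syn_args$seed %||% gen_seed
    cfg <- do.call(synthetic_metabolome_config, syn_args)
    gen <- generate_intensity_matrix(cfg)
    mat <- gen$matrix; truth <- gen$truth
    t0 <- proc.time()[3]
    paths <- write_intensity_matrix(mat, file.path(outdir, "intensity.tsv"),
                                    truth = truth)
    manifest <- record_stage(manifest, "simulate", paths,
                             proc.time()[3] - t0)
  }

  t0 <- proc.time()[3]
  filtered <- filter_missing(mat, cfg_get(config, "max_missing_frac", 0.5))
  complete <- impute_missing(filtered,
                             cfg_get(config, "impute_method", "half_min"))
  pca <- run_pca(complete,
                 n_components = cfg_get(config, "n_components", 2),
                 scaling = cfg_get(config, "scaling", "uv"))
  pca_path <- file.path(outdir, "pca_scores.tsv")
  utils::write.table(
    data.frame(sample_id = rownames(pca$scores), group = pca$group_labels,
               pca$scores, check.names = FALSE),
    pca_path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- record_stage(manifest, "pca", pca_path, proc.time()[3] - t0)

  t0 <- proc.time()[3]
  cv_seed <- derive_stage_seed(seed, "oplsda_cv")
  manifest$seeds$oplsda_cv <- cv_seed
  model <- fit_oplsda(complete,
                      n_orth = cfg_get(config, "n_orth", 1),
                      scaling = cfg_get(config, "scaling", "uv"),
                      cv_folds = cfg_get(config, "cv_folds", 7),
                      cv_seed = cv_seed)
  vip <- compute_vip(model)
  perm_seed <- derive_stage_seed(seed, "permutation")
  manifest$seeds$permutation <- perm_seed
  perm <- permutation_test(complete,
                           n_orth = cfg_get(config, "n_orth", 1),
                           scaling = cfg_get(config, "scaling", "uv"),
                           cv_folds = cfg_get(config, "cv_folds", 7),
                           cv_seed = cv_seed,
                           n_permutations = cfg_get(config, "n_permutations",
                                                    200),
                           seed = perm_seed)
  report_path <- file.path(outdir, "model_report.json")
  jsonlite::write_json(
    list(R2X = model$R2X, R2Y = model$R2Y, Q2 = model$Q2,
         n_orth = model$n_orth, cv_folds = model$cv_folds,
         permutation = list(n = perm$n_permutations, p_R2Y = perm$p_R2Y,
                            p_Q2 = perm$p_Q2)),
    report_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- record_stage(manifest, "oplsda", report_path,
                           proc.time()[3] - t0)

  t0 <- proc.time()[3]
  sdm <- select_sdms(complete, vip,
                     vip_threshold = cfg_get(config, "vip_threshold", 1),
                     p_threshold = cfg_get(config, "p_threshold", 0.05))
  sdm_path <- file.path(outdir, "sdm_table.tsv")
  write_sdm_table(sdm, sdm_path)
  summ <- class_summary(complete, sdm)
  heat_path <- file.path(outdir, "heatmap_z.tsv")
  utils::write.table(
    data.frame(metabolite = rownames(summ$zmatrix), summ$zmatrix,
               check.names = FALSE),
    heat_path, sep = "\t", quote = FALSE, row.names = FALSE)
  counts_path <- file.path(outdir, "class_counts.tsv")
  utils::write.table(summ$counts, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- record_stage(manifest, "sdm",
                           c(sdm_path, heat_path, counts_path),
                           proc.time()[3] - t0)
  finish_manifest(manifest, outdir)
  invisible(list(matrix = complete, truth = truth, pca = pca, model = model,
                 vip = vip, permutation = perm, sdm = sdm,
                 class_summary = summ, outdir = outdir))
}

#' Run the quantified-panel workflow
#'
#' Generates (or reads) the four-metabolite concentration panel and writes
#' the per-metabolite group comparison table (mean +/- SEM, pooled t, df,
#' p, percent change) plus assumption reports.
#'
#' @param config Named list with \code{panel_tsv} or \code{scenario}
#'   (arguments for \code{\link{panel_scenario}}; empty list uses
#'   \code{\link{default_panel_scenario}}); optional \code{var_equal}.
#' @inheritParams run_metabolome_workflow
#' @return Invisibly, the panel, comparison table and assumption reports.
#' @export
run_panel_workflow <- function(config = list(), outdir, seed = 1) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- start_manifest(config, seed)
  if (!is.null(config$panel_tsv)) {
    panel <- read_panel(config$panel_tsv)
  } else {
    gen_seed <- derive_stage_seed(seed, "simulate_panel")
    manifest$seeds$simulate_panel <- gen_seed
    scn <- if (is.null(config$scenario) || length(config$scenario) == 0L) {
      default_panel_scenario(seed = gen_seed)
    } else {
      args <- config$scenario
      args$seed <- args$seed %||% gen_seed
      do.call(panel_scenario, args)
    }
    panel <- generate_panel(scn)
    write_panel(panel, file.path(outdir, "panel.tsv"))
  }
  t0 <- proc.time()[3]
  comparison <- compare_panel(panel,
                              var_equal = cfg_get(config, "var_equal", TRUE))
  cmp_path <- file.path(outdir, "panel_comparison.tsv")
  utils::write.table(comparison, cmp_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  assumptions <- lapply(stats::setNames(nm = unique(panel$metabolite)),
                        function(m) {
    sub <- panel[panel$metabolite == m, ]
    check_assumptions(sub$concentration[sub$group == "low"],
                      sub$concentration[sub$group == "high"])
  })
  assum_path <- file.path(outdir, "assumption_report.json")
  jsonlite::write_json(assumptions, assum_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- record_stage(manifest, "panel", c(cmp_path, assum_path),
                           proc.time()[3] - t0)
  finish_manifest(manifest, outdir)
  invisible(list(panel = panel, comparison = comparison,
                 assumptions = assumptions, outdir = outdir))
}

#' Run the flux-inference workflow
#'
#' parse_network -> build_stoich_matrix -> assemble_balance_system ->
#' solve_fluxes -> normalize_fluxes -> export_flux_graph, writing the flux
#' table, diagnostics JSON, GraphML/DOT graphs and the manifest. With two
#' measurement sets (\code{measurements_low} / \code{measurements_high}) a
#' per-reaction flux comparison table is written as well.
#'
#' @param config Named list: \code{network} (path; default packaged CMP
#'   network), then one of \code{measurements_tsv}, \code{measurements}
#'   (named vector/list), a \code{scenario} block
#'   (\code{list(noise_frac = ...)}) for synthetic input, or the pair
#'   \code{measurements_low} / \code{measurements_high}; optional
#'   \code{nonnegative} (default TRUE) and \code{scale}.
#' @inheritParams run_metabolome_workflow
#' @return Invisibly, solutions, diagnostics and (for scenarios) recovery
#'   error against truth.
#' @export
run_flux_workflow <- function(config = list(), outdir, seed = 1) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- start_manifest(config, seed)
  network <- if (is.null(config$network)) default_cmp_network() else
    parse_network(config$network,
                  cfg_get(config, "reference_reaction_id", "r1"))
  S <- build_stoich_matrix(network)
  scale <- cfg_get(config, "scale", 100)
  nonneg <- cfg_get(config, "nonnegative", TRUE)

  solve_one <- function(meas) {
    system <- assemble_balance_system(S, network, meas, scale = scale)
    raw <- solve_fluxes(system, nonnegative = nonneg)
    list(raw = raw, normalized = normalize_fluxes(raw))
  }

  truth <- NULL; recovery <- NULL
  if (!is.null(config$measurements_low) ||
      !is.null(config$measurements_high)) {
    if (is.null(config$measurements_low) ||
        is.null(config$measurements_high)) {
      stop("both measurements_low and measurements_high are required for a ",
           "two-group comparison", call. = FALSE)
    }
    t0 <- proc.time()[3]
    sol_low <- solve_one(unlist(config$measurements_low))
    sol_high <- solve_one(unlist(config$measurements_high))
    cmp <- data.frame(
      reaction = names(sol_low$normalized$fluxes),
      pathway = unname(sol_low$normalized$pathways),
      flux_low = unname(sol_low$normalized$fluxes),
      flux_high = unname(sol_high$normalized$fluxes),
      stringsAsFactors = FALSE)
    cmp$difference <- cmp$flux_high - cmp$flux_low
    cmp_path <- file.path(outdir, "flux_comparison.tsv")
    utils::write.table(cmp, cmp_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest <- record_stage(manifest, "flux_comparison", cmp_path,
                             proc.time()[3] - t0)
    finish_manifest(manifest, outdir)
    return(invisible(list(low = sol_low$normalized,
                          high = sol_high$normalized,
                          comparison = cmp, outdir = outdir)))
  }

  if (!is.null(config$measurements_tsv)) {
    meas <- read_measurements(config$measurements_tsv)
  } else if (!is.null(config$measurements)) {
    meas <- unlist(config$measurements)
  } else {
    scen_seed <- derive_stage_seed(seed, "flux_scenario")
    manifest$seeds$flux_scenario <- scen_seed
    scen <- generate_flux_scenario(
      network, seed = scen_seed,
      noise_frac = cfg_get(config$scenario, "noise_frac", 0),
      scale = scale)
    meas <- scen$measurements
    truth <- scen$truth
  }

  t0 <- proc.time()[3]
  sol <- solve_one(meas)
  flux_path <- file.path(outdir, "flux_table.tsv")
  write_flux_table(sol$normalized, flux_path, raw_solution = sol$raw)
  diag <- list(residual_norm = sol$normalized$residual_norm,
               total_residual = sol$normalized$total_residual,
               rank = sol$raw$rank,
               n_equations = sol$raw$n_equations,
               n_unknowns = sol$raw$n_unknowns,
               determinacy = sol$raw$determinacy)
  if (!is.null(truth)) {
    rel_err <- abs(sol$normalized$fluxes - truth$fluxes) /
      pmax(abs(truth$fluxes), 1e-12)
    recovery <- list(max_relative_error = max(rel_err),
                     median_relative_error = stats::median(rel_err))
    diag$recovery <- recovery
  }
  diag_path <- file.path(outdir, "flux_diagnostics.json")
  jsonlite::write_json(diag, diag_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  graphs <- export_flux_graph(network, sol$normalized,
                              file.path(outdir, "flux_graph"))
  manifest <- record_stage(manifest, "flux",
                           c(flux_path, diag_path, unname(graphs)),
                           proc.time()[3] - t0)
  finish_manifest(manifest, outdir)
  invisible(list(solution = sol$normalized, raw = sol$raw, truth = truth,
                 diagnostics = diag, recovery = recovery, outdir = outdir))
}
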