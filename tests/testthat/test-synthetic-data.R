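# Synthetic-data generators: determinism, ground-truth bookkeeping, and
# distributional calibration.

test_that("intensity generation is a pure function of its config", {
  cfg <- synthetic_metabolome_config(n_metabolites = 40, seed = 42)
  a <- generate_intensity_matrix(cfg)
  b <- generate_intensity_matrix(cfg)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth$differential_ids, b$truth$differential_ids)
  # a different seed changes the draw
  cfg2 <- synthetic_metabolome_config(n_metabolites = 40, seed = 43)
  expect_false(identical(generate_intensity_matrix(cfg2)$matrix$values,
                         a$matrix$values))
})

test_that("planted-effect bookkeeping matches the config", {
  cfg0 <- synthetic_metabolome_config(n_metabolites = 50,
                                      frac_differential = 0, seed = 1)
  expect_length(generate_intensity_matrix(cfg0)$truth$differential_ids, 0)

  cfg <- synthetic_metabolome_config(n_metabolites = 200,
                                     frac_differential = 0.3, seed = 2)
  gen <- generate_intensity_matrix(cfg)
  expect_length(gen$truth$differential_ids, round(0.3 * 200))
  expect_true(all(gen$truth$differential_ids %in%
                    gen$matrix$metabolite_ids))
  # effects split evenly between up and down at the default ratio
  expect_equal(sum(gen$truth$effects_log2 > 0), round(0.5 * 60))
  # planted log2 group difference has the configured magnitude
  expect_true(all(abs(abs(gen$truth$effects_log2) - 2) < 1e-12))
})

test_that("matrix dimensions, classes and missingness follow the config", {
  cfg <- synthetic_metabolome_config(n_per_group = 5, n_metabolites = 300,
                                     missing_rate = 0.2, n_classes = 3,
                                     seed = 7)
  gen <- generate_intensity_matrix(cfg)
  expect_equal(dim(gen$matrix$values), c(10, 300))
  expect_true(all(gen$matrix$class_labels %in%
                    metabolite_class_vocabulary()[1:3]))
  expect_equal(mean(is.na(gen$matrix$values)), 0.2, tolerance = 0.1)
})

test_that("left-censoring missingness is abundance-biased, MCAR is not", {
  cfg <- synthetic_metabolome_config(n_metabolites = 400, missing_rate = 0.3,
                                     missing_mode = "censor", seed = 3)
  gen <- generate_intensity_matrix(cfg)
  cfg_full <- synthetic_metabolome_config(n_metabolites = 400,
                                          missing_rate = 0, seed = 3)
  full <- generate_intensity_matrix(cfg_full)$matrix$values
  miss <- is.na(gen$matrix$values)
  expect_lt(mean(log2(full[miss])), mean(log2(full[!miss])))
})

test_that("t-test power on planted effects matches normal theory", {
  # oracle: pooled t-test power for delta = 2, sd = 1.5, n = 20/group
  oracle <- power.t.test(n = 20, delta = 2, sd = 1.5,
                         sig.level = 0.05)$power
  expect_gt(oracle, 0.9)  # the configuration is a high-power regime
  hits <- trials <- 0
  for (s in 1:20) {
    cfg <- synthetic_metabolome_config(n_per_group = 20, n_metabolites = 40,
                                       frac_differential = 0.5,
                                       effect_log2 = 2, missing_rate = 0,
                                       seed = s)
    gen <- generate_intensity_matrix(cfg)
    x <- log2(gen$matrix$values)
    hi <- gen$matrix$group_labels == "high"
    p <- apply(x[, gen$truth$differential_ids, drop = FALSE], 2,
               function(col) t.test(col[hi], col[!hi],
                                    var.equal = TRUE)$p.value)
    hits <- hits + sum(p < 0.05); trials <- trials + length(p)
  }
  expect_gte(hits / trials, 0.9)
  expect_equal(hits / trials, oracle, tolerance = 0.05)
})

test_that("null data yield the nominal false-positive rate", {
  n_sig <- n_tot <- 0
  for (s in 1:20) {
    cfg <- synthetic_metabolome_config(n_metabolites = 150,
                                       frac_differential = 0,
                                       missing_rate = 0, seed = s)
    gen <- generate_intensity_matrix(cfg)
    x <- log2(gen$matrix$values)
    hi <- gen$matrix$group_labels == "high"
    p <- apply(x, 2, function(col) t.test(col[hi], col[!hi],
                                          var.equal = TRUE)$p.value)
    n_sig <- n_sig + sum(p < 0.05); n_tot <- n_tot + length(p)
  }
  bound <- 2.576 * sqrt(0.05 * 0.95 / n_tot)  # binomial 99% bounds
  expect_lt(abs(n_sig / n_tot - 0.05), bound + 1e-12)
})

test_that("config validation names the offending field", {
  expect_error(synthetic_metabolome_config(n_per_group = 2), "n_per_group")
  expect_error(synthetic_metabolome_config(frac_differential = 1.2),
               "frac_differential")
  expect_error(synthetic_metabolome_config(missing_rate = 1), "missing_rate")
  expect_error(synthetic_metabolome_config(effect_log2 = -1), "effect_log2")
})

test_that("panel generation respects scenario means, CV and n", {
  scn0 <- panel_scenario(c("glucose", "lactate"), mean_low = c(3, 2.5),
                         mean_high = c(4, 1.7), cv = 0, n_per_group = 4,
                         seed = 1)
  pan0 <- generate_panel(scn0)
  glc <- pan0[pan0$metabolite == "glucose", ]
  expect_equal(glc$concentration[glc$group == "low"], rep(3, 4))
  expect_equal(glc$concentration[glc$group == "high"], rep(4, 4))

  # the default scenario matches the assay design: n = 8/group, 16 records
  pan <- generate_panel(default_panel_scenario(seed = 2))
  expect_equal(sum(pan$metabolite == "glucose"), 16)
  expect_true(all(pan$concentration > 0))
  expect_identical(pan, generate_panel(default_panel_scenario(seed = 2)))

  # Monte-Carlo convergence of the planted percent difference
  scn <- panel_scenario("glucose", mean_low = 1, mean_high = 1.37,
                        cv = 0.05, n_per_group = 1000, seed = 3)
  big <- generate_panel(scn)
  pct <- with(big, (mean(concentration[group == "high"]) -
                      mean(concentration[group == "low"])) /
                mean(concentration[group == "low"]) * 100)
  expect_equal(pct, 37, tolerance = 2 / 37)  # within 2 points
})

test_that("panel scenario validation rejects nonpositive means", {
  expect_error(panel_scenario("x", mean_low = 0, mean_high = 1), "mean_low")
  expect_error(panel_scenario("x", mean_low = 1, mean_high = -2),
               "mean_high")
})

test_that("flux scenarios satisfy internal balances and round-trip", {
  net <- default_cmp_network()
  S <- build_stoich_matrix(net)
  internal <- names(which(sapply(net$nodes, `[[`, "role") == "internal_pss"))
  for (s in c(1, 5, 11)) {
    scen <- generate_flux_scenario(net, seed = s, noise_frac = 0)
    # truth satisfies every pseudo-steady-state balance exactly
    expect_lt(max(abs(S[internal, ] %*% scen$truth$fluxes)), 1e-10)
    expect_true(all(scen$truth$fluxes > 0))
    expect_equal(unname(scen$truth$fluxes[["r1"]]), 100)
    # noiseless measurements recover the truth
    sys <- assemble_balance_system(S, net, scen$measurements)
    sol <- normalize_fluxes(solve_fluxes(sys))
    expect_lt(max(abs(sol$fluxes - scen$truth$fluxes) /
                    abs(scen$truth$fluxes)), 1e-6)
  }
})

test_that("flux recovery is invariant to rescaling all concentrations", {
  net <- default_cmp_network()
  S <- build_stoich_matrix(net)
  scen <- generate_flux_scenario(net, seed = 4, noise_frac = 0)
  sol1 <- normalize_fluxes(solve_fluxes(
    assemble_balance_system(S, net, scen$measurements)))
  sol2 <- normalize_fluxes(solve_fluxes(
    assemble_balance_system(S, net, scen$measurements * 10)))
  expect_equal(sol1$fluxes, sol2$fluxes, tolerance = 1e-12)
})
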