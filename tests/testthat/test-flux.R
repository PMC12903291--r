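# Balance-system assembly, the least-squares solver against a pseudo-inverse
# oracle, normalization, and graph export.

test_that("conservation on a chain: both fluxes equal the anchor", {
  net <- make_chain_network()
  S <- build_stoich_matrix(net)
  sys <- assemble_balance_system(S, net, c(A = 5, C = 5), scale = 100)
  sol <- solve_fluxes(sys)
  expect_equal(unname(sol$fluxes), c(100, 100), tolerance = 1e-10)
  expect_lt(sol$residual_norm, 1e-10)
  expect_equal(sol$determinacy, "determined")
})

test_that("assembly pins boundary rates by concentration ratio", {
  net <- make_chain_network()
  S <- build_stoich_matrix(net)
  sys <- assemble_balance_system(S, net, c(A = 4, C = 2), scale = 100)
  # rows: balance:B, anchor:r1, boundary:C with rhs 100 * 2/4 = 50
  expect_equal(unname(sys$b), c(0, 100, 50))
  # rescaling every concentration leaves (A, b) identical
  sys_k <- assemble_balance_system(S, net, c(A = 4, C = 2) * 7.3,
                                   scale = 100)
  expect_equal(sys$A, sys_k$A)
  expect_equal(sys$b, sys_k$b)
})

test_that("assembly errors name missing or invalid measurements", {
  net <- make_chain_network()
  S <- build_stoich_matrix(net)
  expect_error(assemble_balance_system(S, net, c(A = 5)), "C")
  expect_error(assemble_balance_system(S, net, c(A = 0, C = 2)),
               "measurements")
})

test_that("solve_fluxes matches the dense pseudo-inverse oracle", {
  for (s in 1:50) {
    shape <- c(sample(2:6, 1), sample(2:6, 1))
    sys <- make_consistent_system(shape[1], shape[2], seed = s)
    fake <- structure(
      list(A = matrix(sys$A, nrow(sys$A),
                      dimnames = list(rep("balance:x", nrow(sys$A)),
                                      paste0("r", seq_len(ncol(sys$A))))),
           b = setNames(sys$b, rep("balance:x", length(sys$b))),
           reaction_ids = paste0("r", seq_len(ncol(sys$A))),
           network = list(reference_reaction_id = "r1"),
           scale = 100),
      class = "flux_system")
    sol <- solve_fluxes(fake)
    oracle <- drop(MASS::ginv(sys$A) %*% sys$b)
    expect_equal(unname(sol$fluxes), oracle, tolerance = 1e-8)
  }
})

test_that("noisy scenarios are recovered with bounded median error", {
  net <- default_cmp_network()
  S <- build_stoich_matrix(net)
  med_err <- sapply(1:50, function(s) {
    scen <- generate_flux_scenario(net, seed = s, noise_frac = 0.05)
    sol <- normalize_fluxes(solve_fluxes(
      assemble_balance_system(S, net, scen$measurements)))
    median(abs(sol$fluxes - scen$truth$fluxes) / abs(scen$truth$fluxes))
  })
  expect_lte(median(med_err), 0.10)
})

test_that("nonnegative solving respects irreversibility and flags
           infeasibility", {
  net <- default_cmp_network()
  S <- build_stoich_matrix(net)
  scen <- generate_flux_scenario(net, seed = 2, noise_frac = 0)
  sol <- solve_fluxes(assemble_balance_system(S, net, scen$measurements),
                      nonnegative = TRUE)
  expect_true(all(sol$fluxes >= -1e-8))
  expect_equal(unname(normalize_fluxes(sol)$fluxes),
               unname(scen$truth$fluxes), tolerance = 1e-6)

  # an irreversible chain cannot consume its product: B -> C demanded
  # backwards makes the nonnegative system infeasible
  chain <- make_chain_network()
  Sc <- build_stoich_matrix(chain)
  sys <- assemble_balance_system(Sc, chain, c(A = 5, C = 5))
  sys$b[["boundary:C"]] <- -100
  expect_error(solve_fluxes(sys, nonnegative = TRUE), "infeasible")
})

test_that("normalization anchors the reference at exactly 100 and is
           idempotent and scale-invariant", {
  net <- default_cmp_network()
  S <- build_stoich_matrix(net)
  scen <- generate_flux_scenario(net, seed = 6, noise_frac = 0.1)
  raw <- solve_fluxes(assemble_balance_system(S, net, scen$measurements))
  norm1 <- normalize_fluxes(raw)
  expect_identical(unname(norm1$fluxes[["r1"]]), 100)
  expect_true(norm1$normalized)
  # idempotent
  expect_equal(normalize_fluxes(norm1)$fluxes, norm1$fluxes)
  # doubling all fluxes changes nothing after normalization
  doubled <- raw; doubled$fluxes <- raw$fluxes * 2
  expect_equal(normalize_fluxes(doubled)$fluxes, norm1$fluxes,
               tolerance = 1e-12)
  # zero reference flux is an error
  zero <- raw; zero$fluxes[["r1"]] <- 0
  expect_error(normalize_fluxes(zero), "zero flux")
})

test_that("underdetermined systems are reported and solved minimum-norm", {
  # drop the boundary equations from the default system: 4 free directions
  net <- default_cmp_network()
  S <- build_stoich_matrix(net)
  scen <- generate_flux_scenario(net, seed = 3)
  sys <- assemble_balance_system(S, net, scen$measurements)
  keep <- grepl("^(balance|anchor)", names(sys$b))
  sys$A <- sys$A[keep, , drop = FALSE]; sys$b <- sys$b[keep]
  sol <- solve_fluxes(sys)
  expect_equal(sol$determinacy, "underdetermined")
  expect_lt(sol$residual_norm, 1e-8)
  oracle <- drop(MASS::ginv(unname(sys$A)) %*% unname(sys$b))
  expect_equal(unname(sol$fluxes), oracle, tolerance = 1e-8)
})

test_that("graph export round-trips fluxes and maps width monotonically", {
  net <- default_cmp_network()
  S <- build_stoich_matrix(net)
  scen <- generate_flux_scenario(net, seed = 5)
  raw <- solve_fluxes(assemble_balance_system(S, net, scen$measurements))
  expect_error(export_flux_graph(net, raw, tempfile()), "normalize")
  sol <- normalize_fluxes(raw)
  base <- tempfile()
  paths <- export_flux_graph(net, sol, base)
  expect_true(all(file.exists(paths)))

  g <- igraph::read_graph(paths[["graphml"]], format = "graphml")
  ea <- igraph::edge_attr(g)
  # every reaction's edges carry its normalized flux
  for (rid in names(sol$fluxes)) {
    expect_equal(unique(ea$flux[ea$reaction == rid]),
                 unname(sol$fluxes[[rid]]), tolerance = 1e-6)
  }
  # one edge per substrate-product pair: r7 (2 substrates) and r10 (2)
  # add one extra edge each; r5, r8, r9 (2 products) likewise
  expect_equal(igraph::ecount(g), 15)
  expect_setequal(unique(igraph::vertex_attr(g, "role")),
                  c("boundary_measured", "internal_pss", "sink_unmeasured"))

  dot <- readLines(paths[["dot"]])
  edge_lines <- grep("->", dot, value = TRUE)
  flux <- as.numeric(sub(".*flux=([0-9.eE+-]+),.*", "\\1", edge_lines))
  pw <- as.numeric(sub(".*penwidth=([0-9.]+)\\].*", "\\1", edge_lines))
  expect_equal(order(flux), order(pw))  # monotone map
  expect_true(all(pw >= 0.5 & pw <= 5))
})
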