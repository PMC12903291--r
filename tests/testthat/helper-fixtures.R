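# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# Two-group matrix with a planted mean shift on the first `n_signal`
# metabolites (log2 scale), no missingness.
make_two_group_matrix <- function(n_per_group = 6, p = 50, n_signal = 0,
                                  shift_log2 = 0, seed = 1, sd_log2 = 1.5) {
  set.seed(seed)
  g <- rep(c("low", "high"), each = n_per_group)
  log2x <- matrix(rnorm(2 * n_per_group * p, 20, sd_log2), 2 * n_per_group)
  if (n_signal > 0) {
    log2x[g == "high", seq_len(n_signal)] <-
      log2x[g == "high", seq_len(n_signal)] + shift_log2
  }
  intensity_matrix(2^log2x, g)
}

# Strongly separable fixture used for model-validity checks: generator
# defaults (6/group, 705 metabolites, 31.5% differential) but with a large
# 16-fold planted effect and complete data.
make_separable_matrix <- function(seed = 1) {
  cfg <- synthetic_metabolome_config(effect_log2 = 4, missing_rate = 0,
                                     seed = seed)
  generate_intensity_matrix(cfg)$matrix
}

# Tiny linear chain network A --r1--> B --r2--> C: one internal node (B),
# boundary-measured endpoints.
make_chain_network <- function() {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    metabolites = list(
      list(id = "A", role = "boundary_measured", sign = -1),
      list(id = "B", role = "internal_pss"),
      list(id = "C", role = "boundary_measured", sign = 1)
    ),
    reactions = list(
      list(id = "r1", substrates = list(list("A", 1)),
           products = list(list("B", 1)), pathway = "glycolysis",
           reversible = FALSE),
      list(id = "r2", substrates = list(list("B", 1)),
           products = list(list("C", 1)), pathway = "other",
           reversible = FALSE)
    )), path, auto_unbox = TRUE)
  parse_network(path)
}

# A random small consistent linear system with known solution.
make_consistent_system <- function(n_eq, n_var, seed) {
  set.seed(seed)
  A <- matrix(rnorm(n_eq * n_var), n_eq)
  x <- rnorm(n_var)
  list(A = A, b = drop(A %*% x), x = x)
}

expect_json_number <- function(x) {
  expect_true(is.numeric(x) && length(x) == 1 && is.finite(x))
}
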