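# OPLS-DA model fitting, VIP and permutation validation.

test_that("a perfectly separating no-noise fixture is fit almost exactly", {
  # three metabolites, each binary in the groups up to tiny jitter
  set.seed(1)
  g <- rep(c("low", "high"), each = 6)
  log2x <- sapply(1:3, function(j) {
    ifelse(g == "high", 22, 18) + rnorm(12, 0, 0.01)
  })
  m <- intensity_matrix(2^log2x, g)
  mod <- fit_oplsda(m, n_orth = 1, cv_seed = 1)
  expect_gte(mod$R2Y, 0.99)
  expect_gte(mod$Q2, 0.9)
})

test_that("strongly separable generator data give R2Y >= 0.99, Q2 >= 0.9", {
  mod <- fit_oplsda(make_separable_matrix(seed = 3), cv_seed = 4)
  expect_gte(mod$R2Y, 0.99)
  expect_gte(mod$Q2, 0.9)
  expect_lte(mod$Q2, mod$R2Y + 1e-9)
})

test_that("orthogonal scores carry no covariance with the response", {
  m <- make_two_group_matrix(p = 40, n_signal = 10, shift_log2 = 2, seed = 5)
  mod <- fit_oplsda(m, n_orth = 2, cv_seed = 2)
  for (a in seq_len(mod$n_orth)) {
    expect_lt(abs(cor(mod$orth_scores[, a], mod$y)), 1e-8)
  }
})

test_that("null data with shuffled labels give mean Q2 <= 0.2", {
  q2 <- sapply(1:20, function(s) {
    cfg <- synthetic_metabolome_config(n_metabolites = 80,
                                       frac_differential = 0,
                                       missing_rate = 0, seed = s)
    m <- generate_intensity_matrix(cfg)$matrix
    fit_oplsda(m, cv_seed = s)$Q2
  })
  expect_lte(mean(q2), 0.2)
})

test_that("with n_orth = 0 the model matches an independent PLS-DA", {
  m <- make_two_group_matrix(p = 30, n_signal = 8, shift_log2 = 2, seed = 6)
  mod <- fit_oplsda(m, n_orth = 0, cv_seed = 1)
  ref <- mixOmics::plsda(scale(log2(m$values + 1)),
                         factor(m$group_labels), ncomp = 1, scale = FALSE)
  t_ref <- ref$variates$X[, 1]
  expect_gt(abs(cor(mod$t_p, t_ref)), 1 - 1e-8)
})

test_that("an appended duplicate metabolite barely moves the score direction", {
  m <- make_two_group_matrix(p = 200, n_signal = 50, shift_log2 = 1,
                             seed = 7)
  dup <- intensity_matrix(cbind(m$values, m$values[, 1]),
                          m$group_labels,
                          metabolite_ids = c(m$metabolite_ids, "dup"))
  t1 <- fit_oplsda(m, cv_seed = 1)$t_p
  t2 <- fit_oplsda(dup, cv_seed = 1)$t_p
  expect_gt(cor(t1, t2), 1 - 1e-3)
})

test_that("VIP evaluates its formula and algebraic identity", {
  fake <- function(w) {
    structure(list(weights = w / sqrt(sum(w^2)),
                   metabolite_ids = paste0("M", seq_along(w))),
              class = "oplsda_model")
  }
  # equal shares: every VIP exactly 1
  expect_equal(unname(compute_vip(fake(rep(1, 4)))), rep(1, 4))
  # all weight on one variable: VIP = (sqrt(p), 0, 0)
  expect_equal(unname(compute_vip(fake(c(1, 0, 0)))), c(sqrt(3), 0, 0))
  # fitted models: mean(VIP^2) = 1 to 1e-10, invariant to metabolite order
  m <- make_two_group_matrix(p = 25, n_signal = 5, shift_log2 = 2, seed = 8)
  vip <- compute_vip(fit_oplsda(m, cv_seed = 1))
  expect_equal(mean(vip^2), 1, tolerance = 1e-10)
  perm <- sample(25)
  shuf <- intensity_matrix(m$values[, perm], m$group_labels,
                           metabolite_ids = m$metabolite_ids[perm])
  vip2 <- compute_vip(fit_oplsda(shuf, cv_seed = 1))
  expect_equal(vip2[m$metabolite_ids], vip[m$metabolite_ids],
               tolerance = 1e-8)
  expect_error(compute_vip(list()), "oplsda_model")
})

test_that("permutation test is seeded, calibrated and detects real models", {
  m <- make_two_group_matrix(p = 60, n_signal = 20, shift_log2 = 3, seed = 9)
  a <- permutation_test(m, n_permutations = 50, seed = 21)
  b <- permutation_test(m, n_permutations = 50, seed = 21)
  expect_identical(a$permuted_Q2, b$permuted_Q2)
  expect_identical(a$permuted_R2Y, b$permuted_R2Y)

  full <- permutation_test(m, n_permutations = 200, seed = 22)
  expect_lte(full$p_Q2, 0.01)
  expect_gt(full$p_Q2, 0)  # add-one correction keeps p > 0

  expect_warning(permutation_test(m, n_permutations = 10, seed = 1),
                 "resolution")
})

test_that("model preconditions are enforced", {
  m <- make_two_group_matrix(p = 10, seed = 10)
  expect_error(fit_oplsda(m, n_orth = 10), "n_orth")
  v <- m$values; v[2, 2] <- NA
  expect_error(fit_oplsda(intensity_matrix(v, m$group_labels)), "impute")
})
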