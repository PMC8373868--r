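test_that("fate probabilities reproduce hand evaluations", {
  # unmutated epithelial cell, vanishing crowding, no effectors
  pars <- model_params()
  pr <- compute_fate_probabilities(tumor_cells(1), n_tumor = 1,
                                   immune_state(), pars)
  crowd <- 1 / (1 + 1 / pars$K_0)
  expect_equal(pr$rho_P, pars$p * crowd, tolerance = 1e-12)
  expect_equal(pr$rho_A, pars$d_C, tolerance = 1e-12)
  expect_identical(pr$rho_NK, 0)
  expect_identical(pr$rho_CTL, 0)
  expect_equal(pr$rho_R, 1 - pars$p * crowd - pars$d_C, tolerance = 1e-12)

  # mutated mesenchymal cell under crowding: p (1+Delta_P) (1-Delta_MGA) / 2
  pr2 <- compute_fate_probabilities(
    tumor_cells(1, delta_P = TRUE, zeta = TRUE),
    n_tumor = 100, immune_state(),
    model_params(p = 0.2, Delta_P = 0.5, Delta_MGA = 0.25, K_0 = 100))
  expect_equal(pr2$rho_P, 0.1125, tolerance = 1e-12)

  # NK clearance of a mutated cell: (50/51) * 0.5
  pr3 <- compute_fate_probabilities(
    tumor_cells(1, delta_P = TRUE),
    n_tumor = 100, immune_state(N_NK = 50),
    model_params(K_1 = 100, E_NK = 0.5, Delta_MIE = 0))
  expect_equal(pr3$rho_NK, (50 / 51) * 0.5, tolerance = 1e-9)
})

test_that("complete mesenchymal immune evasion nullifies clearance", {
  pars <- model_params(Delta_MIE = 1)
  pr <- compute_fate_probabilities(
    tumor_cells(1, delta_P = TRUE, delta_IE = FALSE, zeta = TRUE),
    n_tumor = 50, immune_state(N_NK = 1e3, N_CTL = 1e3), pars)
  expect_identical(pr$rho_NK, 0)
  expect_identical(pr$rho_CTL, 0)
})

test_that("fate probabilities conserve mass and respect monotonicities", {
  set.seed(42)
  for (i in 1:50) {
    pars <- model_params(
      p = runif(1), d_C = runif(1), Delta_P = runif(1), Delta_A = runif(1),
      Delta_IE = runif(1), Delta_MGA = runif(1), Delta_MIE = runif(1),
      E_NK = runif(1), E_CTL = runif(1),
      delta_MUT_baseline = runif(1))
    cells <- tumor_cells(8,
      delta_P = sample(c(TRUE, FALSE), 8, TRUE),
      delta_A = sample(c(TRUE, FALSE), 8, TRUE),
      delta_IE = sample(c(TRUE, FALSE), 8, TRUE),
      zeta = sample(c(TRUE, FALSE), 8, TRUE))
    imm <- immune_state(N_NK = runif(1, 0, 100), N_CTL = runif(1, 0, 100),
                        N_Treg = runif(1, 0, 100))
    n_tumor <- sample(1:500, 1)
    pr <- compute_fate_probabilities(cells, n_tumor, imm, pars)
    tot <- pr$rho_P + pr$rho_A + pr$rho_NK + pr$rho_CTL + pr$rho_R
    expect_true(all(abs(tot - 1) < 1e-12))
    expect_true(all(as.matrix(pr) >= 0 & as.matrix(pr) <= 1))

    # crowding: rho_P non-increasing in N_C
    pr_big <- compute_fate_probabilities(cells, n_tumor + 100, imm, pars)
    expect_true(all(pr_big$rho_P <= pr$rho_P + 1e-15))

    # Treg suppression: rho_NK non-increasing in N_Treg
    imm_tr <- immune_state(N_NK = imm$N_NK, N_CTL = imm$N_CTL,
                           N_Treg = imm$N_Treg + 50)
    pr_tr <- compute_fate_probabilities(cells, n_tumor, imm_tr, pars)
    expect_true(all(pr_tr$rho_NK <= pr$rho_NK + 1e-15))
  }
})

test_that("invalid fate-probability inputs are rejected", {
  expect_error(compute_fate_probabilities(tumor_cells(1), 0, immune_state(),
                                          model_params()),
               "n_tumor")
  expect_error(immune_state(N_NK = -1), ">= 0")
})

test_that("fate draws are categorical, reproducible and well-calibrated", {
  degenerate <- tibble::tibble(rho_P = 1, rho_A = 0, rho_NK = 0,
                               rho_CTL = 0, rho_R = 0)
  expect_identical(as.character(draw_fate(degenerate)), "PROLIFERATE")

  probs <- tibble::tibble(rho_P = 0.3, rho_A = 0.2, rho_NK = 0.1,
                          rho_CTL = 0.1, rho_R = 0.3)
  set.seed(9); a <- draw_fate(probs)
  set.seed(9); b <- draw_fate(probs)
  expect_identical(a, b)

  # empirical frequencies within 4 binomial standard errors
  n <- 1e5
  many <- probs[rep(1, n), ]
  set.seed(7)
  f <- draw_fate(many)
  p <- c(0.3, 0.2, 0.1, 0.1, 0.3)
  emp <- as.numeric(table(f)[levels(f)]) / n
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(emp - p) < 4 * se))

  bad <- tibble::tibble(rho_P = 0.5, rho_A = 0.5, rho_NK = 0.5,
                        rho_CTL = 0, rho_R = 0)
  expect_error(draw_fate(bad), "sum to 1")
})

test_that("mutation machinery accrues, resets and replays exactly", {
  pars <- model_params()
  set.seed(1)
  # impossible mutation: pure accrual
  res <- update_mutation_machinery(tumor_cells(1, mut_prob = 0), pars)
  expect_false(res$acquired)
  expect_equal(res$cells$mut_prob, 1e-4)
  # certain mutation: reset to 0 and exactly one pathway gained
  res2 <- update_mutation_machinery(tumor_cells(1, mut_prob = 1), pars)
  expect_true(res2$acquired)
  expect_identical(res2$cells$mut_prob, 0)
  expect_identical(sum(res2$cells$delta_P, res2$cells$delta_A,
                       res2$cells$delta_IE), 1L)
  # 37 consecutive non-mutating proliferations: arithmetic accrual
  cell <- tumor_cells(1, mut_prob = 0)
  pars0 <- model_params()
  for (i in 1:37) {
    step <- update_mutation_machinery(cell, pars0)
    # force the non-mutating branch by construction: acquisition probability
    # is < 37e-4, so re-draw on the rare hit
    while (any(step$acquired)) step <- update_mutation_machinery(cell, pars0)
    cell <- step$cells
  }
  expect_equal(cell$mut_prob, 0.0037, tolerance = 1e-12)
})

test_that("pathway choice is forced, uniform, and saturates to a no-op", {
  pars <- model_params()
  # only delta_IE open
  c1 <- choose_mutation_pathway(tumor_cells(1, delta_P = TRUE,
                                            delta_A = TRUE))
  expect_true(c1$delta_IE)
  # all open: uniform over three pathways
  set.seed(5)
  n <- 1e4
  picks <- choose_mutation_pathway(tumor_cells(n))
  freq <- c(mean(picks$delta_P), mean(picks$delta_A), mean(picks$delta_IE))
  se <- sqrt((1 / 3) * (2 / 3) / n)
  expect_true(all(abs(freq - 1 / 3) < 4 * se))
  expect_true(all(rowSums(cbind(picks$delta_P, picks$delta_A,
                                picks$delta_IE)) == 1))
  # saturation: no open pathway, cell unchanged and flagged
  full <- tumor_cells(1, delta_P = TRUE, delta_A = TRUE, delta_IE = TRUE)
  out <- choose_mutation_pathway(full)
  expect_equal(out, full, ignore_attr = TRUE)
  expect_true(attr(out, "saturated"))
})

test_that("EMT score decays without TGF-beta and converges to its fixed point", {
  pars <- model_params(emt_gain = 0.2, emt_decay = 0.1, K_tau = 2,
                       T_MES = 0.5)
  # zero input: monotone decay toward 0, phenotype reverts
  cells <- tumor_cells(1, emt_score = 0.9, zeta = TRUE)
  prev <- cells$emt_score
  for (i in 1:200) {
    cells <- update_emt_score(cells, 0, pars)
    expect_lte(cells$emt_score, prev)
    prev <- cells$emt_score
  }
  expect_lt(cells$emt_score, 1e-4)
  expect_false(cells$zeta)

  # constant input: fixed point g / (g + decay)
  tau_hat <- 3
  g <- pars$emt_gain * tau_hat / (tau_hat + pars$K_tau)
  fp <- g / (g + pars$emt_decay)
  cells <- tumor_cells(1, emt_score = 0)
  for (i in 1:2000) cells <- update_emt_score(cells, tau_hat, pars)
  expect_equal(cells$emt_score, fp, tolerance = 1e-8)

  # threshold is strict: score exactly at T_MES stays epithelial
  pars_hold <- model_params(emt_gain = 0, emt_decay = 0, T_MES = 0.5)
  at <- update_emt_score(tumor_cells(1, emt_score = 0.5), 0, pars_hold)
  expect_false(at$zeta)
  above <- update_emt_score(tumor_cells(1, emt_score = 0.5000001), 0,
                            pars_hold)
  expect_true(above$zeta)

  expect_error(update_emt_score(tumor_cells(1), -1, pars), "tgfb")
})

test_that("EMT score stays within [0,1] under arbitrary TGF-beta input", {
  pars <- model_params(emt_gain = 0.9, emt_decay = 0.9, K_tau = 0.1)
  set.seed(3)
  cells <- tumor_cells(5, emt_score = runif(5))
  for (i in 1:300) {
    cells <- update_emt_score(cells, rexp(1, 1 / 50), pars)
    expect_true(all(cells$emt_score >= 0 & cells$emt_score <= 1))
  }
})
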